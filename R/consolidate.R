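# Map curated factor baits into each method's orthogroups, combine methods,
# and compute the consolidation statistics (overlap of the two predictors,
# factors with no orthologue under either, factors with co-orthologue
# multiplicity in the target species).

#' Map factors into each method's orthogroups
#'
#' For each factor and method, the orthologue set in species `s` is the union
#' over the factor's baits of the bait's group-mates in `s`. Baits never count
#' as their own orthologues in their own species (the factor's bait genes are
#' excluded from all of its sets). Factors whose baits sit in no group get
#' empty sets. Baits absent from the gene universe are recorded and the
#' factor is processed with the remaining baits.
#'
#' @param inventory Inventory data.frame (see [read_inventory()]).
#' @param groups_by_method Named list of [orthology_groups()] objects.
#' @param target_species Character vector of species to collect sets for.
#' @return A list of `factor_record` objects. Each has `factor_name`,
#'   `compartment`, `baits`, `missing_baits`, `per_method_sets`
#'   (method -> species -> gene ids), `consensus_sets` (species -> union),
#'   and `agreement` (TRUE iff all methods give identical sets for every
#'   target species).
#' @export
map_factors_to_groups <- function(inventory, groups_by_method, target_species) {
  stopifnot(length(groups_by_method) >= 1L)
  if (is.null(names(groups_by_method))) {
    names(groups_by_method) <- vapply(groups_by_method, `[[`, "", "method_id")
  }
  universe <- unique(unlist(lapply(groups_by_method,
                                   function(og) names(og$index)),
                            use.names = FALSE))
  lapply(seq_len(nrow(inventory)), function(i) {
    baits <- inventory$baits[[i]]
    missing <- baits[!(baits %in% universe)]
    per_method <- lapply(groups_by_method, function(og) {
      sets <- lapply(target_species, function(s) {
        mates <- unlist(lapply(baits, function(b) {
          m <- group_mates(og, b, species = s)
          unname(m)
        }), use.names = FALSE)
        sort(unique(setdiff(mates, baits)))
      })
      setNames(sets, target_species)
    })
    consensus <- setNames(lapply(target_species, function(s) {
      sort(unique(unlist(lapply(per_method, `[[`, s), use.names = FALSE)))
    }), target_species)
    agreement <- all(vapply(target_species, function(s) {
      sets <- lapply(per_method, `[[`, s)
      all(vapply(sets, identical, TRUE, y = sets[[1L]]))
    }, TRUE))
    structure(list(factor_name = inventory$factor_name[i],
                   compartment = inventory$compartment[i],
                   baits = baits, missing_baits = missing,
                   per_method_sets = per_method,
                   consensus_sets = consensus,
                   agreement = agreement),
              class = "factor_record")
  })
}

#' @export
print.factor_record <- function(x, ...) {
  cat("factor_record ", x$factor_name, " (", x$compartment, "): ",
      paste(vapply(names(x$consensus_sets), function(s) {
        paste0(s, "=", length(x$consensus_sets[[s]]))
      }, ""), collapse = ", "),
      if (x$agreement) " [methods agree]" else " [methods disagree]",
      "\n", sep = "")
  invisible(x)
}

#' Method-overlap statistic
#'
#' Fraction of factors for which all methods yield identical orthologue sets
#' in every target species (the strict, factor-level reading of prediction
#' overlap).
#'
#' @param records List of factor records from [map_factors_to_groups()].
#' @return Fraction in `[0, 1]`.
#' @export
overlap_statistic <- function(records) {
  if (length(records) == 0L) stop("overlap_statistic undefined for 0 factors")
  if (length(records[[1L]]$per_method_sets) < 2L) {
    stop("overlap_statistic needs >= 2 methods")
  }
  mean(vapply(records, `[[`, TRUE, "agreement"))
}

#' Fraction of factors with no orthologue under any method
#'
#' @param records List of factor records.
#' @param species Species whose sets are inspected.
#' @return Fraction of factors whose set in `species` is empty under every
#'   method.
#' @export
missing_statistic <- function(records, species) {
  if (length(records) == 0L) stop("missing_statistic undefined for 0 factors")
  mean(vapply(records, function(r) {
    all(vapply(r$per_method_sets, function(m) length(m[[species]]) == 0L, TRUE))
  }, TRUE))
}

#' Fraction of factors with more than one consensus (co-)orthologue
#'
#' @param records List of factor records.
#' @param species Species whose consensus sets are inspected.
#' @return Fraction of factors whose consensus set in `species` has size > 1.
#' @export
multiplicity_statistic <- function(records, species) {
  if (length(records) == 0L) {
    stop("multiplicity_statistic undefined for 0 factors")
  }
  mean(vapply(records, function(r) {
    length(r$consensus_sets[[species]]) > 1L
  }, TRUE))
}

#' Orthologue counts over an inventory
#'
#' Both counters of inventory size are emitted: the number of distinct genes
#' appearing in any factor's consensus set for `species`, and the number of
#' factor-gene assignments (a gene claimed by two factors counts twice).
#'
#' @param records List of factor records.
#' @param species Target species.
#' @return List with `distinct_genes` and `assignments`.
#' @export
orthologue_counts <- function(records, species) {
  sets <- lapply(records, function(r) r$consensus_sets[[species]])
  list(distinct_genes = length(unique(unlist(sets, use.names = FALSE))),
       assignments = sum(lengths(sets)))
}

#' Per-factor consolidation table
#'
#' @param records List of factor records.
#' @return data.frame with one row per factor and per-method plus consensus
#'   sets as semicolon-joined strings.
#' @export
consolidation_table <- function(records) {
  methods <- names(records[[1L]]$per_method_sets)
  species <- names(records[[1L]]$consensus_sets)
  rows <- lapply(records, function(r) {
    row <- list(factor_name = r$factor_name, compartment = r$compartment,
                agreement = r$agreement)
    for (m in methods) for (s in species) {
      row[[paste(m, s, sep = "_")]] <-
        paste(r$per_method_sets[[m]][[s]], collapse = ";")
    }
    for (s in species) {
      row[[paste0("consensus_", s)]] <-
        paste(r$consensus_sets[[s]], collapse = ";")
    }
    as.data.frame(row, check.names = FALSE)
  })
  do.call(rbind, rows)
}
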