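# Evidence integration: per factor, resolve the cross-species candidate
# pairs through the cascade consensus -> domain architecture (including
# split genes) -> shared synteny -> expression, and emit the final
# assignment table plus the colour-coded inventory category.

#' Evidence bundle for the assignment cascade
#'
#' Collects everything [integrate_evidence()] consults.
#'
#' @param architectures Named list of architectures.
#' @param gmap A [gene_map()].
#' @param groups_by_method Named list of [orthology_groups()].
#' @param expression Named list of `expression_matrix` objects per species.
#' @param eqmap Domain equivalence map.
#' @param w Synteny window half-width.
#' @param r_min,margin Expression pairing thresholds (see
#'   [assign_by_expression()]).
#' @param fusion_max_gap Rank gap for split-gene partners.
#' @return A list of class `evidence_bundle`.
#' @export
evidence_bundle <- function(architectures, gmap, groups_by_method,
                            expression = NULL,
                            eqmap = default_equivalence_map(), w = 7,
                            r_min = 0.8, margin = 0.1, fusion_max_gap = 1) {
  structure(list(architectures = architectures, gmap = gmap,
                 groups_by_method = groups_by_method,
                 expression = expression, eqmap = eqmap, w = w,
                 r_min = r_min, margin = margin,
                 fusion_max_gap = fusion_max_gap),
            class = "evidence_bundle")
}

assignment_row <- function(factor_name, geneA, geneB, evidence,
                           fusion_id = NA_character_, unresolved = FALSE) {
  n <- max(length(geneA), length(geneB))
  data.frame(factor_name = rep_len(factor_name, n),
             geneA = rep_len(geneA, n), geneB = rep_len(geneB, n),
             evidence = rep_len(evidence, n),
             fusion_id = rep_len(fusion_id, n),
             unresolved = rep_len(unresolved, n), stringsAsFactors = FALSE)
}

empty_assignment <- function() {
  assignment_row(character(0), character(0), character(0), character(0),
                 character(0), logical(0))
}

#' Integrate all evidence for one factor
#'
#' Candidate genes on the A side are the factor's baits in `speciesA` plus
#' its consensus orthologues there; the B side is the consensus set in
#' `speciesB` (plus any `speciesB` baits). The cascade assigns pairs in
#' order: (1) a 1:1 candidate situation is assigned with flag `consensus`;
#' (2) mutually unique equal-architecture matches get flag `architecture`,
#' and an A gene whose architecture equals the concatenation of two adjacent
#' B genes yields one `architecture`-flagged row per partner sharing a
#' fusion-event id; (3) synteny-dominant pairs get `+`; (4) expression-
#' dominant pairs get `#`; (5) whatever remains is emitted as unresolved
#' candidate rows.
#'
#' @param record A `factor_record` from [map_factors_to_groups()].
#' @param evidence An [evidence_bundle()].
#' @param speciesA,speciesB The two species being paired.
#' @return data.frame of assignment rows (columns `factor_name`, `geneA`,
#'   `geneB`, `evidence`, `fusion_id`, `unresolved`).
#' @export
integrate_evidence <- function(record, evidence, speciesA = "spA",
                               speciesB = "spB") {
  ev <- evidence
  fn <- record$factor_name
  baitsA <- unname(record$baits[names(record$baits) == speciesA])
  baitsB <- unname(record$baits[names(record$baits) == speciesB])
  A <- sort(unique(c(baitsA, record$consensus_sets[[speciesA]])))
  B <- sort(unique(c(baitsB, record$consensus_sets[[speciesB]])))
  rows <- empty_assignment()
  if (length(A) == 0L || length(B) == 0L) {
    if (length(A) + length(B) > 0L) {
      rows <- assignment_row(fn,
                             if (length(A)) A else NA_character_,
                             if (length(B)) B else NA_character_,
                             "", unresolved = TRUE)
    }
    return(rows)
  }
  # (1) one-to-one consensus
  if (length(A) == 1L && length(B) == 1L) {
    return(assignment_row(fn, A, B, "consensus"))
  }
  freeA <- A; freeB <- B
  fusion_counter <- 0L
  # (2) architecture: mutually unique equal-architecture matches
  arch_of <- function(g) ev$architectures[[g]] %||% character(0)
  match_mat <- outer(freeA, freeB, Vectorize(function(a, b) {
    la <- arch_of(a); lb <- arch_of(b)
    length(la) > 0L && architectures_equal(la, lb, ev$eqmap)
  }))
  for (ai in seq_along(freeA)) {
    bs <- which(match_mat[ai, ])
    if (length(bs) == 1L && sum(match_mat[, bs]) == 1L) {
      rows <- rbind(rows, assignment_row(fn, freeA[ai], freeB[bs],
                                         "architecture"))
    }
  }
  freeA <- setdiff(freeA, rows$geneA)
  freeB <- setdiff(freeB, rows$geneB)
  # (2b) split genes: one A gene equals two adjacent B genes combined
  for (a in freeA) {
    if (length(arch_of(a)) < 2L) next
    fus <- suppressWarnings(
      detect_fusion(a, speciesB, ev$gmap, ev$architectures, ev$eqmap,
                    max_gap = ev$fusion_max_gap))
    taken <- setdiff(B, freeB)   # B genes already assigned upstream
    fus <- fus[(fus$gene1 %in% freeB | fus$gene2 %in% freeB) &
               !(fus$gene1 %in% taken) & !(fus$gene2 %in% taken), ,
               drop = FALSE]
    if (nrow(fus) == 1L) {
      fusion_counter <- fusion_counter + 1L
      fid <- paste0(fn, "_fusion", fusion_counter)
      rows <- rbind(rows,
                    assignment_row(fn, a, fus$gene1, "architecture", fid),
                    assignment_row(fn, a, fus$gene2, "architecture", fid))
      freeA <- setdiff(freeA, a)
      freeB <- setdiff(freeB, c(fus$gene1, fus$gene2))
    }
  }
  # (3) synteny over the remaining cross product (mappable genes only)
  mappable <- as.data.frame(ev$gmap)$gene_id
  if (length(intersect(freeA, mappable)) > 0L &&
      length(intersect(freeB, mappable)) > 0L) {
    cand <- expand.grid(geneA = intersect(freeA, mappable),
                        geneB = intersect(freeB, mappable),
                        stringsAsFactors = FALSE)
    scored <- score_candidates(cand, ev$gmap, ev$groups_by_method, w = ev$w)
    syn <- assign_by_synteny(scored)
    syn <- syn[syn$flag, , drop = FALSE]
    if (nrow(syn) > 0L) {
      rows <- rbind(rows, assignment_row(fn, syn$geneA, syn$geneB, "+"))
      freeA <- setdiff(freeA, syn$geneA)
      freeB <- setdiff(freeB, syn$geneB)
    }
  }
  # (4) expression over what is still ambiguous
  if (length(freeA) > 0L && length(freeB) > 0L && !is.null(ev$expression)) {
    cand <- expand.grid(geneA = freeA, geneB = freeB,
                        stringsAsFactors = FALSE)
    exA <- ev$expression[[speciesA]]; exB <- ev$expression[[speciesB]]
    scales <- c(platform_scale(attr(exA, "platform")),
                platform_scale(attr(exB, "platform")))
    r <- vapply(seq_len(nrow(cand)), function(i) {
      if (!(cand$geneA[i] %in% rownames(exA)) ||
          !(cand$geneB[i] %in% rownames(exB))) return(NA_real_)
      suppressMessages(expression_correlation(
        exA[cand$geneA[i], ], exB[cand$geneB[i], ],
        platform_scales = scales))
    }, 0)
    expr <- assign_by_expression(cand, r, r_min = ev$r_min,
                                 margin = ev$margin)
    expr <- expr[expr$flag, , drop = FALSE]
    if (nrow(expr) > 0L) {
      rows <- rbind(rows, assignment_row(fn, expr$geneA, expr$geneB, "#"))
      freeA <- setdiff(freeA, expr$geneA)
      freeB <- setdiff(freeB, expr$geneB)
    }
  }
  # (5) unresolved candidates
  if (length(freeA) > 0L && length(freeB) > 0L) {
    cand <- expand.grid(geneA = freeA, geneB = freeB,
                        stringsAsFactors = FALSE)
    rows <- rbind(rows, assignment_row(fn, cand$geneA, cand$geneB, "",
                                       unresolved = TRUE))
  } else if (length(freeA) + length(freeB) > 0L) {
    rows <- rbind(rows, assignment_row(
      fn,
      if (length(freeA)) freeA else NA_character_,
      if (length(freeB)) freeB else NA_character_,
      "", unresolved = TRUE))
  }
  rownames(rows) <- NULL
  rows
}

platform_scale <- function(platform) {
  switch(platform, microarray = 100, rnaseq = 1000, 1)
}

#' Colour-coded inventory category of one factor
#'
#' Deterministic total mapping onto the six display categories: a factor
#' with no plant orthologue at all is `absent_in_plants` (yellow); one found
#' in plants but not in species B is `absent_in_B` (brown); a factor with no
#' non-plant bait is `plant_only` (red); otherwise the gene counts decide
#' `equal` (green), `more_in_B` (blue) or `fewer_in_B` (pink).
#'
#' @param countA,countB Gene counts in species A and B.
#' @param found_in_any_plant Was any plant orthologue found?
#' @param found_in_B Was any orthologue found in species B?
#' @param has_nonplant_bait Does the factor have a non-plant (e.g. yeast)
#'   bait?
#' @return One of `"equal"`, `"more_in_B"`, `"fewer_in_B"`,
#'   `"absent_in_plants"`, `"plant_only"`, `"absent_in_B"`.
#' @export
categorize_factor <- function(countA, countB, found_in_any_plant, found_in_B,
                              has_nonplant_bait) {
  if (!found_in_any_plant) return("absent_in_plants")
  if (!found_in_B) return("absent_in_B")
  if (!has_nonplant_bait) return("plant_only")
  if (countA == countB) "equal" else if (countB > countA) "more_in_B"
  else "fewer_in_B"
}

#' Print and count a factor inventory
#'
#' Prints the total number of curated factors and the per-compartment
#' breakdown.
#'
#' @param inventory Inventory data.frame ([read_inventory()]); defaults to
#'   the packaged 130-factor inventory.
#' @return The number of factor rows, invisibly.
#' @export
report_inventory <- function(inventory = packaged_inventory()) {
  n <- nrow(inventory)
  cat(n, "\n", sep = "")
  cat("factor inventory:", n, "factors\n")
  tab <- table(inventory$compartment)
  for (k in names(tab)) cat("  ", k, ": ", tab[[k]], "\n", sep = "")
  invisible(n)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes qc -> orthology inference (or the emulated method outputs) ->
#' consolidation -> evidence cascade -> assignment, and computes summary
#' statistics; when a planted truth is present, recovery and precision
#' against it are reported. Re-running with the same config (and therefore
#' seed) reproduces every output exactly.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()]; built from
#'   `config` if missing.
#' @param config A [sim_config()] used when `dataset` is missing.
#' @param infer Use the built-in similarity-graph engines (`TRUE`, default)
#'   or the dataset's emulated method outputs (`FALSE`).
#' @param min_score Edge threshold for [build_similarity_graph()].
#' @param w Synteny window half-width.
#' @return List of class `pipeline_result` with `qc`, `groups`, `records`,
#'   `stats`, `assignments`, `categories` and `truth`.
#' @export
run_pipeline <- function(dataset = NULL, config = sim_config(),
                         infer = TRUE, min_score = 1, w = 7) {
  if (is.null(dataset)) dataset <- generate_dataset(config)
  qc <- filter_quality(dataset$proteins)
  kept <- dataset$proteins[dataset$proteins$id %in% qc$kept, , drop = FALSE]
  pgap_qc <- validate_pgap_inputs(dataset$cds, kept)
  groups_by_method <- if (infer) {
    graph <- build_similarity_graph(kept, min_score = min_score)
    list(rbh = infer_rbh_groups(graph), mcl = infer_mcl_groups(graph))
  } else {
    dataset$groups
  }
  species <- sort(unique(dataset$proteins$species))
  records <- map_factors_to_groups(dataset$inventory, groups_by_method,
                                   target_species = species)
  ev <- evidence_bundle(dataset$architectures, dataset$gene_map,
                        groups_by_method, dataset$expression, w = w)
  assignments <- do.call(rbind, lapply(records, integrate_evidence,
                                       evidence = ev,
                                       speciesA = species[1L],
                                       speciesB = species[2L]))
  spB <- species[2L]
  categories <- vapply(records, function(r) {
    nA <- length(unique(c(unname(r$baits[names(r$baits) == species[1L]]),
                          r$consensus_sets[[species[1L]]])))
    nB <- length(r$consensus_sets[[spB]])
    categorize_factor(nA, nB,
                      found_in_any_plant = nA + nB > 0,
                      found_in_B = nB > 0,
                      has_nonplant_bait = any(!(names(r$baits) %in% species)))
  }, "")
  names(categories) <- vapply(records, `[[`, "", "factor_name")
  stats <- list(
    n_factors = length(records),
    overlap = overlap_statistic(records),
    missing = missing_statistic(records, spB),
    multiplicity = multiplicity_statistic(records, spB),
    counts_A = orthologue_counts(records, species[1L]),
    counts_B = orthologue_counts(records, spB))
  truth <- dataset$truth
  if (!is.null(truth)) {
    stats$pair_recovery <- pair_recovery(truth, groups_by_method)
    stats$assignment_precision <- assignment_precision(truth, assignments)
  }
  structure(list(qc = qc, pgap_qc = pgap_qc, groups = groups_by_method,
                 records = records, stats = stats,
                 assignments = assignments, categories = categories,
                 truth = truth),
            class = "pipeline_result")
}

#' Fraction of planted cross-species pairs recovered by the consensus
#'
#' A planted pair (a, b) counts as recovered when b is a group-mate of a
#' under at least one method.
#'
#' @param truth Truth table of a `sim_dataset`.
#' @param groups_by_method Named list of [orthology_groups()].
#' @return Fraction in `[0, 1]`.
#' @export
pair_recovery <- function(truth, groups_by_method) {
  pairs <- truth$pairs
  if (nrow(pairs) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    any(vapply(groups_by_method, function(og) {
      pairs$geneB[i] %in% group_mates(og, pairs$geneA[i])
    }, TRUE))
  }, TRUE)
  mean(hit)
}

#' Precision of confidently flagged assignment rows against planted truth
#'
#' Rows flagged `consensus` or `+` are checked against the planted pair list
#' (rows from split-gene events are checked against the planted fission
#' partners).
#'
#' @param truth Truth table of a `sim_dataset`.
#' @param assignments Assignment table from the pipeline.
#' @return Fraction of flagged rows that are planted pairs, or `NA` when no
#'   row is flagged.
#' @export
assignment_precision <- function(truth, assignments) {
  conf <- assignments[assignments$evidence %in% c("consensus", "+"), ,
                      drop = FALSE]
  if (nrow(conf) == 0L) return(NA_real_)
  key <- paste(truth$pairs$geneA, truth$pairs$geneB)
  mean(paste(conf$geneA, conf$geneB) %in% key)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$stats
  cat("pipeline_result:", s$n_factors, "factors\n")
  cat(sprintf("  overlap %.3f | missing %.3f | multiplicity %.3f\n",
              s$overlap, s$missing, s$multiplicity))
  if (!is.null(s$pair_recovery)) {
    cat(sprintf("  planted-pair recovery %.3f | flagged precision %.3f\n",
                s$pair_recovery, s$assignment_precision))
  }
  invisible(x)
}
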