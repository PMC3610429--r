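# Windowed shared-synteny score: for a candidate cross-species gene pair,
# count orthologues among the seven genes up- and downstream of each gene
# (window half-width configurable), per prediction method, and accumulate
# into a final syntenic score used to claim co-orthologue pairings.

#' Flanking-gene window
#'
#' Up to `w` genes of lower rank plus up to `w` of higher rank on the same
#' chromosome as `gene`, in rank order, focal gene excluded; truncated at
#' chromosome ends.
#'
#' @param gene Focal gene id.
#' @param gmap A [gene_map()].
#' @param w Window half-width in genes (default 7).
#' @return Character vector of gene ids.
#' @export
synteny_window <- function(gene, gmap, w = 7) {
  stopifnot(w >= 1)
  df <- as.data.frame(gmap)
  i <- match(gene, df$gene_id)
  if (is.na(i)) stop("gene ", gene, " absent from gene map")
  cc <- df[df$species == df$species[i] & df$chromosome == df$chromosome[i], ,
           drop = FALSE]
  r0 <- df$rank[i]
  cc <- cc[cc$rank >= r0 - w & cc$rank <= r0 + w & cc$rank != r0, ,
           drop = FALSE]
  cc$gene_id[order(cc$rank)]
}

# directional count: window-A genes with >= 1 group-mate inside window B
directional_count <- function(winA, winB, og) {
  sum(vapply(winA, function(g) {
    any(group_mates(og, g) %in% winB)
  }, TRUE))
}

#' Windowed shared-synteny score of a candidate gene pair
#'
#' Per method, the directional count from A to B is the number of genes in
#' `geneA`'s window having at least one group-mate under that method inside
#' `geneB`'s window (with `count_unit = "pairs"`, the number of such
#' window-gene pairs). Because chromosome ends truncate windows, the two
#' directions can differ; the symmetric per-method count is their minimum.
#' The total accumulates the per-method counts.
#'
#' @param geneA,geneB The candidate pair (different species).
#' @param gmap A [gene_map()] covering both species.
#' @param groups_by_method Named list of [orthology_groups()].
#' @param w Window half-width (default 7).
#' @param count_unit `"genes"` (default) or `"pairs"`.
#' @return A `synteny_score`: list with `pair`, `per_method` (symmetrized),
#'   `directional` (method -> c(ab, ba)) and `total`.
#' @export
syntenic_score <- function(geneA, geneB, gmap, groups_by_method, w = 7,
                           count_unit = c("genes", "pairs")) {
  count_unit <- match.arg(count_unit)
  if (is.null(names(groups_by_method))) {
    names(groups_by_method) <- vapply(groups_by_method, `[[`, "", "method_id")
  }
  winA <- synteny_window(geneA, gmap, w)
  winB <- synteny_window(geneB, gmap, w)
  per <- lapply(groups_by_method, function(og) {
    if (count_unit == "genes") {
      ab <- directional_count(winA, winB, og)
      ba <- directional_count(winB, winA, og)
    } else {
      ab <- sum(vapply(winA, function(g) {
        sum(group_mates(og, g) %in% winB)
      }, 0))
      ba <- sum(vapply(winB, function(g) {
        sum(group_mates(og, g) %in% winA)
      }, 0))
    }
    c(ab = ab, ba = ba)
  })
  sym <- vapply(per, min, 0)
  structure(list(pair = c(geneA = geneA, geneB = geneB),
                 per_method = sym, directional = per,
                 total = sum(sym)),
            class = "synteny_score")
}

#' @export
print.synteny_score <- function(x, ...) {
  cat("synteny_score ", x$pair[["geneA"]], " ~ ", x$pair[["geneB"]], ": ",
      paste(names(x$per_method), x$per_method, sep = "=", collapse = ", "),
      "; total ", x$total, "\n", sep = "")
  invisible(x)
}

#' Score all candidate pairs of a factor
#'
#' @param candidates data.frame with columns `geneA`, `geneB`.
#' @param gmap,groups_by_method,w,count_unit Passed to [syntenic_score()].
#' @return data.frame `geneA`, `geneB`, one `score_<method>` column per
#'   method, and `total`.
#' @export
score_candidates <- function(candidates, gmap, groups_by_method, w = 7,
                             count_unit = "genes") {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    s <- syntenic_score(candidates$geneA[i], candidates$geneB[i], gmap,
                        groups_by_method, w, count_unit)
    out <- data.frame(geneA = candidates$geneA[i], geneB = candidates$geneB[i])
    for (m in names(s$per_method)) out[[paste0("score_", m)]] <- s$per_method[[m]]
    out$total <- s$total
    out
  })
  do.call(rbind, rows)
}

#' Synteny-based co-orthologue pairing
#'
#' Greedy maximum-total-score matching over the factor's candidate pairs
#' (score-descending, lexicographic tie-break on (geneA, geneB); each gene
#' used at most once). A matched pair is flagged `+` only when its total
#' score is positive and strictly exceeds the total of every competing
#' candidate pair sharing either endpoint; ties leave the pair unflagged.
#' With `method = "optimal"` an exhaustive maximum-weight matching replaces
#' the greedy pass.
#'
#' @param scored data.frame from [score_candidates()] (needs `geneA`,
#'   `geneB`, `total`).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return data.frame `geneA`, `geneB`, `total`, `flag` (logical: received
#'   `+`), containing only matched pairs.
#' @export
assign_by_synteny <- function(scored, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (nrow(scored) == 0L) {
    return(data.frame(geneA = character(0), geneB = character(0),
                      total = numeric(0), flag = logical(0)))
  }
  if (method == "greedy") {
    ord <- order(-scored$total, scored$geneA, scored$geneB)
    usedA <- character(0); usedB <- character(0); pick <- integer(0)
    for (i in ord) {
      if (scored$geneA[i] %in% usedA || scored$geneB[i] %in% usedB) next
      pick <- c(pick, i)
      usedA <- c(usedA, scored$geneA[i]); usedB <- c(usedB, scored$geneB[i])
    }
  } else {
    pick <- optimal_matching(scored)
  }
  out <- scored[pick, c("geneA", "geneB", "total"), drop = FALSE]
  out$flag <- vapply(seq_len(nrow(out)), function(k) {
    competing <- scored$geneA == out$geneA[k] | scored$geneB == out$geneB[k]
    competing[which(scored$geneA == out$geneA[k] &
                    scored$geneB == out$geneB[k])] <- FALSE
    out$total[k] > 0 &&
      (!any(competing) || out$total[k] > max(scored$total[competing]))
  }, TRUE)
  rownames(out) <- NULL
  out
}

# exhaustive maximum-weight matching over candidate rows (desk-scale sizes)
optimal_matching <- function(scored) {
  n <- nrow(scored)
  best <- list(w = -Inf, pick = integer(0))
  recurse <- function(i, pick, usedA, usedB, w) {
    if (i > n) {
      if (w > best$w ||
          (w == best$w && length(pick) > length(best$pick))) {
        best <<- list(w = w, pick = pick)
      }
      return(invisible())
    }
    recurse(i + 1L, pick, usedA, usedB, w)
    if (!(scored$geneA[i] %in% usedA) && !(scored$geneB[i] %in% usedB)) {
      recurse(i + 1L, c(pick, i), c(usedA, scored$geneA[i]),
              c(usedB, scored$geneB[i]), w + scored$total[i])
    }
  }
  recurse(1L, integer(0), character(0), character(0), 0)
  best$pick
}
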