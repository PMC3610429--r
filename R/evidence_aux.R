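# Auxiliary evidence: through-origin protein-length fit across species,
# and expression-profile correlation over shared tissues.

#' Through-origin least-squares length fit
#'
#' Fits `y = a * x` to cross-species protein-length pairs by least squares;
#' the closed form is `a = sum(x*y) / sum(x^2)`. No intercept is fitted: the
#' model asserts proportionality of orthologue lengths.
#'
#' @param x,y Positive protein lengths (amino acids) of paired orthologues.
#' @return A `length_fit`: list with slope `a`, `n` and `residual_rms`.
#' @export
length_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (sum(x^2) == 0) stop("degenerate fit: sum(x^2) is zero")
  a <- sum(x * y) / sum(x^2)
  structure(list(a = a, n = length(x),
                 residual_rms = sqrt(mean((y - a * x)^2))),
            class = "length_fit")
}

#' @export
print.length_fit <- function(x, ...) {
  cat(sprintf("length_fit: y = %.4f * x  (n = %d, residual RMS = %.2f aa)\n",
              x$a, x$n, x$residual_rms))
  invisible(x)
}

#' Expression-profile correlation of a candidate orthologue pair
#'
#' Pearson correlation of `log2(1 + scale * value)` across the tissues shared
#' by the two profiles after label mapping (canonical labels `LE`, `F&P`,
#' `S&S`, `RO`). The platform scale factor is applied before the log. Fewer
#' than 3 shared tissues make the correlation undefined: `NA` is returned and
#' the pair is reported as missing evidence.
#'
#' @param profileA,profileB Named numeric vectors (names = tissue labels).
#' @param tissue_map Optional named vector mapping profile labels to
#'   canonical labels.
#' @param platform_scales Numeric length 2: scale for profile A and B (the
#'   conventional factors are 100 for microarray, 1000 for RNA-seq counts).
#' @param log_transform Apply the `log2(1 + .)` transform (default TRUE).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
expression_correlation <- function(profileA, profileB, tissue_map = NULL,
                                   platform_scales = c(100, 1000),
                                   log_transform = TRUE,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  relabel <- function(p) {
    if (!is.null(tissue_map)) {
      hit <- names(p) %in% names(tissue_map)
      names(p)[hit] <- tissue_map[names(p)[hit]]
    }
    p
  }
  profileA <- relabel(profileA); profileB <- relabel(profileB)
  shared <- intersect(names(profileA), names(profileB))
  if (length(shared) < 3L) {
    message("fewer than 3 shared tissues: correlation undefined")
    return(NA_real_)
  }
  va <- platform_scales[1L] * profileA[shared]
  vb <- platform_scales[2L] * profileB[shared]
  if (log_transform) { va <- log2(1 + va); vb <- log2(1 + vb) }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  cor(va, vb, method = method)
}

#' Expression-based pairing of still-ambiguous candidates
#'
#' Among a factor's remaining candidate pairs, the unique pair with the
#' maximum correlation receives the `#` flag, provided its correlation
#' reaches `r_min` and its margin over the runner-up is at least `margin`.
#' Ties or thin margins flag nothing: expression is supporting evidence, not
#' a tie-breaker.
#'
#' @param candidates data.frame with `geneA`, `geneB`.
#' @param correlations Numeric vector aligned with `candidates` rows
#'   (`NA` = evidence missing).
#' @param r_min Minimum correlation (default 0.8).
#' @param margin Required lead over the runner-up (default 0.1).
#' @return `candidates` with columns `r` and `flag` (logical: received `#`).
#' @export
assign_by_expression <- function(candidates, correlations, r_min = 0.8,
                                 margin = 0.1) {
  out <- candidates
  out$r <- correlations
  out$flag <- FALSE
  ok <- which(!is.na(correlations))
  if (length(ok) > 0L) {
    best <- ok[which.max(correlations[ok])]
    runner <- if (length(ok) > 1L) {
      max(correlations[setdiff(ok, best)])
    } else {
      -Inf
    }
    if (correlations[best] >= r_min &&
        correlations[best] - runner >= margin &&
        sum(correlations[ok] == correlations[best]) == 1L) {
      out$flag[best] <- TRUE
    }
  }
  out
}
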