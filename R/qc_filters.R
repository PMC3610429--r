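# Input-eligibility and sequence-quality filters applied before orthology
# inference. Violations are always reported, never silently dropped.

#' Construct a QC report
#'
#' @param kept Character vector of kept gene ids.
#' @param removed data.frame with columns `gene_id`, `reason`.
#' @param count_mismatch Logical; TRUE when the CDS and protein files do not
#'   contain the same number of entries.
#' @return A `qc_report` object.
#' @export
qc_report <- function(kept, removed, count_mismatch = FALSE) {
  stopifnot(!any(kept %in% removed$gene_id))
  structure(list(kept = kept, removed = removed,
                 count_mismatch = count_mismatch),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: ", length(x$kept), " kept, ", nrow(x$removed), " removed",
      if (x$count_mismatch) " [count mismatch]", "\n", sep = "")
  if (nrow(x$removed) > 0) {
    tab <- table(x$removed$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- rbind(
    data.frame(gene_id = report$kept,
               status = rep("kept", length(report$kept)),
               reason = rep("", length(report$kept))),
    data.frame(gene_id = report$removed$gene_id,
               status = rep("removed", nrow(report$removed)),
               reason = report$removed$reason))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

removal_df <- function(gene_id = character(0), reason = character(0)) {
  data.frame(gene_id = gene_id, reason = reason, stringsAsFactors = FALSE)
}

#' Validate CDS/protein input eligibility
#'
#' An entry is eligible when its CDS length stands in a 3:1 relation to its
#' protein length: `cds = 3*L` or, tolerating an annotated terminal stop
#' codon, `cds = 3*(L+1)` (with `strict = TRUE` only `3*L` passes). The id
#' must be unique in both files and the entry must have exactly one
#' CDS-protein pairing. A global `count_mismatch` flag is raised when the two
#' files differ in entry totals. Nothing errors: every violation is reported.
#'
#' @param cds_records data.frame with `id` and either `seq` (nucleotides) or
#'   `cds_length`.
#' @param protein_records data.frame with `id`, `seq`.
#' @param strict Require exactly `cds = 3*L` (default FALSE).
#' @return A [qc_report()].
#' @export
validate_pgap_inputs <- function(cds_records, protein_records, strict = FALSE) {
  cds_len <- if ("cds_length" %in% names(cds_records)) {
    as.integer(cds_records$cds_length)
  } else {
    nchar(cds_records$seq)
  }
  names(cds_len) <- cds_records$id
  ids <- protein_records$id
  L <- nchar(protein_records$seq)
  removed <- removal_df()
  dup <- unique(c(ids[duplicated(ids)],
                  cds_records$id[duplicated(cds_records$id)]))
  keep <- logical(length(ids))
  reasons <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% dup) {
      reasons[i] <- "duplicate_id"
    } else if (!(id %in% names(cds_len))) {
      reasons[i] <- "cds_mismatch"
    } else {
      ok_len <- cds_len[[id]] == 3L * L[i] ||
        (!strict && cds_len[[id]] == 3L * (L[i] + 1L))
      if (ok_len) keep[i] <- TRUE else reasons[i] <- "cds_mismatch"
    }
  }
  # a duplicate id is reported once per occurrence
  removed <- removal_df(ids[!keep], reasons[!keep])
  qc_report(kept = ids[keep], removed = removed,
            count_mismatch = length(cds_len) != length(ids))
}

#' Sequence-quality filter
#'
#' Removes proteins shorter than 10 residues or with more than 20% stop
#' symbols (`*`). Both thresholds are strict inequalities, so a length-10
#' protein and one with exactly 20% stops are kept. A zero-length sequence is
#' removed as `short_protein` (its stop fraction is undefined).
#'
#' @param protein_records data.frame with `id`, `seq`.
#' @param min_length Minimum length kept (default 10).
#' @param max_stop_fraction Maximum tolerated stop fraction (default 0.20).
#' @return A [qc_report()].
#' @export
filter_quality <- function(protein_records, min_length = 10,
                           max_stop_fraction = 0.20) {
  L <- nchar(protein_records$seq)
  stops <- nchar(protein_records$seq) -
    nchar(gsub("*", "", protein_records$seq, fixed = TRUE))
  short <- L < min_length
  stopfrac <- ifelse(L > 0, stops / L, 0)
  stoppy <- !short & stopfrac > max_stop_fraction
  reason <- ifelse(short, "short_protein",
                   ifelse(stoppy, "high_stop_fraction", ""))
  removed_idx <- short | stoppy
  for (i in which(removed_idx)) {
    message("removed ", protein_records$id[i], ": ", reason[i])
  }
  qc_report(kept = protein_records$id[!removed_idx],
            removed = removal_df(protein_records$id[removed_idx],
                                 reason[removed_idx]))
}
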