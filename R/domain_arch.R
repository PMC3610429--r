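# Ordered domain-architecture construction and comparison, the
# architecture-agreement statistic, and split-gene (fusion/fission)
# detection: one gene in species 1 whose architecture equals the
# concatenation of two adjacent genes' architectures in species 2.

#' Default domain-equivalence map
#'
#' Clan-like equivalence classes for domain names. The bundled map treats the
#' two zinc-finger RING variants `zf-RING_2` and `zf-C3HC4_2` as one class;
#' it ships as an editable TSV under `extdata`. Unmapped names map to
#' themselves.
#'
#' @param path Optional TSV with columns `domain_name`, `class`.
#' @return Named character vector: domain_name -> class label.
#' @export
default_equivalence_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domain_equivalence.tsv",
                        package = "coortho", mustWork = TRUE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$class, df$domain_name)
}

map_domain_classes <- function(domains, eqmap) {
  out <- unname(eqmap[domains])
  out[is.na(out)] <- domains[is.na(out)]
  out
}

#' Build the ordered domain architecture of one gene
#'
#' Hits are ordered N to C by envelope start. Among two hits overlapping by
#' more than 50% of the shorter hit, only the higher-scoring one survives
#' (ties: the hit with the lower start). Repeated domains are kept distinct,
#' so three consecutive WD40 hits yield `c("WD40","WD40","WD40")`.
#'
#' @param hits data.frame of domain hits for one gene (`domain_name`,
#'   `start`, `end`, `score`).
#' @return An `architecture`: character vector of domain names in N->C order
#'   (possibly empty).
#' @export
build_architecture <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(character(0))
  ord <- order(-hits$score, hits$start)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j]) + 1L
      if (ov > 0.5 * shorter) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  kept <- kept[order(hits$start[kept])]
  hits$domain_name[kept]
}

#' Build architectures for all genes in a domain table
#'
#' @param domain_table data.frame as from [read_domain_table()].
#' @param gene_ids Optional gene universe; genes without hits get empty
#'   architectures.
#' @return Named list of architectures.
#' @export
build_architectures <- function(domain_table, gene_ids = NULL) {
  archs <- lapply(split(domain_table, domain_table$gene_id), build_architecture)
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, names(archs))
    archs <- c(archs, setNames(rep(list(character(0)), length(missing)), missing))
    archs <- archs[gene_ids]
  }
  archs
}

#' Compare two architectures under an equivalence map
#'
#' Architectures are equal when their mapped domain-class sequences are
#' identical as ordered lists. Domain lengths are ignored: a domain 20 amino
#' acids shorter in one orthologue still counts as the same domain.
#'
#' @param archA,archB Character vectors of domain names.
#' @param eqmap Equivalence map (see [default_equivalence_map()]).
#' @return TRUE or FALSE.
#' @export
architectures_equal <- function(archA, archB, eqmap = default_equivalence_map()) {
  identical(map_domain_classes(archA, eqmap), map_domain_classes(archB, eqmap))
}

#' Cross-species architecture-agreement statistic
#'
#' Fraction of proteins of the two species, among those appearing in groups,
#' that have at least one cross-species group-mate with an equal architecture.
#'
#' @param groups An [orthology_groups()] object.
#' @param architectures Named list of architectures (gene -> architecture).
#' @param speciesA,speciesB The two species compared.
#' @param eqmap Equivalence map.
#' @return Fraction in `[0, 1]`.
#' @export
agreement_statistic <- function(groups, architectures, speciesA, speciesB,
                                eqmap = default_equivalence_map()) {
  num <- 0L; den <- 0L
  for (g in groups$groups) {
    in_pair <- names(g) %in% c(speciesA, speciesB)
    for (k in which(in_pair)) {
      den <- den + 1L
      other <- g[names(g) %in% c(speciesA, speciesB) & names(g) != names(g)[k]]
      hit <- any(vapply(other, function(mate) {
        architectures_equal(architectures[[g[[k]]]], architectures[[mate]],
                            eqmap)
      }, TRUE))
      if (isTRUE(hit)) num <- num + 1L
    }
  }
  if (den == 0L) stop("no proteins of the two species appear in groups")
  num / den
}

#' Detect split-gene (fusion/fission) partners
#'
#' Finds ordered pairs of genes in `target_species`, lying on one chromosome
#' within `max_gap` ranks of each other, whose concatenated architectures (in
#' either order) equal the architecture of `gene_x` under the equivalence
#' map. This is the situation where a single gene in one species corresponds
#' to two adjacent annotations in the other.
#'
#' @param gene_x Query gene id (in the other species).
#' @param target_species Species searched for partner pairs.
#' @param gmap A [gene_map()].
#' @param architectures Named list of architectures.
#' @param eqmap Equivalence map.
#' @param max_gap Maximum rank distance between partners (default 1,
#'   i.e. adjacent annotations).
#' @return data.frame with columns `gene1`, `gene2` (`gene1` at the lower
#'   rank); zero rows if none. A query without an architecture yields zero
#'   rows with a warning.
#' @export
detect_fusion <- function(gene_x, target_species, gmap, architectures,
                          eqmap = default_equivalence_map(), max_gap = 1) {
  ax <- architectures[[gene_x]]
  if (is.null(ax) || length(ax) == 0L) {
    warning("gene ", gene_x, " has no architecture")
    return(data.frame(gene1 = character(0), gene2 = character(0)))
  }
  ax <- map_domain_classes(ax, eqmap)
  sub <- as.data.frame(gmap)
  sub <- sub[sub$species == target_species, , drop = FALSE]
  g1 <- character(0); g2 <- character(0)
  for (chr in unique(sub$chromosome)) {
    cc <- sub[sub$chromosome == chr, , drop = FALSE]
    cc <- cc[order(cc$rank), , drop = FALSE]
    n <- nrow(cc)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):min(n, i + max_gap)) {
        a1 <- map_domain_classes(architectures[[cc$gene_id[i]]] %||% character(0), eqmap)
        a2 <- map_domain_classes(architectures[[cc$gene_id[j]]] %||% character(0), eqmap)
        if (length(a1) == 0L && length(a2) == 0L) next
        if (identical(c(a1, a2), ax) || identical(c(a2, a1), ax)) {
          g1 <- c(g1, cc$gene_id[i]); g2 <- c(g2, cc$gene_id[j])
        }
      }
    }
  }
  data.frame(gene1 = g1, gene2 = g2, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
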