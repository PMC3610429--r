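# Built-in stand-ins for the two external orthogroup engines so the pipeline
# is end-to-end runnable at desk scale:
#   method "rbh" - reciprocal-best-hit seeds + inparalog grouping
#   method "mcl" - Markov flow clustering on the similarity graph
# Both are explicitly surrogates; externally produced group files can be
# substituted anywhere an orthology_groups object is accepted.

#' Alignment scoring configuration
#'
#' Fixed, versioned defaults for the Smith-Waterman similarity surrogate:
#' BLOSUM62 (as bundled with Biostrings), gap open 10, gap extend 1.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings.
#' @param gap_open Gap opening cost (positive).
#' @param gap_extend Gap extension cost (positive).
#' @return A list of class `aa_scoring`.
#' @export
aa_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  structure(list(matrix_name = matrix, submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "aa_scoring")
}

# raw Smith-Waterman local scores of many patterns against one subject
sw_scores_raw <- function(patterns, subject, scoring) {
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    type = "local",
    substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend,
    scoreOnly = TRUE))
}

#' Local-alignment similarity of two protein sequences
#'
#' Smith-Waterman local alignment score, normalized by the length of the
#' shorter sequence and clamped at zero (a local alignment with no positive-
#' scoring stretch scores 0). Symmetric by construction.
#'
#' @param seqA,seqB Amino-acid strings (`*` permitted).
#' @param scoring An [aa_scoring()] configuration.
#' @return A single non-negative similarity score.
#' @export
score_pair <- function(seqA, seqB, scoring = aa_scoring()) {
  if (nchar(seqA) == 0L || nchar(seqB) == 0L) {
    warning("empty sequence; score 0")
    return(0)
  }
  s <- sw_scores_raw(seqA, seqB, scoring)
  max(0, s) / min(nchar(seqA), nchar(seqB))
}

#' Build the all-vs-all similarity graph
#'
#' Aligns every pair of proteins (within and across species) and keeps edges
#' whose normalized local-alignment score reaches `min_score`.
#'
#' @param records data.frame with columns `id`, `seq`, `species`.
#' @param scoring An [aa_scoring()].
#' @param min_score Minimum normalized score for an edge (default 1).
#' @return A `similarity_graph`: list with `nodes` (data.frame `gene_id`,
#'   `species`) and `edges` (data.frame `geneA`, `geneB`, `score`).
#' @export
build_similarity_graph <- function(records, scoring = aa_scoring(),
                                   min_score = 1) {
  stopifnot(all(c("id", "seq", "species") %in% names(records)))
  n <- nrow(records)
  ea <- eb <- character(0); sc <- numeric(0)
  if (n >= 2L) {
    len <- nchar(records$seq)
    for (j in 2:n) {
      raw <- sw_scores_raw(records$seq[1:(j - 1L)], records$seq[j], scoring)
      norm <- pmax(0, raw) / pmin(len[1:(j - 1L)], len[j])
      keep <- which(norm >= min_score)
      if (length(keep)) {
        ea <- c(ea, records$id[keep])
        eb <- c(eb, rep(records$id[j], length(keep)))
        sc <- c(sc, norm[keep])
      }
    }
  }
  similarity_graph(
    nodes = data.frame(gene_id = records$id, species = records$species,
                       stringsAsFactors = FALSE),
    edges = data.frame(geneA = ea, geneB = eb, score = sc,
                       stringsAsFactors = FALSE))
}

#' Construct a similarity graph from node and edge tables
#'
#' @param nodes data.frame with `gene_id`, `species`.
#' @param edges data.frame with `geneA`, `geneB`, `score` (undirected).
#' @return A `similarity_graph` object.
#' @export
similarity_graph <- function(nodes, edges) {
  stopifnot(!anyDuplicated(nodes$gene_id),
            all(edges$geneA %in% nodes$gene_id),
            all(edges$geneB %in% nodes$gene_id))
  if (any(edges$geneA == edges$geneB)) stop("self-edges are not allowed")
  if (any(!is.finite(edges$score)) || any(edges$score < 0)) {
    stop("edge scores must be finite and non-negative")
  }
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph: ", nrow(x$nodes), " genes (",
      length(unique(x$nodes$species)), " species), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# dense symmetric score matrix keyed by gene id
graph_matrix <- function(graph) {
  ids <- graph$nodes$gene_id
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$geneA, ids)
    ib <- match(graph$edges$geneB, ids)
    S[cbind(ia, ib)] <- graph$edges$score
    S[cbind(ib, ia)] <- graph$edges$score
  }
  S
}

#' Reciprocal-best-hit orthogroups with inparalog grouping
#'
#' Seed orthologue pairs are mutually best-scoring cross-species pairs
#' (positive score; ties broken lexicographically on (species, gene_id)).
#' Each seed pair recruits inparalogs: same-species genes whose score to the
#' seed member of their species is at least the seed pair's score.
#' Overlapping seed clusters are merged transitively.
#'
#' @param graph A `similarity_graph` with at least two species.
#' @return An [orthology_groups()] object, method id `"rbh"`.
#' @export
infer_rbh_groups <- function(graph) {
  sp <- graph$nodes$species
  if (length(unique(sp)) < 2L) stop("need >= 2 species")
  ids <- graph$nodes$gene_id
  ord <- order(sp, ids)             # lexicographic tie-break order
  S <- graph_matrix(graph)[ord, ord, drop = FALSE]
  sp <- sp[ord]; ids <- ids[ord]
  n <- length(ids)
  # best cross-species hit of gene i in species t (first index wins ties)
  best_hit <- function(i, t) {
    cand <- which(sp == t)
    s <- S[i, cand]
    if (all(s <= 0)) return(NA_integer_)
    cand[which.max(s)]
  }
  seeds <- list()
  species_list <- unique(sp)
  for (i in seq_len(n)) {
    for (t in species_list) {
      if (t <= sp[i]) next             # each unordered species pair once
      j <- best_hit(i, t)
      if (!is.na(j) && identical(best_hit(j, sp[i]), i)) {
        seeds[[length(seeds) + 1L]] <- c(i, j)
      }
    }
  }
  parent <- seq_len(n)
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unionp <- function(a, b) { ra <- findp(a); rb <- findp(b); if (ra != rb) parent[rb] <<- ra }
  clustered <- logical(n)
  for (seed in seeds) {
    i <- seed[1L]; j <- seed[2L]
    s0 <- S[i, j]
    members <- c(i, j,
                 which(sp == sp[i] & S[, i] >= s0 & seq_len(n) != i),
                 which(sp == sp[j] & S[, j] >= s0 & seq_len(n) != j))
    clustered[members] <- TRUE
    for (m in members[-1L]) unionp(members[1L], m)
  }
  roots <- vapply(seq_len(n), findp, 1L)
  keep <- which(clustered)
  groups <- lapply(split(keep, roots[keep]), function(idx) {
    idx <- idx[order(sp[idx], ids[idx])]
    setNames(ids[idx], sp[idx])
  })
  orthology_groups("rbh", unname(groups))
}

#' Markov-flow (MCL-style) orthogroups
#'
#' Builds a column-stochastic matrix from the similarity graph (self-loops
#' weighted by each gene's strongest incident edge, 1 for isolated genes,
#' which damps the period-2 oscillation of pure expansion), then alternates
#' expansion (matrix squaring) and inflation (elementwise power and column
#' renormalization) until the iteration is stationary. Groups are the
#' connected components of the thresholded limit matrix; singletons are
#' dropped. Column-stochasticity is asserted after every iteration.
#'
#' @param graph A `similarity_graph`.
#' @param inflation Inflation exponent, > 1 (default 1.5).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the max entrywise change (default 1e-6).
#' @param threshold Entries above this in the limit define cluster edges
#'   (default 1e-8).
#' @return An [orthology_groups()] object, method id `"mcl"`.
#' @export
infer_mcl_groups <- function(graph, inflation = 1.5, max_iter = 100,
                             tol = 1e-6, threshold = 1e-8) {
  stopifnot(inflation > 1)
  ids <- graph$nodes$gene_id
  sp <- setNames(graph$nodes$species, ids)
  S <- graph_matrix(graph)
  loop <- apply(S, 2, max)
  diag(S) <- ifelse(loop > 0, loop, 1)
  M <- sweep(S, 2, colSums(S), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion
    M2 <- M2 ^ inflation             # inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    stopifnot(all(abs(colSums(M2) - 1) <= 1e-9))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  if (delta >= tol) warning("MCL did not converge in ", max_iter,
                            " iterations; returning current partition")
  A <- (M > threshold) | (t(M) > threshold)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- lapply(split(ids, comp), function(members) {
    members <- sort(members)
    setNames(members, unname(sp[members]))
  })
  orthology_groups("mcl", unname(groups))
}
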