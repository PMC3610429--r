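# Independent oracles and fixture builders used across the suite. Each
# oracle re-derives the quantity from its definition, sharing no code with
# the implementation it checks.

# Affine-gap Smith-Waterman (Gotoh), gap of length L costs open + L * extend.
sw_oracle <- function(a, b, submat, open = 10, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in A (move along B)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in B
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (open + extend),
                             E[i + 1, j] - extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (open + extend),
                             F[i, j + 1] - extend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + submat[A[i], B[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# Plain union-find over species|gene tokens; groups of size >= 2.
union_find_oracle <- function(pairs) {
  verts <- unique(c(pairs[[1]], pairs[[2]]))
  parent <- setNames(verts, verts)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[[1]][k]); rb <- find(pairs[[2]][k])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(verts, find, "")
  comps <- split(verts, roots)
  comps <- comps[vapply(comps, length, 1L) >= 2L]
  lapply(unname(comps), sort)
}

# canonical form of an orthology_groups object for set comparison
canon_groups <- function(og) {
  gs <- lapply(og$groups, function(g) sort(paste(names(g), g, sep = "|")))
  gs[order(vapply(gs, `[`, "", 1L))]
}

# Recursive elimination for architecture building, straight from the rule:
# the best-scoring hit (ties: lower start) always survives; every hit
# overlapping it by > 50% of the shorter is removed; recurse on the rest.
arch_oracle <- function(hits) {
  survivors <- integer(0)
  pool <- seq_len(nrow(hits))
  conflicts <- function(i, j) {
    ov <- min(hits$end[i], hits$end[j]) -
      max(hits$start[i], hits$start[j]) + 1
    shorter <- min(hits$end[i] - hits$start[i],
                   hits$end[j] - hits$start[j]) + 1
    ov > 0.5 * shorter
  }
  while (length(pool) > 0) {
    top <- pool[order(-hits$score[pool], hits$start[pool])][1]
    survivors <- c(survivors, top)
    pool <- setdiff(pool, top)
    pool <- pool[!vapply(pool, conflicts, TRUE, j = top)]
  }
  hits$domain_name[survivors[order(hits$start[survivors])]]
}

# Brute-force windowed synteny: scan every (window-A gene, window-B gene)
# pair and test co-membership by searching the raw group lists.
synteny_oracle <- function(geneA, geneB, gmap_df, groups_list, w) {
  win <- function(g) {
    i <- which(gmap_df$gene_id == g)
    cc <- gmap_df[gmap_df$species == gmap_df$species[i] &
                  gmap_df$chromosome == gmap_df$chromosome[i], ]
    cc$gene_id[abs(cc$rank - gmap_df$rank[i]) <= w &
               cc$gene_id != g]
  }
  same_group <- function(x, y) {
    any(vapply(groups_list, function(g) x %in% g && y %in% g, TRUE))
  }
  wa <- win(geneA); wb <- win(geneB)
  ab <- sum(vapply(wa, function(x) any(vapply(wb, same_group, TRUE, x = x)), TRUE))
  ba <- sum(vapply(wb, function(x) any(vapply(wa, same_group, TRUE, x = x)), TRUE))
  min(ab, ba)
}

# Brute-force RBH + inparalog grouping from the definition.
rbh_oracle <- function(nodes, edges) {
  score <- function(x, y) {
    hit <- (edges$geneA == x & edges$geneB == y) |
           (edges$geneA == y & edges$geneB == x)
    if (any(hit)) edges$score[hit][1] else 0
  }
  sp <- setNames(nodes$species, nodes$gene_id)
  ids <- nodes$gene_id[order(nodes$species, nodes$gene_id)]
  best <- function(x, target) {
    cand <- ids[sp[ids] == target]
    s <- vapply(cand, score, 0, x = x)
    if (all(s <= 0)) NA_character_ else cand[which.max(s)]
  }
  clusters <- list()
  for (x in ids) for (y in ids) {
    if (sp[x] >= sp[y]) next
    if (identical(best(x, sp[y]), y) && identical(best(y, sp[x]), x)) {
      s0 <- score(x, y)
      candx <- ids[sp[ids] == sp[x] & ids != x]
      candy <- ids[sp[ids] == sp[y] & ids != y]
      inx <- candx[vapply(candx, score, 0, y = x) >= s0]
      iny <- candy[vapply(candy, score, 0, y = y) >= s0]
      clusters[[length(clusters) + 1L]] <- unique(c(x, y, inx, iny))
    }
  }
  # transitive merge of overlapping clusters
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        if (length(intersect(clusters[[i]], clusters[[j]])) > 0) {
          clusters[[i]] <- union(clusters[[i]], clusters[[j]])
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  lapply(clusters, function(cl) {
    cl <- sort(cl)
    sort(paste(sp[cl], cl, sep = "|"))
  })
}

# exhaustive best matching weight by enumeration over all pair subsets
matching_weight_oracle <- function(scored) {
  n <- nrow(scored)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (anyDuplicated(scored$geneA[idx]) || anyDuplicated(scored$geneB[idx]))
      next
    best <- max(best, sum(scored$total[idx]))
  }
  best
}

# Fixture: two verbatim-duplicated n-gene genomes plus 1:1 groups under
# both methods (the perfectly conserved synteny scenario).
dup_genome_fixture <- function(n = 30) {
  a <- sprintf("a%02d", seq_len(n)); b <- sprintf("b%02d", seq_len(n))
  gmap <- gene_map(data.frame(
    gene_id = c(a, b),
    species = rep(c("spA", "spB"), each = n),
    chromosome = "chr1", rank = c(seq_len(n), seq_len(n)) - 1L,
    strand = "+"))
  groups <- lapply(seq_len(n), function(i) {
    setNames(c(a[i], b[i]), c("spA", "spB"))
  })
  list(a = a, b = b, gmap = gmap,
       methods = list(m1 = orthology_groups("m1", groups),
                      m2 = orthology_groups("m2", groups)),
       groups_list = lapply(groups, unname))
}
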