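test_that("score_pair is maximal on self, zero without positive alignment, symmetric", {
  s <- "MKLERWFYHNQD"
  self <- score_pair(s, s)
  expect_gt(self, 0)
  set.seed(3)
  for (i in 1:10) {
    other <- random_aa(12)
    expect_lte(score_pair(s, other), self)
    expect_equal(score_pair(s, other), score_pair(other, s))
  }
  expect_equal(score_pair("AAAA", "CCCC"), 0)
  expect_warning(z <- score_pair("", "MKV"), "empty")
  expect_equal(z, 0)
})

test_that("score_pair matches an independent Gotoh DP oracle on random pairs", {
  set.seed(41)
  scoring <- aa_scoring()
  for (i in 1:30) {
    a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
    expect_equal(score_pair(a, b, scoring),
                 max(0, sw_oracle(a, b, scoring$submat)) /
                   min(nchar(a), nchar(b)),
                 tolerance = 1e-12)
  }
})

test_that("RBH groups identical single-gene proteomes and equal-score inparalogs", {
  g1 <- similarity_graph(
    nodes = data.frame(gene_id = c("a1", "b1"), species = c("A", "B")),
    edges = data.frame(geneA = "a1", geneB = "b1", score = 5))
  expect_equal(canon_groups(infer_rbh_groups(g1)), list(c("A|a1", "B|b1")))

  g2 <- similarity_graph(
    nodes = data.frame(gene_id = c("a1", "b1", "b2"),
                       species = c("A", "B", "B")),
    edges = data.frame(geneA = c("a1", "a1", "b1"),
                       geneB = c("b1", "b2", "b2"),
                       score = c(5, 4, 5)))
  expect_equal(canon_groups(infer_rbh_groups(g2)),
               list(c("A|a1", "B|b1", "B|b2")))
})

test_that("RBH equals the brute-force seed+inparalog oracle on small random graphs", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    nodes <- data.frame(gene_id = paste0("g", seq_len(n)),
                        species = sample(c("A", "B"), n, TRUE))
    if (length(unique(nodes$species)) < 2) nodes$species[1:2] <- c("A", "B")
    pairs <- t(combn(nodes$gene_id, 2))
    keep <- runif(nrow(pairs)) < 0.7
    edges <- data.frame(geneA = pairs[keep, 1], geneB = pairs[keep, 2],
                        score = sample(1:8, sum(keep), TRUE))
    got <- canon_groups(infer_rbh_groups(similarity_graph(nodes, edges)))
    want <- rbh_oracle(nodes, edges)
    want <- want[order(vapply(want, `[`, "", 1L))]
    expect_equal(got, want)
  }
})

test_that("MCL: no cross edges gives zero groups; disconnected triangles stay apart", {
  iso <- similarity_graph(
    nodes = data.frame(gene_id = paste0("g", 1:4),
                       species = rep(c("A", "B"), 2)),
    edges = data.frame(geneA = character(0), geneB = character(0),
                       score = numeric(0)))
  expect_length(infer_mcl_groups(iso)$groups, 0L)

  tri <- function(ids) data.frame(geneA = ids[c(1, 1, 2)],
                                  geneB = ids[c(2, 3, 3)], score = 5)
  g <- similarity_graph(
    nodes = data.frame(gene_id = paste0("g", 1:6),
                       species = rep(c("A", "B", "A"), 2)),
    edges = rbind(tri(paste0("g", 1:3)), tri(paste0("g", 4:6))))
  got <- infer_mcl_groups(g)
  expect_length(got$groups, 2L)
  expect_setequal(lengths(got$groups), c(3L, 3L))
})

test_that("MCL groups refine the connected components of the input graph", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    nodes <- data.frame(gene_id = paste0("g", seq_len(n)),
                        species = sample(c("A", "B"), n, TRUE))
    pairs <- t(combn(nodes$gene_id, 2))
    keep <- runif(nrow(pairs)) < 0.35
    edges <- data.frame(geneA = pairs[keep, 1], geneB = pairs[keep, 2],
                        score = runif(sum(keep), 1, 6))
    og <- infer_mcl_groups(similarity_graph(nodes, edges))
    if (nrow(edges) == 0) { expect_length(og$groups, 0L); next }
    comp <- union_find_oracle(data.frame(a = edges$geneA, b = edges$geneB))
    comp_of <- unlist(lapply(seq_along(comp),
                             function(i) setNames(rep(i, length(comp[[i]])),
                                                  comp[[i]])))
    for (grp in og$groups) {
      expect_length(unique(comp_of[unname(grp)]), 1L)
    }
  }
})

test_that("both engines are equivariant under gene relabeling", {
  set.seed(5)
  nodes <- data.frame(gene_id = paste0("g", 1:6),
                      species = rep(c("A", "B"), 3))
  pairs <- t(combn(nodes$gene_id, 2))
  edges <- data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                      score = round(runif(nrow(pairs), 0, 6), 2))
  edges <- edges[edges$score > 2, ]
  g <- similarity_graph(nodes, edges)
  relab <- setNames(paste0("z", 6:1), nodes$gene_id)  # order-reversing
  nodes2 <- transform(nodes, gene_id = unname(relab[gene_id]))
  edges2 <- transform(edges, geneA = unname(relab[geneA]),
                      geneB = unname(relab[geneB]))
  g2 <- similarity_graph(nodes2, edges2)
  relabel_canon <- function(og) {
    gs <- lapply(og$groups, function(grp) {
      sort(paste(names(grp), unname(relab[grp]), sep = "|"))
    })
    gs[order(vapply(gs, `[`, "", 1L))]
  }
  expect_equal(relabel_canon(infer_rbh_groups(g)),
               canon_groups(infer_rbh_groups(g2)))
  expect_equal(relabel_canon(infer_mcl_groups(g)),
               canon_groups(infer_mcl_groups(g2)))
})

test_that("zero-divergence clone proteomes are recovered 1:1 by both engines", {
  cfg <- sim_config(n_ancestral_genes = 25, n_chromosomes = 1,
                    events_A = character(0), events_B = character(0),
                    loss_prob = 0, fission_prob = 0, substitution_rate = 0,
                    rearrangement_ops = 0, n_factors = 10, seed = 99)
  ds <- generate_dataset(cfg)
  graph <- build_similarity_graph(ds$proteins)
  for (og in list(infer_rbh_groups(graph), infer_mcl_groups(graph))) {
    expect_equal(pair_recovery(ds$truth, list(og)), 1.0)
    expect_length(og$groups, 25L)
    expect_true(all(lengths(og$groups) == 2L))
  }
})
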