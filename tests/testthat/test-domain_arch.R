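hitdf <- function(name, start, end, score) {
  data.frame(gene_id = "g", domain_name = name, start = start, end = end,
             score = score, stringsAsFactors = FALSE)
}

test_that("tandem repeats stay distinct and ordered N to C", {
  hits <- hitdf("WD40", c(90, 10, 50), c(120, 40, 80), c(30, 30, 30))
  expect_equal(build_architecture(hits), c("WD40", "WD40", "WD40"))
})

test_that("among heavily overlapping hits only the higher score survives", {
  hits <- hitdf(c("A", "B"), c(10, 10), c(40, 40), c(30, 10))
  expect_equal(build_architecture(hits), "A")
  # equal scores: lower start survives
  tie <- hitdf(c("A", "B"), c(12, 10), c(40, 38), c(20, 20))
  expect_equal(build_architecture(tie), "B")
  # half-overlap boundary: exactly 50% of the shorter is tolerated
  half <- hitdf(c("A", "B"), c(1, 6), c(10, 15), c(30, 10))
  expect_equal(build_architecture(half), c("A", "B"))
})

test_that("architecture construction equals the pairwise fixed-point oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(1:8, 1)
    start <- sample(1:80, n, TRUE)
    hits <- data.frame(gene_id = "g",
                       domain_name = sample(LETTERS[1:5], n, TRUE),
                       start = start,
                       end = start + sample(5:30, n, TRUE),
                       score = sample(seq(5, 60, by = 5), n, TRUE))
    expect_equal(build_architecture(hits), arch_oracle(hits))
  }
})

test_that("architecture equality respects order and the equivalence map", {
  eq <- default_equivalence_map()
  expect_true(architectures_equal("SRP54", "SRP54", eq))
  expect_true(architectures_equal("zf-RING_2", "zf-C3HC4_2", eq))
  expect_false(architectures_equal(c("WD40", "RING"), c("RING", "WD40"), eq))
  expect_false(architectures_equal("WD40", c("WD40", "WD40"), eq))
})

test_that("architecture equality is an equivalence relation", {
  eq <- c(default_equivalence_map(), c(A1 = "cls", A2 = "cls", A3 = "cls"))
  set.seed(13)
  pool <- replicate(12, sample(c("A1", "A2", "A3", "B", "C"),
                               sample(1:3, 1), replace = TRUE),
                    simplify = FALSE)
  for (x in pool) expect_true(architectures_equal(x, x, eq))
  for (i in seq_along(pool)) for (j in seq_along(pool)) {
    expect_equal(architectures_equal(pool[[i]], pool[[j]], eq),
                 architectures_equal(pool[[j]], pool[[i]], eq))
    for (k in seq_along(pool)) {
      if (architectures_equal(pool[[i]], pool[[j]], eq) &&
          architectures_equal(pool[[j]], pool[[k]], eq)) {
        expect_true(architectures_equal(pool[[i]], pool[[k]], eq))
      }
    }
  }
})

test_that("agreement statistic counts proteins with an equal-architecture mate", {
  archs <- list(a1 = "X", t1 = "X",       # agree
                a2 = "Y", t2 = "Z")       # disagree
  og <- orthology_groups("m", list(
    c(at = "a1", sl = "t1"), c(at = "a2", sl = "t2")))
  expect_equal(agreement_statistic(og, archs, "at", "sl"), 0.5)
  # identical duplicated proteomes agree fully
  og2 <- orthology_groups("m", list(c(at = "a1", sl = "t1")))
  expect_equal(agreement_statistic(og2, archs, "at", "sl"), 1.0)
  expect_error(agreement_statistic(og, archs, "xx", "yy"), "no proteins")
})

test_that("one planted architecture change among 10 pairs gives 18/20", {
  archs <- setNames(rep("D1", 20), c(paste0("a", 1:10), paste0("t", 1:10)))
  archs[["t4"]] <- "D9"
  archs <- lapply(archs, identity)
  og <- orthology_groups("m", lapply(1:10, function(i) {
    setNames(c(paste0("a", i), paste0("t", i)), c("at", "sl"))
  }))
  expect_equal(agreement_statistic(og, archs, "at", "sl"), 18 / 20)
})

test_that("split-gene detection finds the adjacent RING + 3xWD40 case", {
  gm <- gene_map(data.frame(
    gene_id = c("Solyc11g005020", "Solyc11g005030", "Solyc11g005040"),
    species = "sl", chromosome = "ch11", rank = 0:2, strand = "+"))
  archs <- list(
    AT1G21651 = c("zf-RING_2", "WD40", "WD40", "WD40"),
    Solyc11g005040 = "zf-C3HC4_2",
    Solyc11g005030 = c("WD40", "WD40", "WD40"),
    Solyc11g005020 = "SecA")
  hit <- detect_fusion("AT1G21651", "sl", gm, archs)
  expect_equal(hit, data.frame(gene1 = "Solyc11g005030",
                               gene2 = "Solyc11g005040"))
  # a length-1 query cannot match any two-gene concatenation
  archs$short <- "zf-RING_2"
  expect_equal(nrow(detect_fusion("short", "sl", gm, archs)), 0L)
  expect_warning(none <- detect_fusion("nothere", "sl", gm, archs), "architecture")
  expect_equal(nrow(none), 0L)
})

test_that("split-gene detection equals the exhaustive concatenation oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    ids <- paste0("t", seq_len(n))
    gm <- gene_map(data.frame(gene_id = ids, species = "sl",
                              chromosome = "c1", rank = seq_len(n) - 1L,
                              strand = "+"))
    archs <- setNames(lapply(seq_len(n), function(i) {
      sample(LETTERS[1:4], sample(1:3, 1), replace = TRUE)
    }), ids)
    i <- sample(n - 1, 1)
    archs$query <- c(archs[[ids[i]]], archs[[ids[i + 1]]])
    got <- detect_fusion("query", "sl", gm, archs)
    # oracle: enumerate every adjacent pair and both concatenation orders
    want <- data.frame(gene1 = character(0), gene2 = character(0))
    for (k in seq_len(n - 1)) {
      for (ord in list(c(k, k + 1), c(k + 1, k))) {
        if (identical(c(archs[[ids[ord[1]]]], archs[[ids[ord[2]]]]),
                      archs$query)) {
          want <- rbind(want, data.frame(gene1 = ids[k], gene2 = ids[k + 1]))
          break
        }
      }
    }
    expect_equal(got, unique(want))
  }
})

test_that("no split genes are reported when architectures are random and distinct", {
  set.seed(29)
  for (rep in 1:10) {
    n <- 8
    ids <- paste0("t", seq_len(n))
    gm <- gene_map(data.frame(gene_id = ids, species = "sl",
                              chromosome = "c1", rank = seq_len(n) - 1L,
                              strand = "+"))
    # distinct single domains per gene; a query that concatenates none of them
    archs <- setNames(lapply(sprintf("D%02d_%d", seq_len(n), rep), identity), ids)
    archs$query <- c("QX", "QY")
    expect_equal(nrow(detect_fusion("query", "sl", gm, archs)), 0L)
  }
})
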