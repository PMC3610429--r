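fig1d_fixture <- function() {
  gm <- gene_map(data.frame(
    gene_id = c("AT1G21650", "AT1G21651",
                "Solyc11g005020", "Solyc11g005030", "Solyc11g005040"),
    species = c("spA", "spA", "spB", "spB", "spB"),
    chromosome = c("c1", "c1", "ch11", "ch11", "ch11"),
    rank = c(0L, 1L, 0L, 1L, 2L), strand = "+"))
  archs <- list(
    AT1G21650 = "SecA",
    AT1G21651 = c("zf-RING_2", "WD40", "WD40", "WD40"),
    Solyc11g005020 = "SecA",
    Solyc11g005030 = c("WD40", "WD40", "WD40"),
    Solyc11g005040 = "zf-C3HC4_2")
  og <- orthology_groups("m1", list(
    setNames(c("AT1G21650", "AT1G21651", "Solyc11g005020",
               "Solyc11g005030", "Solyc11g005040"),
             c("spA", "spA", "spB", "spB", "spB"))))
  record <- structure(list(
    factor_name = "cpSecA2", compartment = "Chloroplast",
    baits = c(spA = "AT1G21651"), missing_baits = character(0),
    per_method_sets = list(m1 = list(
      spA = "AT1G21650",
      spB = c("Solyc11g005020", "Solyc11g005030", "Solyc11g005040"))),
    consensus_sets = list(
      spA = "AT1G21650",
      spB = c("Solyc11g005020", "Solyc11g005030", "Solyc11g005040")),
    agreement = TRUE), class = "factor_record")
  list(gm = gm, archs = archs, og = og, record = record)
}

test_that("a 1:1 consensus factor yields a single consensus-flagged row", {
  rec <- structure(list(factor_name = "F1", compartment = "x",
                        baits = c(spA = "a1"), missing_baits = character(0),
                        per_method_sets = list(m1 = list(spA = character(0),
                                                         spB = "t1")),
                        consensus_sets = list(spA = character(0), spB = "t1"),
                        agreement = TRUE), class = "factor_record")
  gm <- gene_map(data.frame(gene_id = c("a1", "t1"),
                            species = c("spA", "spB"), chromosome = "c",
                            rank = 0L, strand = "+"))
  ev <- evidence_bundle(list(), gm, list())
  rows <- integrate_evidence(rec, ev)
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$evidence, "consensus")
  expect_equal(rows$geneA, "a1")
  expect_equal(rows$geneB, "t1")
})

test_that("the split-gene case emits two fusion-annotated rows plus the 1:1 mate", {
  fx <- fig1d_fixture()
  ev <- evidence_bundle(fx$archs, fx$gm, list(m1 = fx$og))
  rows <- integrate_evidence(fx$record, ev)
  fus <- rows[!is.na(rows$fusion_id), ]
  expect_equal(nrow(fus), 2L)
  expect_equal(fus$geneA, rep("AT1G21651", 2))
  expect_setequal(fus$geneB, c("Solyc11g005030", "Solyc11g005040"))
  expect_length(unique(fus$fusion_id), 1L)
  expect_true(all(fus$evidence == "architecture"))
  # the other cpSecA2 orthologue pairs by unique architecture
  single <- rows[is.na(rows$fusion_id), ]
  expect_equal(single$geneA, "AT1G21650")
  expect_equal(single$geneB, "Solyc11g005020")
  expect_false(any(rows$unresolved))
})

test_that("factors with an empty side are emitted unresolved", {
  rec <- structure(list(factor_name = "F1", compartment = "x",
                        baits = c(spA = "a1"), missing_baits = character(0),
                        per_method_sets = list(m1 = list(spA = character(0),
                                                         spB = character(0))),
                        consensus_sets = list(spA = character(0),
                                              spB = character(0)),
                        agreement = TRUE), class = "factor_record")
  gm <- gene_map(data.frame(gene_id = "a1", species = "spA",
                            chromosome = "c", rank = 0L, strand = "+"))
  rows <- integrate_evidence(rec, evidence_bundle(list(), gm, list()))
  expect_true(all(rows$unresolved))
  expect_true(all(is.na(rows$geneB)))
})

test_that("synteny resolves planted multi-candidate factors with '+' flags", {
  fx <- dup_genome_fixture(30)
  # factor with two A-side and two B-side candidates, true pairing (a10,b10),(a20,b20)
  rec <- structure(list(factor_name = "F1", compartment = "x",
                        baits = c(spA = fx$a[10]), missing_baits = character(0),
                        per_method_sets = list(
                          m1 = list(spA = c(fx$a[10], fx$a[20]),
                                    spB = c(fx$b[10], fx$b[20]))),
                        consensus_sets = list(spA = c(fx$a[10], fx$a[20]),
                                              spB = c(fx$b[10], fx$b[20])),
                        agreement = TRUE), class = "factor_record")
  archs <- setNames(rep(list("DOM"), 60), c(fx$a, fx$b))
  ev <- evidence_bundle(archs, fx$gmap, fx$methods)
  rows <- integrate_evidence(rec, ev)
  plus <- rows[rows$evidence == "+", ]
  expect_equal(nrow(plus), 2L)
  expect_setequal(paste(plus$geneA, plus$geneB),
                  c("a10 b10", "a20 b20"))
})

test_that("inventory categories follow the colour-code precedence", {
  expect_equal(categorize_factor(2, 2, TRUE, TRUE, TRUE), "equal")
  expect_equal(categorize_factor(1, 4, TRUE, TRUE, TRUE), "more_in_B")
  expect_equal(categorize_factor(3, 1, TRUE, TRUE, TRUE), "fewer_in_B")
  expect_equal(categorize_factor(0, 0, FALSE, FALSE, TRUE), "absent_in_plants")
  expect_equal(categorize_factor(1, 0, TRUE, FALSE, TRUE), "absent_in_B")
  expect_equal(categorize_factor(1, 1, TRUE, TRUE, FALSE), "plant_only")
})

test_that("category counts partition the inventory", {
  res <- run_pipeline(generate_dataset(sim_config(n_ancestral_genes = 40,
                                                  n_factors = 12, seed = 7)),
                      infer = FALSE)
  expect_length(res$categories, length(res$records))
  expect_equal(sum(table(res$categories)), 12L)
})

test_that("the inventory report prints and returns the factor count", {
  inv <- packaged_inventory()
  out <- capture.output(n <- report_inventory(inv))
  expect_equal(n, nrow(inv))
  expect_equal(out[1], as.character(nrow(inv)))
})
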