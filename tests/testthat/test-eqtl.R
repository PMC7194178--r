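# eQTL stage: BH adjustment, association lookup, cis/trans, eGene sets.

test_that("BH adjustment reproduces hand-computed and degenerate cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment matches the literal step-up oracle and ignores order", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(1:80, 1L)
    p <- runif(m)^sample(1:3, 1L)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(m)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
})

test_that("association lookup returns all tissue rows and reports untested pairs", {
  pairs <- data.table::data.table(rsid = c("rs1", "rs2"),
                                  gene_id = c("G1", "G2"))
  assoc <- data.table::data.table(
    rsid = c("rs1", "rs1", "rs1", "rs9"),
    gene_id = c("G1", "G1", "G1", "G9"),
    tissue = c("t1", "t2", "t3", "t1"),
    pval_nominal = c(0.01, 0.2, 0.5, 0.9))
  qa <- query_associations(pairs, assoc)
  expect_equal(nrow(qa$tested), 3L)
  expect_equal(qa$untested$rsid, "rs2")
  empty <- query_associations(pairs[0L], assoc)
  expect_equal(nrow(empty$tested), 0L)
})

test_that("cis/trans classification follows the inclusive 1 Mb convention", {
  # upstream SNP, 400 kb from the gene edge -> cis
  ct <- classify_cis_trans("chr1", 1000000, "chr1", 1400000, 1600000)
  expect_equal(ct$class, "cis"); expect_equal(ct$distance, 400000)
  # different chromosome -> trans, distance undefined
  ct <- classify_cis_trans("chr1", 100, "chr2", 50, 500)
  expect_equal(ct$class, "trans"); expect_true(is.na(ct$distance))
  # distance exactly the window -> cis (inclusive)
  ct <- classify_cis_trans("chr1", 0, "chr1", 1000000, 1200000)
  expect_equal(ct$class, "cis"); expect_equal(ct$distance, 1e6)
  # one bp further -> trans
  ct <- classify_cis_trans("chr1", 0, "chr1", 1000001, 1200000)
  expect_equal(ct$class, "trans")
  # SNP inside the gene body -> distance 0
  ct <- classify_cis_trans("chr1", 150, "chr1", 100, 200)
  expect_equal(ct$distance, 0)
})

test_that("eGene collection uses the >=1 significant call rule and is monotone in alpha", {
  calls <- data.table::data.table(
    rsid = c("rs1", "rs1", "rs2", "rs3"),
    gene_id = c("G1", "G1", "G2", "G3"),
    tissue = c("t1", "t2", "t1", "t1"),
    q = c(0.001, 0.9, 0.04, 0.2))
  es <- collect_egenes(calls, "A", alpha = 0.05)
  expect_setequal(es$egenes, c("G1", "G2"))  # one of many tissues suffices
  expect_setequal(es$eqtl_snps, c("rs1", "rs2"))
  es_small <- collect_egenes(calls, "A", alpha = 0.01)
  expect_true(all(es_small$egenes %in% es$egenes))
  es_none <- collect_egenes(calls, "A", alpha = 1e-6)
  expect_length(es_none$egenes, 0L)
})

test_that("summaries report eQTL fractions and a total cis/trans partition", {
  calls <- data.table::data.table(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    gene_id = paste0("G", 1:4), tissue = "t1",
    q = c(0.01, 0.01, 0.01, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    cis_trans = c("cis", "cis", "trans", "cis"))
  es <- collect_egenes(calls, "A", "combined", alpha = 0.05)
  snp_tab <- list(A = data.table::data.table(rsid = sprintf("rs%d", 1:10)))
  sm <- summarize_proportions(list(es), snp_tab, list(calls))
  expect_equal(sm$n_snps, 10L)
  expect_equal(sm$n_eqtl_snps, 3L)
  expect_equal(sm$fraction, 0.3)
  expect_equal(sm$n_cis + sm$n_trans, sum(calls$significant))
})

test_that("dataset partition splits eQTL SNPs into only-A / only-B / both", {
  mk <- function(ph, src, snps) structure(
    list(phenotype = ph, hic_source = src, egenes = character(0),
         eqtl_snps = snps), class = "egene_set")
  sets <- list(mk("P1", "cell", c("s1", "s2")), mk("P1", "musc", c("s2", "s3")),
               mk("P2", "cell", c("x1", "x2")), mk("P2", "musc", character(0)))
  part <- partition_by_dataset(sets)
  p1 <- part[phenotype == "P1"]
  expect_equal(unlist(p1[, .(only_cell, only_musc, both)]),
               c(only_cell = 1L, only_musc = 1L, both = 1L))
  p2 <- part[phenotype == "P2"]   # no muscle-specific eQTLs
  expect_equal(unlist(p2[, .(only_cell, only_musc, both)]),
               c(only_cell = 2L, only_musc = 0L, both = 0L))
  expect_error(partition_by_dataset(list(sets[[1L]])), "two Hi-C")
})

test_that("noise-free generation recovers the planted eQTL fraction exactly", {
  cfg <- small_sim_config(77, noise_free = TRUE)
  dir <- file.path(tempdir(), "eqtl_frac")
  sim <- simulate_dataset(cfg, dir)
  rc <- run_config(out_dir = file.path(dir, "out"), input_dir = dir,
                   simulate = FALSE, n_boot = 50L, seed = 77)
  rep <- run_all(rc)
  sm <- data.table::rbindlist(rep$eqtl$summary)
  for (ph in c("A", "B", "C")) {
    n <- cfg$phenotypes[[ph]]
    expected <- round(0.8 * n) / n
    got <- sm[phenotype == ph & hic_source == "combined", fraction]
    expect_equal(got, expected)
  }
  unlink(dir, recursive = TRUE)
})
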