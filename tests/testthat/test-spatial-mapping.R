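# Spatial mapping: significance filter, fragment assignment, pair calling.

test_that("significance filter is boundary-inclusive and order-preserving", {
  snps <- data.table::data.table(
    rsid = c("rs1", "rs2", "rs3"), chrom = "chr1", pos = c(10L, 20L, 30L),
    phenotype = "A", assoc_p = c(1e-7, 5e-6, 6e-6))
  kept <- filter_snps_by_significance(snps, alpha = 5e-6)
  expect_equal(kept$rsid, c("rs1", "rs2"))
  expect_equal(filter_snps_by_significance(snps, alpha = 1)$rsid,
               snps$rsid)
  expect_warning(out <- filter_snps_by_significance(snps, alpha = 1e-9),
                 "no SNPs")
  expect_equal(nrow(out), 0L)
})

test_that("SNPs map to the containing fragment under the half-open convention", {
  fr <- toy_fragments(3L, 4000L)
  snps <- data.table::data.table(
    rsid = c("rsA", "rsB"), chrom = "chr1", pos = c(4000L, 3999L),
    phenotype = "A", assoc_p = 1e-8)
  asg <- assign_to_fragments(snps, fr, what = "snp")
  expect_equal(asg[rsid == "rsA", frag_id], "F002")  # boundary: right-hand
  expect_equal(asg[rsid == "rsB", frag_id], "F001")
  bad <- data.table::data.table(rsid = "rsX", chrom = "chr9", pos = 5L,
                                phenotype = "A", assoc_p = 1e-8)
  expect_error(assign_to_fragments(bad, fr, what = "snp"), "rsX")
})

test_that("genes map to every overlapping fragment", {
  fr <- toy_fragments(3L, 4000L)
  genes <- data.table::data.table(gene_id = "G1", symbol = "g",
                                  chrom = "chr1", start = 3900L,
                                  end = 8100L)
  asg <- assign_to_fragments(genes, fr, what = "gene")
  expect_setequal(asg$frag_id, c("F001", "F002", "F003"))
})

test_that("pair calling honours contacts, the self-fragment rule and set semantics", {
  fr <- toy_fragments(7L, 1000L)
  snps <- data.table::data.table(
    rsid = c("rs1", "rs2"), chrom = "chr1", pos = c(100L, 6100L),
    phenotype = "A", assoc_p = 1e-8)
  genes <- data.table::data.table(
    gene_id = c("G1", "G2"), symbol = "g", chrom = "chr1",
    start = c(6050L, 2100L), end = c(6500L, 2900L))
  sf <- assign_to_fragments(snps, fr, "snp")
  gf <- assign_to_fragments(genes, fr, "gene")
  contacts <- list(
    cellline = data.table::data.table(frag_a = "F001", frag_b = "F007",
                                      count = 3L),
    muscle = data.table::data.table(frag_a = "F001", frag_b = "F007",
                                    count = 1L))
  pairs <- call_spatial_pairs(sf, gf, contacts)
  # rs1 (F001) contacts F007 which hosts G1, in both datasets -> one row
  expect_equal(pairs[rsid == "rs1" & gene_id == "G1", datasets],
               "cellline,muscle")
  # rs2 sits inside G1's own fragment: supported without any contact row
  expect_true(nrow(pairs[rsid == "rs2" & gene_id == "G1"]) == 1L)
  # self-fragment rule can be disabled
  pairs_ns <- call_spatial_pairs(sf, gf, contacts, self_contact = FALSE)
  expect_equal(nrow(pairs_ns[rsid == "rs2"]), 0L)
  # no contact, no co-location -> G2 absent
  expect_equal(nrow(pairs[gene_id == "G2"]), 0L)
  # unknown fragment id is an error when the fragment map is supplied
  bad <- list(cellline = data.table::data.table(
    frag_a = "F001", frag_b = "F999", count = 1L))
  expect_error(call_spatial_pairs(sf, gf, bad, fragments = fr), "F999")
})

test_that("pair calling matches exhaustive enumeration on random toys", {
  for (seed in 1:30) {
    toy <- random_spatial_toy(seed)
    sf <- assign_to_fragments(toy$snps, toy$fragments, "snp")
    gf <- assign_to_fragments(toy$genes, toy$fragments, "gene")
    got <- call_spatial_pairs(sf, gf, toy$contacts)
    want <- spatial_oracle(sf, gf, toy$contacts)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("pair calling is invariant to contact row order and orientation", {
  toy <- random_spatial_toy(99)
  sf <- assign_to_fragments(toy$snps, toy$fragments, "snp")
  gf <- assign_to_fragments(toy$genes, toy$fragments, "gene")
  base <- call_spatial_pairs(sf, gf, toy$contacts)
  scrambled <- lapply(toy$contacts, function(ct) {
    ct <- ct[sample(nrow(ct))]
    flip <- seq_len(nrow(ct)) %% 2L == 0L
    data.table::data.table(
      frag_a = ifelse(flip, ct$frag_b, ct$frag_a),
      frag_b = ifelse(flip, ct$frag_a, ct$frag_b), count = ct$count)
  })
  set.seed(7)
  expect_equal(as.data.frame(call_spatial_pairs(sf, gf, scrambled)),
               as.data.frame(base))
})

test_that("adding contact rows never removes a spatial pair", {
  toy <- random_spatial_toy(123)
  sf <- assign_to_fragments(toy$snps, toy$fragments, "snp")
  gf <- assign_to_fragments(toy$genes, toy$fragments, "gene")
  base <- call_spatial_pairs(sf, gf, toy$contacts)
  augmented <- toy$contacts
  augmented[[1L]] <- rbind(augmented[[1L]], data.table::data.table(
    frag_a = "F001", frag_b = "F025", count = 1L))
  grown <- call_spatial_pairs(sf, gf, augmented)
  key <- function(x) paste(x$rsid, x$gene_id)
  expect_true(all(key(base) %in% key(grown)))
})
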