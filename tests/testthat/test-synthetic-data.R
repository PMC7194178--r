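# Generator: genome tiling, SNP tables, planted structure, haplotypes.

test_that("fragments tile each chromosome exactly and genes are placed validly", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1L, chrom_length = 1e6,
                    fragment_mean_length = 4000, n_genes = 50L,
                    phenotypes = c(A = 10L, B = 5L))
  genome <- generate_genome(cfg)
  fr <- genome$fragments[order(start)]
  expect_equal(fr$start[1L], 0L)
  expect_equal(fr$end[nrow(fr)], 1e6)
  expect_true(all(fr$start[-1L] == fr$end[-nrow(fr)]))   # no gaps/overlaps
  expect_equal(sum(fr$end - fr$start), 1e6)              # conservation
  expect_gt(nrow(fr), 180); expect_lt(nrow(fr), 330)     # ~1e6 / 4000

  g <- genome$genes[order(start)]
  expect_equal(nrow(g), 50L)
  expect_true(all(g$start < g$end))
  expect_true(all(g$start >= 0 & g$end <= 1e6))
  expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))      # non-overlapping
})

test_that("genome generation errors when genes cannot fit", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1L, chrom_length = 60000,
                    n_genes = 50L, gene_length_range = c(2000, 5000),
                    phenotypes = c(A = 5L, B = 5L))
  expect_error(generate_genome(cfg), "cannot host")
})

test_that("SNP tables carry the configured per-phenotype counts, disjoint and thresholded", {
  cfg <- sim_config(seed = 9, n_genes = 200L)   # default GS/MG/MS/ALS sizes
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  counts <- table(snps$phenotype)
  expect_equal(counts[["GS"]], 179L)
  expect_equal(counts[["MG"]], 18L)
  expect_equal(counts[["MS"]], 285L)
  expect_equal(counts[["ALS"]], 135L)
  expect_equal(anyDuplicated(snps$rsid), 0L)               # pairwise disjoint
  expect_equal(anyDuplicated(snps[, .(chrom, pos)]), 0L)   # unique positions
  expect_true(all(snps$assoc_p <= 5e-6))
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- small_sim_config(31)
  d1 <- file.path(tempdir(), "simdet1"); d2 <- file.path(tempdir(), "simdet2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_true(length(f1) >= 10)
  md1 <- tools::md5sum(f1)
  md2 <- tools::md5sum(file.path(d2, basename(f1)))
  expect_true(all(unname(md1) == unname(md2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("decoy association p-values are consistent with Uniform(0,1)", {
  cfg <- small_sim_config(71, phenotypes = c(A = 150L, B = 150L),
                          planted_shared_egenes = list("A:B" = 3L),
                          decoys_per_snp = 15L, n_genes = 500L,
                          chrom_length = 2e6)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  assoc <- generate_eqtl_table(cfg, genome, snps, truth)
  true_keys <- paste(truth$pairs$rsid, truth$pairs$gene_id)
  decoy_p <- assoc[!paste(rsid, gene_id) %in% true_keys, pval_nominal]
  expect_gt(length(decoy_p), 1e4)
  ks <- suppressWarnings(ks.test(decoy_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth planting respects set relations and dataset support", {
  cfg <- small_sim_config(13)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  ne <- round(0.8 * c(A = 30, B = 12, C = 40))
  for (ph in names(ne)) {
    expect_length(truth$eqtl_snps[[ph]], ne[[ph]])
    expect_length(truth$egenes[[ph]], ne[[ph]])
  }
  # shared eGenes are subsets of each involved phenotype's set
  expect_length(truth$shared_egenes[["A:C"]], 5L)
  expect_true(all(truth$shared_egenes[["A:C"]] %in% truth$egenes$A))
  expect_true(all(truth$shared_egenes[["A:C"]] %in% truth$egenes$C))
  expect_false(any(truth$shared_egenes[["A:C"]] %in% truth$egenes$B))
  # every pair has at least one supporting dataset
  expect_true(all(nchar(truth$pairs$datasets) > 0))
})

test_that("a zero density multiplier removes a dataset's support for that phenotype", {
  cfg <- small_sim_config(
    17, datasets = list(cell = c(A = 1, B = 1, C = 1),
                        musc = c(A = 0.5, B = 0, C = 0.5)))
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  b_ds <- unlist(strsplit(truth$pairs[phenotype == "B", datasets], ","))
  expect_false("musc" %in% b_ds)
  a_ds <- unlist(strsplit(truth$pairs[phenotype == "A", datasets], ","))
  expect_true("musc" %in% a_ds)
})

test_that("contact lists are canonical and cover every planted pair", {
  cfg <- small_sim_config(23)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  contacts <- generate_contacts(cfg, genome, snps, truth)
  for (ct in contacts) {
    expect_true(all(ct$frag_a <= ct$frag_b))
    expect_equal(anyDuplicated(ct[, .(frag_a, frag_b)]), 0L)
  }
  snp_frag <- assign_to_fragments(snps, genome$fragments, "snp")
  gene_frag <- assign_to_fragments(genome$genes, genome$fragments, "gene")
  snp_map <- setNames(snp_frag$frag_id, snp_frag$rsid)
  gene_map <- split(gene_frag$frag_id, gene_frag$gene_id)
  keys <- lapply(contacts, function(ct) paste(ct$frag_a, ct$frag_b))
  for (i in seq_len(nrow(truth$pairs))) {
    sf <- snp_map[[truth$pairs$rsid[i]]]
    gf <- gene_map[[truth$pairs$gene_id[i]]]
    ok <- any(vapply(strsplit(truth$pairs$datasets[i], ",")[[1L]],
                     function(ds) any(paste(pmin(sf, gf), pmax(sf, gf))
                                      %in% keys[[ds]]), logical(1L)))
    expect_true(ok)
  }
})

test_that("planted pathways contain specific eGenes of each member but no shared eGenes", {
  cfg <- small_sim_config(37)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  pw <- generate_pathways(cfg, genome, truth)
  expect_length(pw$pathways, 60L)
  expect_true(all(unlist(pw$pathways) %in% genome$genes$gene_id))
  planted <- pw$truth$cooccur_pathways[["A:B:C"]]
  expect_length(planted, 1L)
  genes_in <- pw$pathways[[planted]]
  shared_union <- unique(unlist(truth$shared_egenes))
  expect_false(any(genes_in %in% shared_union))
  for (ph in c("A", "B", "C")) {
    expect_gt(length(intersect(genes_in, truth$specific_egenes[[ph]])), 0L)
  }
})

test_that("drug table matches the configured druggable fraction", {
  cfg <- sim_config(seed = 41, n_genes = 1000L, chrom_length = 4e6,
                    phenotypes = c(A = 10L, B = 10L),
                    druggable_fraction = 0.13)
  genome <- generate_genome(cfg)
  dgi <- generate_drug_table(cfg, genome)
  n_drg <- length(unique(dgi$gene_id))
  expect_true(all(dgi$gene_id %in% genome$genes$gene_id))
  # 130 +- binomial sampling (99.9% envelope)
  expect_gt(n_drg, qbinom(5e-4, 1000, 0.13))
  expect_lt(n_drg, qbinom(1 - 5e-4, 1000, 0.13))
  cfg0 <- sim_config(seed = 41, n_genes = 200L,
                     phenotypes = c(A = 10L, B = 10L),
                     druggable_fraction = 0)
  expect_equal(nrow(generate_drug_table(cfg0, generate_genome(cfg0))), 0L)
})

test_that("haplotypes realise planted LD and cross-chromosome independence", {
  cfg <- small_sim_config(57, phenotypes = c(A = 40L, B = 40L),
                          planted_shared_egenes = list("A:B" = 2L),
                          n_haplotypes = 1000L)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  haps <- generate_haplotypes(cfg, snps, truth)
  expect_equal(ncol(haps), nrow(snps))
  expect_equal(nrow(truth$ld_pairs), 1L)
  r2 <- ld_r2(haps, truth$ld_pairs$rsid_a[1L], truth$ld_pairs$rsid_b[1L])
  expect_gt(r2, 0.8)
  # SNPs on different chromosomes are independent: r2 small at H = 1000
  set.seed(1)
  chr1 <- snps[chrom == "chr1", rsid]; chr2 <- snps[chrom == "chr2", rsid]
  for (i in 1:20) {
    r2x <- ld_r2(haps, sample(chr1, 1L), sample(chr2, 1L))
    expect_lt(r2x, 0.2)
  }
})

test_that("VCF round-trips the haplotype matrix and has one site per SNP", {
  cfg <- small_sim_config(63, phenotypes = c(A = 15L, B = 15L),
                          planted_shared_egenes = list("A:B" = 1L),
                          n_haplotypes = 60L)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  haps <- generate_haplotypes(cfg, snps, truth)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_haplotypes(haps, snps, vcf)
  rt <- read_haplotypes(vcf)
  expect_equal(nrow(rt$snps), nrow(snps))
  expect_equal(rt$haps[, colnames(haps)], haps)
  unlink(vcf)
})

test_that("config validation rejects inconsistent planting", {
  expect_error(
    sim_config(phenotypes = c(A = 10L, B = 10L),
               planted_eqtl_fraction = 0.5,
               planted_shared_egenes = list("A:B" = 9L)),
    "exceed")
  expect_error(sim_config(phenotypes = c(A = 10L, B = 10L),
                          planted_shared_egenes = list("A:Z" = 1L)),
               "unknown phenotypes")
  expect_error(sim_config(n_haplotypes = 7L,
                          phenotypes = c(A = 5L, B = 5L)), "even")
})
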