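# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles implement definitions literally, sharing no code with
# the package paths they check.

# literal Benjamini-Hochberg step-up: q_i = min over j with p_j >= p_i of
# p_j * m / rank(j), clipped to 1 (ties take the largest rank)
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  cand <- p * m / r
  vapply(seq_len(m), function(i) min(1, min(cand[p >= p[i]])), numeric(1))
}

# exhaustive (SNP, gene, dataset) triple enumeration for spatial pairs
spatial_oracle <- function(snp_frags, gene_frags, contacts,
                           self_contact = TRUE) {
  gene_map <- split(gene_frags$frag_id, gene_frags$gene_id)
  keys <- lapply(contacts, function(ct) {
    unique(paste(pmin(ct$frag_a, ct$frag_b), pmax(ct$frag_a, ct$frag_b)))
  })
  rows <- list()
  for (i in seq_len(nrow(snp_frags))) {
    sf <- snp_frags$frag_id[i]
    for (g in names(gene_map)) {
      gf <- gene_map[[g]]
      supp <- character(0)
      for (ds in names(contacts)) {
        hit <- any(paste(pmin(sf, gf), pmax(sf, gf)) %in% keys[[ds]])
        if (self_contact && sf %in% gf) hit <- TRUE
        if (hit) supp <- c(supp, ds)
      }
      if (length(supp)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          rsid = snp_frags$rsid[i], gene_id = g,
          datasets = paste(sort(supp), collapse = ","))
      }
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(rsid = character(),
                                  gene_id = character(),
                                  datasets = character()))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, rsid, gene_id)
  out
}

# upper-tail hypergeometric probability by direct pmf summation with
# choose(); X = overlap of a draw of n from an urn of N with K marked
hyper_tail_oracle <- function(k, K, N, n) {
  support <- seq.int(max(0L, n + K - N), min(K, n))
  keep <- support >= k
  if (!any(keep)) return(0)
  sum(choose(K, support[keep]) * choose(N - K, n - support[keep])) /
    choose(N, n)
}

# r2 via explicit 2x2 haplotype contingency enumeration (determinant form)
r2_contingency_oracle <- function(haps, a, b) {
  x <- haps[, a]; y <- haps[, b]
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  H <- length(x)
  num <- (n11 * n00 - n10 * n01)^2
  den <- as.numeric(n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  num / den
}

# build a haplotype matrix from 2x2 haplotype counts (AB, Ab, aB, ab)
haps_from_counts <- function(n_ab11, n_ab10, n_ab01, n_ab00,
                             rsids = c("snpA", "snpB")) {
  a <- c(rep(1L, n_ab11), rep(1L, n_ab10), rep(0L, n_ab01),
         rep(0L, n_ab00))
  b <- c(rep(1L, n_ab11), rep(0L, n_ab10), rep(1L, n_ab01),
         rep(0L, n_ab00))
  matrix(c(a, b), ncol = 2L, dimnames = list(NULL, rsids))
}

# tiling fragment map on one chromosome with equal-width fragments
toy_fragments <- function(n_frag = 5L, width = 4000L, chrom = "chr1") {
  data.table::data.table(
    frag_id = sprintf("F%03d", seq_len(n_frag)), chrom = chrom,
    start = (seq_len(n_frag) - 1L) * width,
    end = seq_len(n_frag) * width)
}

# random toy instance for spatial-pair oracle checks
random_spatial_toy <- function(seed, max_snps = 15L, max_genes = 15L,
                               n_frag = 30L, n_datasets = 2L) {
  set.seed(seed)
  width <- 1000L
  fragments <- toy_fragments(n_frag, width)
  L <- n_frag * width
  n_snps <- sample.int(max_snps, 1L)
  n_genes <- sample.int(max_genes, 1L)
  snps <- data.table::data.table(
    rsid = sprintf("rs%03d", seq_len(n_snps)), chrom = "chr1",
    pos = sample.int(L, n_snps) - 1L, phenotype = "A",
    assoc_p = 1e-8)
  starts <- sample.int(L - 3500L, n_genes) - 1L
  genes <- data.table::data.table(
    gene_id = sprintf("G%03d", seq_len(n_genes)), symbol = "g",
    chrom = "chr1", start = starts,
    end = starts + sample(500:3000, n_genes, replace = TRUE))
  contacts <- lapply(seq_len(n_datasets), function(d) {
    n_ct <- sample.int(40L, 1L)
    ia <- sample(fragments$frag_id, n_ct, replace = TRUE)
    ib <- sample(fragments$frag_id, n_ct, replace = TRUE)
    unique(data.table::data.table(
      frag_a = pmin(ia, ib), frag_b = pmax(ia, ib),
      count = 1L)[frag_a != frag_b])
  })
  names(contacts) <- paste0("ds", seq_len(n_datasets))
  list(fragments = fragments, snps = snps, genes = genes,
       contacts = contacts)
}

# compact generator configuration for fast pipeline-level tests
small_sim_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_chromosomes = 2L, chrom_length = 8e5, n_genes = 300L,
    phenotypes = c(A = 30L, B = 12L, C = 40L),
    planted_shared_egenes = list("A:C" = 5L, "A:B" = 2L),
    planted_pathway_cooccurrence = list("A:B:C" = 1L),
    planted_pathway_hits = 6L, n_pathways = 60L, n_tissues = 10L,
    n_haplotypes = 200L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
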