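# Synthetic-data generator. Every pipeline input is emulated with planted
# ground truth (true eGenes, shared eGenes, co-occurring pathways, high-LD
# SNP pairs) recorded in a truth object / truth.tsv. Each stage seeds its own
# RNG stream from the master seed via stable_hash(), so stages are
# individually reproducible and a full run is byte-deterministic.

#' Generate the toy genome: gene models and a restriction-fragment map
#'
#' Fragments tile each chromosome exactly (0-based half-open, no gaps, no
#' overlaps) with lengths drawn around `fragment_mean_length`. Genes are
#' placed without overlap, fully inside their chromosome.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (gene_id, symbol, chrom, start, end) and
#'   `fragments` (frag_id, chrom, start, end), both data.tables, plus
#'   `chrom_sizes` (named vector).
#' @export
generate_genome <- function(cfg) {
  set.seed(stable_hash(cfg$seed, "genome"))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  L <- cfg$chrom_length
  fm <- cfg$fragment_mean_length

  frag_rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    n_draw <- ceiling(L / fm * 2) + 10L
    lens <- pmax(200, round(rnorm(n_draw, mean = fm, sd = fm / 4)))
    ends <- cumsum(lens)
    lens <- lens[ends < L]
    starts <- c(0, cumsum(lens))
    ends <- c(cumsum(lens), L)              # last fragment absorbs remainder
    frag_rows[[ci]] <- data.table::data.table(
      chrom = chroms[ci], start = as.integer(starts), end = as.integer(ends))
  }
  fragments <- data.table::rbindlist(frag_rows)
  fragments[, frag_id := sprintf("F%06d", .I)]
  data.table::setcolorder(fragments, c("frag_id", "chrom", "start", "end"))

  # allocate genes across chromosomes as evenly as possible
  n_per <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_genes %% cfg$n_chromosomes
  if (extra > 0L) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
  gene_rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    k <- n_per[ci]
    if (k == 0L) next
    lens <- round(runif(k, cfg$gene_length_range[1L],
                        cfg$gene_length_range[2L]))
    free <- L - sum(lens)
    if (free < k) {
      stop(sprintf(
        paste0("chromosome length %g bp cannot host %d non-overlapping ",
               "genes totalling %g bp; increase chrom_length or reduce ",
               "n_genes/gene_length_range"), L, k, sum(lens)), call. = FALSE)
    }
    offs <- sort(sample.int(free + 1L, k) - 1L)
    starts <- offs + cumsum(c(0, lens[-k]))
    gene_rows[[ci]] <- data.table::data.table(
      chrom = chroms[ci], start = as.integer(starts),
      end = as.integer(starts + lens))
  }
  genes <- data.table::rbindlist(gene_rows)
  genes[, gene_id := sprintf("SG%05d", .I)]
  genes[, symbol := sprintf("gene%d", .I)]
  data.table::setcolorder(genes, c("gene_id", "symbol", "chrom", "start",
                                   "end"))
  list(genes = genes[], fragments = fragments[],
       chrom_sizes = setNames(rep(L, length(chroms)), chroms))
}

#' Generate per-phenotype GWAS SNP tables
#'
#' Every SNP gets a unique rsID-style identifier, a unique genomic position
#' and an association p-value at or below the suggestive threshold; the
#' phenotype SNP sets are pairwise disjoint.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @return data.table with rsid, chrom, pos (0-based), phenotype, assoc_p.
#' @export
generate_phenotype_snps <- function(cfg, genome) {
  set.seed(stable_hash(cfg$seed, "snps"))
  n_total <- sum(cfg$phenotypes)
  avail <- cfg$n_chromosomes * cfg$chrom_length
  if (n_total > avail) {
    stop(sprintf(
      "requested %d SNPs exceed the %g available distinct positions",
      n_total, avail), call. = FALSE)
  }
  chroms <- names(genome$chrom_sizes)
  chrom <- sample(chroms, n_total, replace = TRUE)
  pos <- integer(n_total)
  for (cn in chroms) {
    idx <- which(chrom == cn)
    if (length(idx)) {
      pos[idx] <- sample.int(genome$chrom_sizes[[cn]], length(idx)) - 1L
    }
  }
  ord <- sample.int(n_total)      # shuffle before phenotype assignment
  snps <- data.table::data.table(
    rsid = sprintf("rs%07d", sample.int(9999999L, n_total)),
    chrom = chrom[ord], pos = pos[ord],
    phenotype = rep(names(cfg$phenotypes), cfg$phenotypes),
    assoc_p = cfg$gwas_p_threshold * 10^(-runif(n_total, 0, 4))
  )
  snps[]
}

#' Plant the ground truth: true eQTL SNPs, eGenes, shared eGenes, LD pairs
#'
#' For each phenotype a `planted_eqtl_fraction` of its SNPs become true
#' eQTLs, each regulating one eGene. Shared eGenes are planted per
#' combination by assigning one gene to a SNP of every member phenotype
#' (preferring cis placements); remaining true-eQTL SNPs get their own
#' condition-specific eGene. Cross-phenotype high-LD SNP pairs are chosen
#' among the true eQTL SNPs of two phenotypes on a shared chromosome.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @param snps Output of [generate_phenotype_snps()].
#' @return A truth object (list); see [write_truth()] for the serialised
#'   form. Also carries internal decoy-pair bookkeeping used by the contact
#'   and association generators.
#' @export
build_truth <- function(cfg, genome, snps, cis_window = 1e6) {
  set.seed(stable_hash(cfg$seed, "truth"))
  snps <- data.table::as.data.table(snps)
  genes <- genome$genes
  ne <- planted_egene_counts(cfg)
  phenos <- names(cfg$phenotypes)

  eqtl_snps <- lapply(phenos, function(ph) {
    ids <- snps[phenotype == ph, rsid]
    sort(sample(ids, ne[[ph]]))
  })
  names(eqtl_snps) <- phenos

  gene_used <- logical(nrow(genes))
  snp_avail <- lapply(eqtl_snps, function(x) x)
  pair_rows <- list()
  shared_egenes <- list()

  snp_pos <- setNames(snps$pos, snps$rsid)
  snp_chrom <- setNames(snps$chrom, snps$rsid)

  pick_gene_near <- function(rsid) {
    # cis placement with prob cis_fraction, else anywhere (trans-prone)
    cand <- integer(0)
    if (runif(1) < cfg$cis_fraction) {
      cand <- which(!gene_used & genes$chrom == snp_chrom[[rsid]] &
                    genes$start <= snp_pos[[rsid]] + cis_window &
                    genes$end > snp_pos[[rsid]] - cis_window)
    }
    if (!length(cand)) cand <- which(!gene_used)
    if (!length(cand)) {
      stop("gene universe exhausted while planting eGenes; increase n_genes",
           call. = FALSE)
    }
    cand[sample.int(length(cand), 1L)]
  }

  take_snp_near <- function(ph, gi) {
    av <- snp_avail[[ph]]
    on_chr <- av[snp_chrom[av] == genes$chrom[gi]]
    pick <- if (length(on_chr)) {
      mid <- (genes$start[gi] + genes$end[gi]) / 2
      on_chr[which.min(abs(snp_pos[on_chr] - mid))]
    } else {
      av[sample.int(length(av), 1L)]
    }
    snp_avail[[ph]] <<- setdiff(av, pick)
    pick
  }

  for (cmb in names(cfg$planted_shared_egenes)) {
    members <- parse_combo(cmb)
    cnt <- cfg$planted_shared_egenes[[cmb]]
    ids <- character(cnt)
    for (j in seq_len(cnt)) {
      anchor_ph <- members[which.max(vapply(members, function(m)
        length(snp_avail[[m]]), integer(1L)))]
      anchor <- snp_avail[[anchor_ph]][
        sample.int(length(snp_avail[[anchor_ph]]), 1L)]
      gi <- pick_gene_near(anchor)
      gene_used[gi] <- TRUE
      ids[j] <- genes$gene_id[gi]
      for (m in members) {
        rs <- take_snp_near(m, gi)
        pair_rows[[length(pair_rows) + 1L]] <- data.table::data.table(
          phenotype = m, rsid = rs, gene_id = genes$gene_id[gi])
      }
    }
    shared_egenes[[cmb]] <- sort(ids)
  }

  for (ph in phenos) {
    for (rs in snp_avail[[ph]]) {
      gi <- pick_gene_near(rs)
      gene_used[gi] <- TRUE
      pair_rows[[length(pair_rows) + 1L]] <- data.table::data.table(
        phenotype = ph, rsid = rs, gene_id = genes$gene_id[gi])
    }
    snp_avail[[ph]] <- character(0)
  }

  pairs <- data.table::rbindlist(pair_rows)

  # Hi-C dataset support: a fraction of pairs is confined to one dataset
  ds_names <- names(cfg$datasets)
  pairs[, datasets := vapply(seq_len(.N), function(i) {
    mults <- vapply(ds_names, dataset_multiplier, numeric(1L),
                    cfg = cfg, ph = pairs$phenotype[i])
    active <- ds_names[mults > 0]
    if (!length(active)) {
      stop(sprintf(
        "phenotype '%s' has zero density multiplier in every dataset",
        pairs$phenotype[i]), call. = FALSE)
    }
    if (length(active) > 1L && runif(1) < cfg$dataset_specific_fraction) {
      active <- sample(active, 1L, prob = mults[mults > 0])
    }
    paste(active, collapse = ",")
  }, character(1L))]

  egenes <- lapply(phenos, function(ph)
    sort(unique(pairs[phenotype == ph, gene_id])))
  names(egenes) <- phenos
  shared_union <- unique(unlist(shared_egenes))
  specific_egenes <- lapply(egenes, function(g) setdiff(g, shared_union))

  # decoy (non-eQTL) association pairs; a fraction also gets a Hi-C contact
  true_genes_by_snp <- split(pairs$gene_id, pairs$rsid)
  decoy_rows <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    excl <- true_genes_by_snp[[snps$rsid[i]]] %||% character(0)
    pool <- setdiff(genes$gene_id, excl)
    dg <- sample(pool, min(cfg$decoys_per_snp, length(pool)))
    decoy_rows[[i]] <- data.table::data.table(
      phenotype = snps$phenotype[i], rsid = snps$rsid[i], gene_id = dg)
  }
  decoys <- data.table::rbindlist(decoy_rows)
  decoys[, tested := runif(.N) < cfg$tested_decoy_fraction]
  decoys[, dataset := vapply(seq_len(.N), function(i) {
    if (!decoys$tested[i]) return("")
    mults <- vapply(ds_names, dataset_multiplier, numeric(1L),
                    cfg = cfg, ph = decoys$phenotype[i])
    if (!any(mults > 0)) return("")
    sample(ds_names[mults > 0], 1L, prob = mults[mults > 0])
  }, character(1L))]
  decoys[dataset == "", tested := FALSE]

  # planted cross-phenotype high-LD pairs among true eQTL SNPs
  ld_rows <- list()
  if (cfg$planted_ld_pairs > 0L && length(phenos) >= 2L) {
    pref <- if (all(c("MG", "MS") %in% phenos)) c("MG", "MS") else
      phenos[1:2]
    used_ld <- character(0)
    for (j in seq_len(cfg$planted_ld_pairs)) {
      a_cand <- setdiff(eqtl_snps[[pref[1L]]], used_ld)
      b_cand <- setdiff(eqtl_snps[[pref[2L]]], used_ld)
      common <- intersect(unique(snp_chrom[a_cand]),
                          unique(snp_chrom[b_cand]))
      if (!length(common) || !length(a_cand) || !length(b_cand)) break
      cn <- sample(common, 1L)
      a <- sample(a_cand[snp_chrom[a_cand] == cn], 1L)
      b <- sample(b_cand[snp_chrom[b_cand] == cn], 1L)
      used_ld <- c(used_ld, a, b)
      ld_rows[[j]] <- data.table::data.table(
        rsid_a = a, rsid_b = b,
        phenotype_a = pref[1L], phenotype_b = pref[2L])
    }
  }
  ld_pairs <- if (length(ld_rows)) data.table::rbindlist(ld_rows) else
    data.table::data.table(rsid_a = character(), rsid_b = character(),
                           phenotype_a = character(),
                           phenotype_b = character())

  list(egenes = egenes, eqtl_snps = eqtl_snps, pairs = pairs[],
       shared_egenes = shared_egenes, specific_egenes = specific_egenes,
       cooccur_pathways = list(), ld_pairs = ld_pairs, decoys = decoys[])
}

#' Generate per-dataset Hi-C fragment-pair contact lists
#'
#' Every planted (SNP, eGene) pair receives a contact between the SNP's
#' fragment and a fragment overlapping the gene in each of its supporting
#' datasets; tested decoy pairs receive one contact in their assigned
#' dataset; random background contacts are added at dataset-specific
#' density. Records are in canonical unordered form (`frag_a <= frag_b`).
#'
#' @param cfg A [sim_config()].
#' @param genome,snps,truth Earlier generator outputs.
#' @return Named list (one per dataset) of data.tables with frag_a, frag_b,
#'   count.
#' @export
generate_contacts <- function(cfg, genome, snps, truth) {
  set.seed(stable_hash(cfg$seed, "contacts"))
  snp_frag <- assign_to_fragments(snps, genome$fragments, what = "snp")
  gene_frag <- assign_to_fragments(genome$genes, genome$fragments,
                                   what = "gene")
  snp_map <- setNames(snp_frag$frag_id, snp_frag$rsid)
  gene_map <- split(gene_frag$frag_id, gene_frag$gene_id)

  ds_names <- names(cfg$datasets)
  rows <- setNames(vector("list", length(ds_names)), ds_names)
  for (ds in ds_names) rows[[ds]] <- list()

  add_contact <- function(ds, fa, fb) {
    cp <- canonical_pair(fa, fb)
    rows[[ds]][[length(rows[[ds]]) + 1L]] <<- c(cp$a, cp$b)
  }

  for (i in seq_len(nrow(truth$pairs))) {
    fs <- snp_map[[truth$pairs$rsid[i]]]
    gfs <- gene_map[[truth$pairs$gene_id[i]]]
    for (ds in parse_combo2(truth$pairs$datasets[i])) {
      add_contact(ds, fs, gfs[sample.int(length(gfs), 1L)])
    }
  }
  tested <- truth$decoys[tested == TRUE]
  for (i in seq_len(nrow(tested))) {
    fs <- snp_map[[tested$rsid[i]]]
    gfs <- gene_map[[tested$gene_id[i]]]
    add_contact(tested$dataset[i], fs, gfs[sample.int(length(gfs), 1L)])
  }

  n_frag <- nrow(genome$fragments)
  out <- setNames(vector("list", length(ds_names)), ds_names)
  for (ds in ds_names) {
    mult <- mean(vapply(names(cfg$phenotypes), dataset_multiplier,
                        numeric(1L), cfg = cfg, ds = ds))
    n_bg <- round(cfg$background_contacts_per_fragment * mult * n_frag)
    dt <- data.table::data.table(frag_a = character(0),
                                 frag_b = character(0))
    if (n_bg > 0) {
      ia <- sample.int(n_frag, n_bg, replace = TRUE)
      ib <- sample.int(n_frag, n_bg, replace = TRUE)
      keep <- ia != ib
      cp <- canonical_pair(genome$fragments$frag_id[ia[keep]],
                           genome$fragments$frag_id[ib[keep]])
      dt <- data.table::data.table(frag_a = cp$a, frag_b = cp$b)
    }
    if (length(rows[[ds]])) {
      planted <- data.table::as.data.table(
        do.call(rbind, rows[[ds]]))
      data.table::setnames(planted, c("frag_a", "frag_b"))
      dt <- rbind(planted, dt)
    }
    dt <- unique(dt)
    dt[, count := sample.int(50L, .N, replace = TRUE)]
    data.table::setorder(dt, frag_a, frag_b)
    out[[ds]] <- dt[]
  }
  out
}

parse_combo2 <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]

#' Generate the eQTL association table over (variant, gene, tissue)
#'
#' Planted true pairs get 1-3 tissues with nominal p drawn log-uniformly
#' from `sig_p_range` plus a few non-significant tissue rows; decoy pairs
#' get Uniform(decoy_p_min, 1) p-values in 1-5 tissues.
#'
#' @param cfg A [sim_config()].
#' @param genome,snps,truth Earlier generator outputs.
#' @return data.table with rsid, gene_id, tissue, pval_nominal.
#' @export
generate_eqtl_table <- function(cfg, genome, snps, truth) {
  set.seed(stable_hash(cfg$seed, "eqtl"))
  tissues <- sprintf("Tissue%02d", seq_len(cfg$n_tissues))
  lo <- log10(cfg$sig_p_range[1L]); hi <- log10(cfg$sig_p_range[2L])

  planted <- lapply(seq_len(nrow(truth$pairs)), function(i) {
    n_sig <- sample.int(3L, 1L)
    n_null <- min(3L, cfg$n_tissues - n_sig)
    tis <- sample(tissues, n_sig + n_null)
    data.table::data.table(
      rsid = truth$pairs$rsid[i], gene_id = truth$pairs$gene_id[i],
      tissue = tis,
      pval_nominal = c(10^runif(n_sig, lo, hi),
                       runif(n_null, max(cfg$decoy_p_min, 0.06), 1)))
  })
  decoy <- lapply(seq_len(nrow(truth$decoys)), function(i) {
    n_t <- sample.int(5L, 1L)
    data.table::data.table(
      rsid = truth$decoys$rsid[i], gene_id = truth$decoys$gene_id[i],
      tissue = sample(tissues, n_t),
      pval_nominal = runif(n_t, cfg$decoy_p_min, 1))
  })
  assoc <- data.table::rbindlist(c(planted, decoy))
  data.table::setorder(assoc, rsid, gene_id, tissue)
  assoc[]
}

#' Generate the pathway collection (GMT)
#'
#' Plants `planted_pathway_cooccurrence` pathways containing
#' condition-specific eGenes from every member phenotype (and no shared
#' eGenes, so their co-occurrence signal is condition-specific by
#' construction); all other pathways are uniform random gene sets.
#'
#' @param cfg A [sim_config()].
#' @param genome,truth Earlier generator outputs.
#' @return List with `pathways` (named list of gene-id vectors) and the
#'   `truth` object with `cooccur_pathways` filled in.
#' @export
generate_pathways <- function(cfg, genome, truth) {
  set.seed(stable_hash(cfg$seed, "pathways"))
  all_genes <- genome$genes$gene_id
  if (cfg$pathway_size_range[2L] > length(all_genes)) {
    stop(sprintf(
      "pathway size %d exceeds the %d-gene universe",
      cfg$pathway_size_range[2L], length(all_genes)), call. = FALSE)
  }
  n_planted <- sum(unlist(cfg$planted_pathway_cooccurrence))
  if (n_planted > cfg$n_pathways) {
    stop("more planted co-occurring pathways than n_pathways",
         call. = FALSE)
  }
  sizes <- sample(seq.int(cfg$pathway_size_range[1L],
                          cfg$pathway_size_range[2L]),
                  cfg$n_pathways, replace = TRUE)
  ids <- sprintf("PW%04d", seq_len(cfg$n_pathways))
  pathways <- setNames(vector("list", cfg$n_pathways), ids)

  egene_union <- unique(unlist(truth$egenes))
  filler_pool <- setdiff(all_genes, egene_union)
  idx <- 1L
  for (cmb in names(cfg$planted_pathway_cooccurrence)) {
    members <- parse_combo(cmb)
    cnt <- cfg$planted_pathway_cooccurrence[[cmb]]
    pids <- character(cnt)
    for (j in seq_len(cnt)) {
      hits <- unlist(lapply(members, function(m) {
        pool <- truth$specific_egenes[[m]]
        if (!length(pool)) {
          stop(sprintf(
            "phenotype '%s' has no condition-specific eGenes to plant", m),
            call. = FALSE)
        }
        sample(pool, min(cfg$planted_pathway_hits, length(pool)))
      }))
      size_j <- max(sizes[idx], length(hits))
      fill <- sample(filler_pool, min(size_j - length(hits),
                                      length(filler_pool)))
      pathways[[idx]] <- sort(c(hits, fill))
      pids[j] <- ids[idx]
      idx <- idx + 1L
    }
    truth$cooccur_pathways[[cmb]] <- pids
  }
  for (k in seq.int(idx, cfg$n_pathways)) {
    pathways[[k]] <- sort(sample(all_genes, sizes[k]))
  }
  list(pathways = pathways, truth = truth)
}

#' Generate the drug-gene interaction table
#'
#' Each gene is druggable with probability `druggable_fraction`; druggable
#' genes receive 1-3 (drug, source) rows.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @return data.table with gene_id, drug, source.
#' @export
generate_drug_table <- function(cfg, genome) {
  set.seed(stable_hash(cfg$seed, "dgi"))
  hit <- rbinom(nrow(genome$genes), 1L, cfg$druggable_fraction) == 1L
  gids <- genome$genes$gene_id[hit]
  if (!length(gids)) {
    return(data.table::data.table(gene_id = character(),
                                  drug = character(),
                                  source = character()))
  }
  n_rows <- sample.int(3L, length(gids), replace = TRUE)
  data.table::data.table(
    gene_id = rep(gids, n_rows),
    drug = sprintf("DRUG%04d", sample.int(5000L, sum(n_rows),
                                          replace = TRUE)),
    source = sample(c("chem_a", "chem_b", "chem_c"), sum(n_rows),
                    replace = TRUE)
  )
}

#' Generate phased haplotypes over all SNPs
#'
#' SNPs within an `ld_block_length` window on a chromosome copy a shared
#' ancestral haplotype with per-allele error `ld_block_flip` (background
#' within-block r-squared around 0.25); planted pairs copy a shared base
#' haplotype with error `planted_ld_flip` (expected r-squared about 0.92 at
#' the default); cross-block and
#' cross-chromosome SNPs are independent.
#'
#' @param cfg A [sim_config()].
#' @param snps SNP table.
#' @param truth Truth object (for planted LD pairs).
#' @return Integer matrix, haplotypes x SNPs, columns named by rsid.
#' @export
generate_haplotypes <- function(cfg, snps, truth) {
  set.seed(stable_hash(cfg$seed, "haplotypes"))
  snps <- data.table::as.data.table(snps)
  data.table::setorder(snps, chrom, pos)
  H <- cfg$n_haplotypes
  haps <- matrix(0L, nrow = H, ncol = nrow(snps),
                 dimnames = list(NULL, snps$rsid))
  block <- paste(snps$chrom, snps$pos %/% cfg$ld_block_length)
  for (b in unique(block)) {
    members <- which(block == b)
    anc <- rbinom(H, 1L, runif(1, 0.2, 0.8))
    for (i in members) {
      flips <- rbinom(H, 1L, cfg$ld_block_flip)
      haps[, i] <- as.integer(xor(anc, flips))
    }
  }
  if (nrow(truth$ld_pairs)) {
    for (i in seq_len(nrow(truth$ld_pairs))) {
      a <- truth$ld_pairs$rsid_a[i]; b <- truth$ld_pairs$rsid_b[i]
      base <- rbinom(H, 1L, runif(1, 0.3, 0.7))
      haps[, a] <- as.integer(xor(base, rbinom(H, 1L, cfg$planted_ld_flip)))
      haps[, b] <- as.integer(xor(base, rbinom(H, 1L, cfg$planted_ld_flip)))
    }
  }
  # guard against monomorphic columns (r2 undefined)
  mono <- which(matrixStats_colAllEqual(haps))
  for (j in mono) {
    flip_at <- sample.int(H, 1L)
    haps[flip_at, j] <- 1L - haps[flip_at, j]
  }
  haps
}

matrixStats_colAllEqual <- function(m) {
  apply(m, 2L, function(x) all(x == x[1L]))
}

#' Run every generator stage and write all pipeline inputs to a directory
#'
#' Emits genes.tsv, fragments.bed, snps_<phenotype>.tsv,
#' contacts_<dataset>.tsv, eqtl_associations.tsv, pathways.gmt, dgi.tsv,
#' haplotypes.vcf, background_all_egenes.txt (all genes appearing in the
#' association table, the stand-in for an external all-eGenes background)
#' and truth.tsv. Identical configs produce byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all in-memory objects and file paths.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(cfg)
  snps <- generate_phenotype_snps(cfg, genome)
  truth <- build_truth(cfg, genome, snps)
  contacts <- generate_contacts(cfg, genome, snps, truth)
  assoc <- generate_eqtl_table(cfg, genome, snps, truth)
  pw <- generate_pathways(cfg, genome, truth)
  truth <- pw$truth
  dgi <- generate_drug_table(cfg, genome)
  haps <- generate_haplotypes(cfg, snps, truth)

  p <- function(f) file.path(out_dir, f)
  write_genes(genome$genes, p("genes.tsv"))
  write_fragments_bed(genome$fragments, p("fragments.bed"))
  for (ph in names(cfg$phenotypes)) {
    write_snps(snps[phenotype == ph], p(sprintf("snps_%s.tsv", ph)))
  }
  for (ds in names(contacts)) {
    write_contacts(contacts[[ds]], p(sprintf("contacts_%s.tsv", ds)))
  }
  write_eqtl_table(assoc, p("eqtl_associations.tsv"))
  write_gmt(pw$pathways, p("pathways.gmt"))
  write_dgi(dgi, p("dgi.tsv"))
  write_vcf_haplotypes(haps, snps, p("haplotypes.vcf"))
  write_gene_list(sort(unique(assoc$gene_id)),
                  p("background_all_egenes.txt"))
  write_truth(truth, p("truth.tsv"))

  invisible(list(
    cfg = cfg, genome = genome, snps = snps, truth = truth,
    contacts = contacts, assoc = assoc, pathways = pw$pathways, dgi = dgi,
    haps = haps, dir = out_dir
  ))
}
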