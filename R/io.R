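# Readers and writers for the pipeline's on-disk formats. All coordinates are
# 0-based half-open in memory; BED is emitted natively, the GTF-like gene
# table is emitted 1-based inclusive with conversion at this boundary.
# See FORMATS.md at the repository root for column-level documentation.

#' Write / read the gene model table
#'
#' The on-disk table is GTF-like (1-based, inclusive coordinates); in memory
#' genes use 0-based half-open `start`/`end`.
#'
#' @param genes data.table with gene_id, symbol, chrom, start, end (0-based
#'   half-open).
#' @param path Output TSV path.
#' @export
write_genes <- function(genes, path) {
  out <- data.table::copy(data.table::as.data.table(genes))
  out[, start := start + 1L]        # half-open end == inclusive 1-based end
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_genes
#' @export
read_genes <- function(path) {
  g <- data.table::fread(path, sep = "\t")
  g[, start := start - 1L]
  g[]
}

#' Write / read the restriction-fragment map (BED4)
#' @param fragments data.table with frag_id, chrom, start, end.
#' @param path BED file path.
#' @export
write_fragments_bed <- function(fragments, path) {
  out <- data.table::as.data.table(fragments)[, .(chrom, start, end, frag_id)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  f <- data.table::fread(path, sep = "\t",
                         col.names = c("chrom", "start", "end", "frag_id"))
  f[, .(frag_id, chrom, start, end)]
}

#' Write / read a per-phenotype SNP table
#'
#' Columns: rsid, chrom, pos (0-based), phenotype, assoc_p.
#' @param snps data.table of SNP records.
#' @param path TSV path.
#' @export
write_snps <- function(snps, path) {
  data.table::fwrite(data.table::as.data.table(snps), path, sep = "\t")
  invisible(path)
}

#' @rdname write_snps
#' @export
read_snps <- function(path) data.table::fread(path, sep = "\t")

#' Write / read a Hi-C fragment-pair contact list
#'
#' Canonical form: one row per unordered fragment pair, `frag_a <= frag_b`.
#' @param contacts data.table with frag_a, frag_b, count.
#' @param path TSV path.
#' @export
write_contacts <- function(contacts, path) {
  data.table::fwrite(data.table::as.data.table(contacts), path, sep = "\t")
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) data.table::fread(path, sep = "\t")

#' Write / read the eQTL association table
#' Columns: rsid, gene_id, tissue, pval_nominal.
#' @param assoc data.table of association rows.
#' @param path TSV path.
#' @export
write_eqtl_table <- function(assoc, path) {
  data.table::fwrite(data.table::as.data.table(assoc), path, sep = "\t")
  invisible(path)
}

#' @rdname write_eqtl_table
#' @export
read_eqtl_table <- function(path) data.table::fread(path, sep = "\t")

#' Write / read gene-set collections in GMT format
#'
#' Reading delegates to [fgsea::gmtPathways()].
#' @param pathways Named list of character vectors of gene ids.
#' @param path GMT file path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "synthetic", pathways[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write / read the drug-gene interaction table
#' Columns: gene_id, drug, source.
#' @param dgi data.table of interactions.
#' @param path TSV path.
#' @export
write_dgi <- function(dgi, path) {
  data.table::fwrite(data.table::as.data.table(dgi), path, sep = "\t")
  invisible(path)
}

#' @rdname write_dgi
#' @export
read_dgi <- function(path) data.table::fread(path, sep = "\t")

#' Write phased haplotypes as a minimal VCF 4.2
#'
#' Haplotype `2i - 1` and `2i` become the phased genotype of sample `i`.
#'
#' @param haps Integer matrix, rows = haplotypes, columns = SNPs (0/1 allele
#'   codes), column names = rsids. The number of rows must be even.
#' @param snps SNP table with rsid, chrom, pos (0-based).
#' @param path VCF path.
#' @export
write_vcf_haplotypes <- function(haps, snps, path) {
  snps <- data.table::as.data.table(snps)
  stopifnot(nrow(haps) %% 2L == 0L, all(snps$rsid %in% colnames(haps)))
  n_samp <- nrow(haps) / 2L
  samples <- sprintf("HAP%04d", seq_len(n_samp))
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=spatialmorbid synthetic haplotype generator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  odd <- seq(1L, nrow(haps), by = 2L)
  body <- vapply(seq_len(nrow(snps)), function(i) {
    col <- haps[, snps$rsid[i]]
    gt <- paste0(col[odd], "|", col[odd + 1L])
    paste(c(snps$chrom[i], snps$pos[i] + 1L, snps$rsid[i], "A", "G", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Parses with [vcfR::read.vcfR()] and expands each phased diploid genotype
#' into two haplotype rows.
#'
#' @param path VCF path.
#' @return List with `haps` (integer matrix, haplotypes x SNPs, columns named
#'   by rsid) and `snps` (data.table rsid, chrom, pos 0-based).
#' @export
read_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  fix <- data.table::data.table(
    rsid = as.character(v@fix[, "ID"]),
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]) - 1L
  )
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  n_samp <- ncol(gt)
  haps <- matrix(0L, nrow = 2L * n_samp, ncol = nrow(gt),
                 dimnames = list(NULL, fix$rsid))
  haps[seq(1L, 2L * n_samp, by = 2L), ] <- t(a1)
  haps[seq(2L, 2L * n_samp, by = 2L), ] <- t(a2)
  list(haps = haps, snps = fix)
}

#' Write / read a plain gene-id list (one per line)
#' @param genes Character vector.
#' @param path File path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) readLines(path)

#' Write / read the planted-truth table
#'
#' Flat TSV with a `role` column; see FORMATS.md. Roles: `egene`,
#' `eqtl_snp`, `pair`, `shared_egene`, `cooccur_pathway`, `ld_pair`.
#' @param truth A truth object from [build_truth()] (with pathway and LD
#'   slots filled by the later generator stages).
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  rows <- list()
  for (ph in names(truth$egenes)) {
    if (length(truth$egenes[[ph]])) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        role = "egene", group = ph, id1 = truth$egenes[[ph]], id2 = "",
        info = "")
    }
    if (length(truth$eqtl_snps[[ph]])) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        role = "eqtl_snp", group = ph, id1 = truth$eqtl_snps[[ph]], id2 = "",
        info = "")
    }
  }
  if (nrow(truth$pairs)) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      role = "pair", group = truth$pairs$phenotype, id1 = truth$pairs$rsid,
      id2 = truth$pairs$gene_id, info = truth$pairs$datasets)
  }
  for (cmb in names(truth$shared_egenes)) {
    if (length(truth$shared_egenes[[cmb]])) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        role = "shared_egene", group = cmb, id1 = truth$shared_egenes[[cmb]],
        id2 = "", info = "")
    }
  }
  for (cmb in names(truth$cooccur_pathways)) {
    if (length(truth$cooccur_pathways[[cmb]])) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        role = "cooccur_pathway", group = cmb,
        id1 = truth$cooccur_pathways[[cmb]], id2 = "", info = "")
    }
  }
  if (!is.null(truth$ld_pairs) && nrow(truth$ld_pairs)) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      role = "ld_pair",
      group = paste(truth$ld_pairs$phenotype_a, truth$ld_pairs$phenotype_b,
                    sep = ":"),
      id1 = truth$ld_pairs$rsid_a, id2 = truth$ld_pairs$rsid_b, info = "")
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = 1:5))
  split_ids <- function(role_name) {
    sub <- tt[role == role_name]
    split(sub$id1, sub$group)
  }
  pairs <- tt[role == "pair",
              .(phenotype = group, rsid = id1, gene_id = id2,
                datasets = info)]
  ldp <- tt[role == "ld_pair"]
  ld_pairs <- if (nrow(ldp)) {
    phs <- data.table::tstrsplit(ldp$group, ":", fixed = TRUE)
    data.table::data.table(rsid_a = ldp$id1, rsid_b = ldp$id2,
                           phenotype_a = phs[[1L]], phenotype_b = phs[[2L]])
  } else {
    data.table::data.table(rsid_a = character(), rsid_b = character(),
                           phenotype_a = character(),
                           phenotype_b = character())
  }
  list(
    egenes = split_ids("egene"),
    eqtl_snps = split_ids("eqtl_snp"),
    pairs = pairs,
    shared_egenes = split_ids("shared_egene"),
    cooccur_pathways = split_ids("cooccur_pathway"),
    ld_pairs = ld_pairs
  )
}
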