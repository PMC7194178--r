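# Annotation stage: druggability of eGenes and enriched pathways, and LD
# (r-squared) screening of cross-phenotype eQTL pairs from phased
# haplotypes.

#' Annotate eGene sets with drug-gene interactions
#'
#' @param egene_sets Named list (phenotype -> gene ids).
#' @param dgi Drug-gene interaction table with a `gene_id` column.
#' @return List with `druggable` (phenotype -> druggable gene ids),
#'   `fraction` (druggable share of the union of all eGenes), and
#'   `n_union`.
#' @export
annotate_druggable <- function(egene_sets, dgi) {
  dgi_genes <- unique(data.table::as.data.table(dgi)$gene_id)
  druggable <- lapply(egene_sets, function(g)
    sort(intersect(unique(g), dgi_genes)))
  all_eg <- unique(unlist(egene_sets))
  frac <- if (length(all_eg)) {
    length(intersect(all_eg, dgi_genes)) / length(all_eg)
  } else 0
  list(druggable = druggable, fraction = frac, n_union = length(all_eg))
}

#' Druggable pathways per phenotype, with overlap combinations
#'
#' A pathway is druggable for phenotype P when it is enriched for P and
#' contains at least one druggable eGene of P. Cross-phenotype overlaps of
#' druggable-pathway sets are computed with the usual inclusive
#' intersections, and pairwise overlaps supported by zero shared druggable
#' eGenes are flagged (a pathway can be a shared drug target even when the
#' two phenotypes' druggable genes in it are disjoint).
#'
#' @param enriched_sets Named list (phenotype -> enriched pathway ids).
#' @param pathways Named list of pathway gene vectors.
#' @param druggable_sets Named list (phenotype -> druggable eGene ids).
#' @return List with `druggable_pathways` (phenotype -> pathway ids),
#'   `overlaps` (as [compute_intersections()], `NULL` with < 2 phenotypes),
#'   and `no_shared_gene` (data.table of pairwise shared-druggable-pathway
#'   cases with no shared druggable gene).
#' @export
druggable_pathways <- function(enriched_sets, pathways, druggable_sets) {
  dps <- lapply(names(enriched_sets), function(ph) {
    ids <- enriched_sets[[ph]]
    keep <- vapply(ids, function(pid)
      length(intersect(pathways[[pid]], druggable_sets[[ph]])) > 0L,
      logical(1L))
    sort(ids[keep])
  })
  names(dps) <- names(enriched_sets)
  overlaps <- if (length(dps) >= 2L) compute_intersections(dps) else NULL
  flag_rows <- list()
  if (length(dps) >= 2L) {
    for (pair in combn(names(dps), 2L, simplify = FALSE)) {
      shared_pw <- intersect(dps[[pair[1L]]], dps[[pair[2L]]])
      for (pid in shared_pw) {
        da <- intersect(pathways[[pid]], druggable_sets[[pair[1L]]])
        db <- intersect(pathways[[pid]], druggable_sets[[pair[2L]]])
        if (!length(intersect(da, db))) {
          flag_rows[[length(flag_rows) + 1L]] <- data.table::data.table(
            pathway_id = pid, phenotype_a = pair[1L],
            phenotype_b = pair[2L])
        }
      }
    }
  }
  no_shared <- if (length(flag_rows)) data.table::rbindlist(flag_rows) else
    data.table::data.table(pathway_id = character(),
                           phenotype_a = character(),
                           phenotype_b = character())
  list(druggable_pathways = dps, overlaps = overlaps,
       no_shared_gene = no_shared)
}

#' LD r-squared between two SNPs from phased haplotypes
#'
#' `r2 = D^2 / (pA (1 - pA) pB (1 - pB))` with `D = pAB - pA pB`, all
#' frequencies taken directly from the haplotype matrix (exact, no EM).
#' Symmetric in its arguments and invariant to allele relabelling at
#' either locus. A monomorphic SNP makes r-squared undefined: returned as
#' `NA` with a warning.
#'
#' @param haps Integer 0/1 matrix, haplotypes x SNPs, columns named by
#'   rsid.
#' @param snp_a,snp_b rsids of the two SNPs (must differ).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(haps, snp_a, snp_b) {
  if (identical(snp_a, snp_b)) stop("the two SNPs must differ",
                                    call. = FALSE)
  for (s in c(snp_a, snp_b)) {
    if (!s %in% colnames(haps)) {
      stop(sprintf("SNP '%s' absent from the haplotype matrix", s),
           call. = FALSE)
    }
  }
  if (nrow(haps) < 2L) stop("need at least two haplotypes", call. = FALSE)
  a <- haps[, snp_a]; b <- haps[, snp_b]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    warning(sprintf("monomorphic SNP in pair (%s, %s): r2 undefined",
                    snp_a, snp_b), call. = FALSE)
    return(NA_real_)
  }
  D <- mean(a == 1L & b == 1L) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# pairwise r2 matrix for a set of columns; NA for monomorphic SNPs
ld_r2_matrix <- function(haps, rsids) {
  m <- haps[, rsids, drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  r2 <- suppressWarnings(stats::cor(m))^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  r2
}

#' Screen cross-phenotype eQTL pairs for strong LD
#'
#' Computes r-squared for every pair of eQTL SNPs belonging to different
#' phenotypes on the same chromosome and reports pairs above the
#' threshold. The output annotates (never removes) shared-eGene findings
#' that might be explained by LD rather than independent signals.
#'
#' @param eqtl_snps Named list (phenotype -> rsids of eQTL SNPs).
#' @param haps Haplotype matrix (haplotypes x SNPs).
#' @param snp_info Table with rsid and chrom columns.
#' @param threshold r-squared cut-off in (0, 1] (default 0.8; pairs must
#'   exceed it strictly).
#' @return data.table with rsid_a, rsid_b, phenotype_a, phenotype_b, r2.
#' @export
screen_ld_confounding <- function(eqtl_snps, haps, snp_info,
                                  threshold = 0.8) {
  assert_prob(threshold, "threshold")
  snp_info <- data.table::as.data.table(snp_info)
  ph_of <- rep(names(eqtl_snps), lengths(eqtl_snps))
  names(ph_of) <- unlist(eqtl_snps, use.names = FALSE)
  all_snps <- names(ph_of)
  all_snps <- all_snps[all_snps %in% colnames(haps)]
  chrom_of <- setNames(snp_info$chrom, snp_info$rsid)
  rows <- list()
  for (cn in unique(chrom_of[all_snps])) {
    on_chr <- all_snps[chrom_of[all_snps] == cn]
    if (length(on_chr) < 2L) next
    r2 <- ld_r2_matrix(haps, on_chr)
    idx <- which(upper.tri(r2) & !is.na(r2) & r2 > threshold,
                 arr.ind = TRUE)
    if (!nrow(idx)) next
    a <- on_chr[idx[, 1L]]; b <- on_chr[idx[, 2L]]
    cross <- ph_of[a] != ph_of[b]
    if (!any(cross)) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      rsid_a = a[cross], rsid_b = b[cross],
      phenotype_a = unname(ph_of[a[cross]]),
      phenotype_b = unname(ph_of[b[cross]]),
      r2 = r2[idx][cross])
  }
  if (!length(rows)) {
    return(data.table::data.table(
      rsid_a = character(), rsid_b = character(),
      phenotype_a = character(), phenotype_b = character(),
      r2 = numeric()))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, -r2)
  out[]
}
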