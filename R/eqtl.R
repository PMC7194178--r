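# eQTL stage: join spatial pairs to the association table, correct with
# Benjamini-Hochberg across all tested (SNP, gene, tissue) triples, classify
# cis/trans, and collect per-phenotype eGene sets.

#' Look up association rows for called spatial pairs
#'
#' Returns every (rsid, gene_id, tissue) association row whose (rsid,
#' gene_id) appears in the spatial-pair table; pairs with no association
#' rows are reported separately as untested.
#'
#' @param pairs Spatial-pair table (rsid, gene_id, ...).
#' @param assoc Association table (rsid, gene_id, tissue, pval_nominal).
#' @return List with `tested` (association rows for covered pairs) and
#'   `untested` (pairs absent from the table).
#' @export
query_associations <- function(pairs, assoc) {
  pairs <- unique(data.table::as.data.table(pairs)[, .(rsid, gene_id)])
  assoc <- data.table::as.data.table(assoc)
  if (nrow(pairs) == 0L) {
    return(list(tested = assoc[0L], untested = pairs))
  }
  tested <- merge(assoc, pairs, by = c("rsid", "gene_id"))
  covered <- unique(tested[, .(rsid, gene_id)])
  untested <- data.table::fsetdiff(pairs, covered)
  list(tested = tested[], untested = untested[])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order: `q_i = min over j with p_(j) >= p_(i)
#' of p_(j) * m / rank(j)`, clipped to 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  assert_prob(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Classify SNP-gene associations as cis or trans
#'
#' cis: same chromosome and distance at most `window` (inclusive, per the
#' 1 Mb convention); trans otherwise, including all inter-chromosomal
#' pairs. Distance is 0 when the SNP lies inside the gene body, else the
#' bp gap to the nearest gene edge (gene-body anchor; switch to
#' `anchor = "tss"` to measure from the gene start).
#'
#' @param snp_chrom,snp_pos SNP coordinates (0-based), vectorised.
#' @param gene_chrom,gene_start,gene_end Gene coordinates (0-based
#'   half-open), vectorised.
#' @param window cis window in bp (default 1e6).
#' @param anchor `"gene_body"` (default) or `"tss"`.
#' @return List with `class` (character, "cis"/"trans") and `distance`
#'   (bp; `NA` for inter-chromosomal pairs).
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                               gene_end, window = 1e6,
                               anchor = c("gene_body", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(window > 0)
  if (anchor == "tss") {
    distance <- abs(snp_pos - gene_start)
  } else {
    distance <- ifelse(snp_pos < gene_start, gene_start - snp_pos,
                       ifelse(snp_pos >= gene_end, snp_pos - gene_end + 1L,
                              0L))
  }
  same <- snp_chrom == gene_chrom
  cls <- ifelse(same & distance <= window, "cis", "trans")
  distance[!same] <- NA_real_
  list(class = cls, distance = distance)
}

#' Collect the eGene set from corrected eQTL calls
#'
#' @param calls eQTL call table with rsid, gene_id, q columns (BH applied
#'   jointly over all tested triples of this phenotype/source run).
#' @param phenotype,hic_source Labels recorded on the result.
#' @param alpha FDR threshold (significant when `q < alpha`; default 0.05).
#' @return An `egene_set`: list with phenotype, hic_source, egenes (gene
#'   ids with >=1 significant call) and eqtl_snps (SNPs with >=1
#'   significant call).
#' @export
collect_egenes <- function(calls, phenotype, hic_source = "combined",
                           alpha = 0.05) {
  assert_prob(alpha, "alpha")
  calls <- data.table::as.data.table(calls)
  sig <- calls[q < alpha]
  structure(list(
    phenotype = phenotype, hic_source = hic_source,
    egenes = sort(unique(sig$gene_id)),
    eqtl_snps = sort(unique(sig$rsid))
  ), class = "egene_set")
}

#' @export
print.egene_set <- function(x, ...) {
  cat(sprintf("<egene_set> %s / %s: %d eGenes from %d eQTL SNPs\n",
              x$phenotype, x$hic_source, length(x$egenes),
              length(x$eqtl_snps)))
  invisible(x)
}

#' Run the eQTL stage for one phenotype and Hi-C source
#'
#' Restricts spatial pairs to those supported by `hic_source` ("combined"
#' keeps every pair), joins the association table, applies one joint BH
#' correction across all tested (SNP, gene, tissue) triples (the
#' conservative scope; `scope = "per_tissue"` corrects within each tissue
#' instead), and classifies each call cis/trans.
#'
#' @param pairs Spatial-pair table with a `datasets` column.
#' @param assoc Association table.
#' @param snps SNP table (rsid, chrom, pos).
#' @param genes Gene table (gene_id, chrom, start, end; 0-based).
#' @param phenotype Phenotype label (pairs are assumed pre-filtered to this
#'   phenotype's SNPs).
#' @param hic_source Dataset label or "combined".
#' @param alpha FDR threshold.
#' @param cis_window cis window in bp.
#' @param scope BH correction scope.
#' @return List with `calls` (full call table with q, significant,
#'   cis_trans, distance), `egenes` (an `egene_set`) and `untested` pairs.
#' @export
run_eqtl <- function(pairs, assoc, snps, genes, phenotype,
                     hic_source = "combined", alpha = 0.05,
                     cis_window = 1e6, scope = c("joint", "per_tissue")) {
  scope <- match.arg(scope)
  pairs <- data.table::as.data.table(pairs)
  if (hic_source != "combined") {
    keep <- vapply(strsplit(pairs$datasets, ",", fixed = TRUE),
                   function(d) hic_source %in% d, logical(1L))
    pairs <- pairs[keep]
  }
  qa <- query_associations(pairs, assoc)
  calls <- qa$tested
  if (nrow(calls)) {
    if (scope == "joint") {
      calls[, q := bh_adjust(pval_nominal)]
    } else {
      calls[, q := bh_adjust(pval_nominal), by = tissue]
    }
    calls[, significant := q < alpha]
    snps <- data.table::as.data.table(snps)
    genes <- data.table::as.data.table(genes)
    calls <- merge(calls, snps[, .(rsid, snp_chrom = chrom, snp_pos = pos)],
                   by = "rsid")
    calls <- merge(calls,
                   genes[, .(gene_id, gene_chrom = chrom,
                             gene_start = start, gene_end = end)],
                   by = "gene_id")
    ct <- classify_cis_trans(calls$snp_chrom, calls$snp_pos,
                             calls$gene_chrom, calls$gene_start,
                             calls$gene_end, window = cis_window)
    calls[, cis_trans := ct$class]
    calls[, distance := ct$distance]
    calls[, c("snp_chrom", "snp_pos", "gene_chrom", "gene_start",
              "gene_end") := NULL]
    data.table::setorder(calls, rsid, gene_id, tissue)
  } else {
    calls <- data.table::data.table(
      gene_id = character(), rsid = character(), tissue = character(),
      pval_nominal = numeric(), q = numeric(), significant = logical(),
      cis_trans = character(), distance = numeric())
  }
  list(calls = calls[],
       egenes = collect_egenes(calls, phenotype, hic_source, alpha),
       untested = qa$untested)
}

#' Per-phenotype eQTL / eGene summary table
#'
#' One row per phenotype x Hi-C source: post-threshold SNP count, eQTL SNP
#' count and fraction, eGene count, and the cis/trans partition of
#' significant calls.
#'
#' @param egene_sets List of `egene_set` objects.
#' @param snp_tables Named list (phenotype -> SNP table) of post-threshold
#'   SNPs.
#' @param calls_list List of call tables parallel to `egene_sets`.
#' @return data.table summary.
#' @export
summarize_proportions <- function(egene_sets, snp_tables, calls_list) {
  rows <- lapply(seq_along(egene_sets), function(i) {
    es <- egene_sets[[i]]
    calls <- data.table::as.data.table(calls_list[[i]])
    sig <- calls[significant == TRUE]
    n_snps <- nrow(snp_tables[[es$phenotype]])
    data.table::data.table(
      phenotype = es$phenotype, hic_source = es$hic_source,
      n_snps = n_snps, n_eqtl_snps = length(es$eqtl_snps),
      fraction = if (n_snps > 0) length(es$eqtl_snps) / n_snps else NA_real_,
      n_egenes = length(es$egenes),
      n_cis = sum(sig$cis_trans == "cis"),
      n_trans = sum(sig$cis_trans == "trans"))
  })
  data.table::rbindlist(rows)
}

#' Partition eQTL SNPs by supporting Hi-C dataset
#'
#' For exactly two Hi-C sources, splits each phenotype's eQTL SNPs into
#' source-A-only, source-B-only and both; the three counts sum to the size
#' of the union.
#'
#' @param egene_sets List of `egene_set` objects from per-dataset runs
#'   (exclude the "combined" source).
#' @return data.table with phenotype, only_<A>, only_<B>, both.
#' @export
partition_by_dataset <- function(egene_sets) {
  srcs <- unique(vapply(egene_sets, function(e) e$hic_source,
                        character(1L)))
  srcs <- setdiff(srcs, "combined")
  if (length(srcs) != 2L) {
    stop(paste0("dataset partition requires results from exactly two Hi-C ",
                "sources; run the eQTL stage for both datasets"),
         call. = FALSE)
  }
  phenos <- unique(vapply(egene_sets, function(e) e$phenotype,
                          character(1L)))
  rows <- lapply(phenos, function(ph) {
    get_set <- function(src) {
      for (e in egene_sets) {
        if (e$phenotype == ph && e$hic_source == src) return(e$eqtl_snps)
      }
      character(0)
    }
    a <- get_set(srcs[1L]); b <- get_set(srcs[2L])
    data.table::data.table(
      phenotype = ph,
      only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
      both = length(intersect(a, b)))
  })
  out <- data.table::rbindlist(rows)
  data.table::setnames(out, c("only_a", "only_b"),
                       paste0("only_", srcs))
  out[]
}
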