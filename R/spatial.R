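# Spatial mapping stage: SNPs and genes are assigned to restriction
# fragments, and SNP-gene pairs are called from per-dataset Hi-C contact
# lists. Interval work is delegated to GenomicRanges/IRanges.

#' Filter a SNP table at a significance threshold
#'
#' Retains rows with `assoc_p <= alpha` (boundary inclusive), preserving
#' input order. Warns (does not error) when nothing survives.
#'
#' @param snps SNP table with an `assoc_p` column.
#' @param alpha Threshold in (0, 1]; defaults to the suggestive GWAS level
#'   5e-6.
#' @return The filtered table.
#' @export
filter_snps_by_significance <- function(snps, alpha = 5e-6) {
  assert_prob(alpha, "alpha")
  snps <- data.table::as.data.table(snps)
  out <- snps[assoc_p <= alpha]
  if (nrow(out) == 0L) {
    warning("no SNPs pass the significance threshold", call. = FALSE)
  }
  out[]
}

#' Assign SNPs or genes to restriction fragments
#'
#' A SNP maps to the single fragment containing its position (half-open:
#' a SNP on a fragment boundary belongs to the right-hand fragment). A gene
#' maps to every fragment overlapping `[start, end)`.
#'
#' @param x SNP table (rsid, chrom, pos) or gene table (gene_id, chrom,
#'   start, end); coordinates 0-based.
#' @param fragments Fragment table (frag_id, chrom, start, end), tiling
#'   each referenced chromosome.
#' @param what `"snp"` or `"gene"`.
#' @return data.table mapping each record to its fragment(s).
#' @export
assign_to_fragments <- function(x, fragments, what = c("snp", "gene")) {
  what <- match.arg(what)
  x <- data.table::as.data.table(x)
  fragments <- data.table::as.data.table(fragments)
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(fragments$start + 1L, fragments$end))
  if (what == "snp") {
    q_gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$pos + 1L, width = 1L))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q_gr, frag_gr))
    covered <- S4Vectors::queryHits(hits)
    missing <- setdiff(seq_len(nrow(x)), covered)
    if (length(missing)) {
      stop(sprintf(
        "SNP(s) outside the fragment map: %s",
        paste(x$rsid[head(missing, 5L)], collapse = ", ")), call. = FALSE)
    }
    out <- data.table::data.table(
      rsid = x$rsid[covered],
      frag_id = fragments$frag_id[S4Vectors::subjectHits(hits)])
    if (anyDuplicated(out$rsid)) {
      stop("fragment map is not disjoint: a SNP matched several fragments",
           call. = FALSE)
    }
  } else {
    q_gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1L, x$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q_gr, frag_gr))
    covered <- unique(S4Vectors::queryHits(hits))
    missing <- setdiff(seq_len(nrow(x)), covered)
    if (length(missing)) {
      stop(sprintf(
        "gene(s) outside the fragment map: %s",
        paste(x$gene_id[head(missing, 5L)], collapse = ", ")),
        call. = FALSE)
    }
    out <- data.table::data.table(
      gene_id = x$gene_id[S4Vectors::queryHits(hits)],
      frag_id = fragments$frag_id[S4Vectors::subjectHits(hits)])
  }
  out[]
}

#' Call SNP-gene pairs supported by Hi-C contacts
#'
#' A (SNP, gene) pair is supported by dataset `d` when `d`'s contact list
#' contains the unordered fragment pair (SNP fragment, any gene fragment),
#' or when the SNP's fragment itself overlaps the gene (self-fragment rule:
#' proximity ligation cannot report within-fragment contacts, so a SNP
#' sitting in a gene's own fragment is treated as spatially connected;
#' disable with `self_contact = FALSE`). Contact counts are ignored
#' (presence/absence only) and adjacency confers no support.
#'
#' @param snp_frags SNP-fragment assignment (rsid, frag_id), from
#'   [assign_to_fragments()]; extra columns (e.g. phenotype) are carried
#'   through.
#' @param gene_frags Gene-fragment assignment (gene_id, frag_id).
#' @param contacts Named list of per-dataset contact tables (frag_a,
#'   frag_b) in canonical unordered form; orientation and row order do not
#'   affect the result.
#' @param self_contact Apply the self-fragment rule (default `TRUE`).
#' @param fragments Optional fragment table; when supplied, contact rows
#'   naming a fragment id absent from it raise an error.
#' @return data.table with rsid, gene_id, datasets (comma-joined sorted
#'   dataset labels); pairs with no support are absent.
#' @export
call_spatial_pairs <- function(snp_frags, gene_frags, contacts,
                               self_contact = TRUE, fragments = NULL) {
  snp_frags <- data.table::as.data.table(snp_frags)
  gene_frags <- data.table::as.data.table(gene_frags)
  universe <- if (!is.null(fragments)) {
    data.table::as.data.table(fragments)$frag_id
  }
  pieces <- list()

  for (ds in names(contacts)) {
    ct <- data.table::as.data.table(contacts[[ds]])
    if (nrow(ct)) {
      if (!is.null(universe)) {
        unknown <- setdiff(unique(c(ct$frag_a, ct$frag_b)), universe)
        if (length(unknown)) {
          stop(sprintf("unknown fragment id(s) in contact list '%s': %s",
                       ds, paste(head(unknown, 5L), collapse = ", ")),
               call. = FALSE)
        }
      }
      cp <- canonical_pair(ct$frag_a, ct$frag_b)
      ct <- unique(data.table::data.table(frag_a = cp$a, frag_b = cp$b))
      # join in both orientations: SNP fragment on either side
      left <- merge(snp_frags[, .(rsid, frag_id)], ct,
                    by.x = "frag_id", by.y = "frag_a",
                    allow.cartesian = TRUE)
      left <- merge(left, gene_frags, by.x = "frag_b", by.y = "frag_id",
                    allow.cartesian = TRUE)
      right <- merge(snp_frags[, .(rsid, frag_id)], ct,
                     by.x = "frag_id", by.y = "frag_b",
                     allow.cartesian = TRUE)
      right <- merge(right, gene_frags, by.x = "frag_a", by.y = "frag_id",
                     allow.cartesian = TRUE)
      found <- unique(rbind(left[, .(rsid, gene_id)],
                            right[, .(rsid, gene_id)]))
      if (nrow(found)) {
        found[, dataset := ds]
        pieces[[length(pieces) + 1L]] <- found
      }
    }
    if (self_contact) {
      selfp <- merge(snp_frags[, .(rsid, frag_id)], gene_frags,
                     by = "frag_id", allow.cartesian = TRUE)
      if (nrow(selfp)) {
        selfp <- unique(selfp[, .(rsid, gene_id)])
        selfp[, dataset := ds]
        pieces[[length(pieces) + 1L]] <- selfp
      }
    }
  }
  if (!length(pieces)) {
    return(data.table::data.table(rsid = character(),
                                  gene_id = character(),
                                  datasets = character()))
  }
  all_pairs <- unique(data.table::rbindlist(pieces))
  out <- all_pairs[, .(datasets = paste(sort(unique(dataset)),
                                        collapse = ",")),
                   by = .(rsid, gene_id)]
  data.table::setorder(out, rsid, gene_id)
  out[]
}

#' Genes captured as having any spatial contact
#'
#' The "spatially contacted genes" background used for the conservative
#' overlap bootstrap: every gene appearing in at least one called spatial
#' pair.
#'
#' @param pairs A spatial-pair table from [call_spatial_pairs()].
#' @return Sorted character vector of gene ids.
#' @export
spatial_gene_background <- function(pairs) {
  sort(unique(data.table::as.data.table(pairs)$gene_id))
}
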