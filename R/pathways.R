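# Pathway stage: hypergeometric over-representation of each phenotype's
# eGene set, cross-phenotype pathway overlap with a bootstrap null over
# pathway space, and classification of shared pathways by shared vs
# condition-specific eGene co-occurrence.

#' Hypergeometric over-representation analysis of a gene set
#'
#' For each pathway, the exact upper-tail probability of observing `k`
#' eGenes among the pathway's `K` universe members in a draw of `n` genes
#' from a universe of `N`, with BH correction across all pathways tested.
#' The default universe is every gene annotated to at least one pathway
#' (the standard conservative ORA choice); eGenes outside the universe are
#' dropped with a warning.
#'
#' @param egenes Character vector of gene ids.
#' @param pathways Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe Optional character vector; defaults to the union of all
#'   pathway members.
#' @param alpha FDR threshold for the enriched flag (default 0.05).
#' @return data.table with pathway_id, k, K, n, N, p, q, enriched.
#' @export
ora_enrich <- function(egenes, pathways, universe = NULL, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  if (is.null(universe)) universe <- unique(unlist(pathways))
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  egenes <- unique(egenes)
  outside <- setdiff(egenes, universe)
  if (length(outside)) {
    warning(sprintf("%d eGene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    egenes <- intersect(egenes, universe)
  }
  N <- length(universe)
  n <- length(egenes)
  K <- vapply(pathways, function(g) length(intersect(g, universe)),
              integer(1L))
  k <- vapply(pathways, function(g) length(intersect(g, egenes)),
              integer(1L))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.table::data.table(
    pathway_id = names(pathways), k = k, K = K, n = n, N = N, p = p,
    q = if (length(p)) bh_adjust(p) else numeric(0))
  out[, enriched := q < alpha]
  out[]
}

#' Cross-phenotype overlap counts of enriched pathways
#'
#' Same inclusive-intersection semantics as the eGene overlap, applied to
#' per-phenotype enriched-pathway id sets.
#'
#' @param enriched_sets Named list (phenotype -> pathway ids).
#' @return As [compute_intersections()].
#' @export
pathway_overlaps <- function(enriched_sets) {
  compute_intersections(enriched_sets)
}

#' Bootstrap null for a pathway overlap
#'
#' Identical machinery to [bootstrap_overlap()] with pathway ids as the
#' sampled elements: replicates draw uniform random pathway sets of the
#' observed sizes from the pathway background (all pathways, or the
#' restricted background of pathways containing at least one identified
#' eGene).
#'
#' @inheritParams bootstrap_overlap
#' @param pathway_background Character vector of pathway ids.
#' @export
bootstrap_pathway_overlap <- function(set_sizes, pathway_background,
                                      observed, n_boot = 10000L, seed = 1L,
                                      background_label = "all_pathways") {
  bootstrap_overlap(set_sizes, pathway_background, observed,
                    n_boot = n_boot, seed = seed,
                    background_label = background_label)
}

#' Classify a shared pathway by what drives its co-occurrence
#'
#' Within a combination, a pathway member gene is a "shared" hit when it
#' belongs to the eGene sets of at least two member phenotypes.
#' `condition_specific`: no hit gene is shared; `shared_egenes`: every hit
#' gene is shared; `mixed`: both kinds present. The pathway must be
#' enriched for every member phenotype.
#'
#' @param pathway_id Pathway identifier.
#' @param pathway_genes Character vector of the pathway's member genes.
#' @param combination Character vector of phenotype labels.
#' @param egene_sets Named list (phenotype -> gene ids) covering the
#'   combination.
#' @param enriched_sets Named list (phenotype -> enriched pathway ids) used
#'   to enforce the precondition.
#' @return A `shared_pathway_record`: pathway_id, combination,
#'   driver_class, egene_breakdown (phenotype -> hit genes).
#' @export
classify_shared_pathway <- function(pathway_id, pathway_genes, combination,
                                    egene_sets, enriched_sets) {
  not_enriched <- combination[!vapply(combination, function(ph)
    pathway_id %in% enriched_sets[[ph]], logical(1L))]
  if (length(not_enriched)) {
    stop(sprintf("pathway '%s' is not enriched for: %s", pathway_id,
                 paste(not_enriched, collapse = ", ")), call. = FALSE)
  }
  hits <- lapply(combination, function(ph)
    intersect(pathway_genes, egene_sets[[ph]]))
  names(hits) <- combination
  all_hits <- unlist(hits, use.names = FALSE)
  hit_counts <- table(all_hits)
  shared_genes <- names(hit_counts)[hit_counts >= 2L]
  uniq_hits <- unique(all_hits)
  driver_class <- if (!length(shared_genes)) {
    "condition_specific"
  } else if (length(shared_genes) == length(uniq_hits)) {
    "shared_egenes"
  } else {
    "mixed"
  }
  structure(list(
    pathway_id = pathway_id, combination = combination,
    driver_class = driver_class, egene_breakdown = hits
  ), class = "shared_pathway_record")
}

#' @export
print.shared_pathway_record <- function(x, ...) {
  cat(sprintf("<shared_pathway_record> %s | %s | %s\n", x$pathway_id,
              combo_label(x$combination), x$driver_class))
  invisible(x)
}
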