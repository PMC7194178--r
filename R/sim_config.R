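#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator with validated defaults. The
#' defaults describe the study conditions the pipeline is exercised under:
#' four phenotypes with 179, 18, 285 and 135 suggestively associated SNPs
#' (GS, MG, MS, ALS), a suggestive GWAS threshold of 5e-6, two Hi-C contact
#' datasets of very different density (immortalised cell lines vs psoas
#' muscle, the latter roughly ten-fold sparser), 48 eQTL tissues, 536
#' pathways, and a 13% druggable-gene fraction.
#'
#' @param seed Integer master seed; every generator stage derives its own
#'   stream from it via [stable_hash()], so identical configs produce
#'   byte-identical output files.
#' @param n_chromosomes Number of chromosomes in the toy genome.
#' @param chrom_length Chromosome length in bp (all chromosomes equal).
#' @param fragment_mean_length Mean restriction-fragment length in bp.
#' @param n_genes Number of genes placed (non-overlapping) on the genome.
#' @param gene_length_range Length-2 numeric, min/max gene length in bp.
#' @param phenotypes Named integer vector: SNP count per phenotype.
#' @param gwas_p_threshold Suggestive association threshold; every emitted
#'   SNP satisfies `assoc_p <= gwas_p_threshold`.
#' @param planted_eqtl_fraction Proportion of each phenotype's SNPs that are
#'   true eQTLs; scalar or named per phenotype. Default (`NULL`): 0.8,
#'   lowered to 0.45 for a phenotype labelled "ALS".
#' @param planted_shared_egenes Named list mapping combination labels
#'   (e.g. `"GS:MS"`) to the number of eGenes planted as shared by exactly
#'   that combination. Default (`NULL`): a standard map over the GS/MG/MS/
#'   ALS labels (filtered to the labels present), or 2 genes shared by the
#'   first two phenotypes for custom labels.
#' @param cis_fraction Probability that a planted eGene is placed within the
#'   cis window (1 Mb) of its eQTL SNP.
#' @param n_tissues Number of tissues in the association table.
#' @param n_pathways Number of gene sets in the GMT collection.
#' @param pathway_size_range Length-2 integer, min/max pathway size.
#' @param planted_pathway_cooccurrence Named list mapping combination labels
#'   to the number of pathways planted to contain condition-specific eGenes
#'   from every member phenotype (and no shared eGenes). Default (`NULL`):
#'   3 pathways co-occurring across all phenotypes.
#' @param planted_pathway_hits Target number of condition-specific eGenes
#'   contributed per phenotype to each planted pathway (capped by
#'   availability).
#' @param druggable_fraction Per-gene probability of having at least one
#'   drug-gene interaction row.
#' @param n_haplotypes Number of phased haplotypes (must be even).
#' @param ld_block_length LD block size in bp; SNPs within a block share an
#'   ancestral haplotype copied with noise.
#' @param ld_block_flip Per-allele copy error within an LD block
#'   (keeps background within-block r-squared well below 0.8).
#' @param planted_ld_flip Copy error for planted high-LD pairs; both SNPs
#'   copy a shared base haplotype, so the expected r-squared is
#'   `(1 - 2 * flip)^4` (0.01 gives about 0.92).
#' @param planted_ld_pairs Number of planted cross-phenotype high-LD SNP
#'   pairs on a shared chromosome.
#' @param datasets Named list of Hi-C datasets; each value is a
#'   contact-density multiplier, either a scalar or a named vector per
#'   phenotype (a multiplier of 0 removes that dataset's support for the
#'   phenotype's planted pairs).
#' @param dataset_specific_fraction Fraction of planted SNP-gene pairs whose
#'   Hi-C support is confined to a single dataset (chosen with probability
#'   proportional to the density multipliers).
#' @param background_contacts_per_fragment Expected number of random
#'   background contacts per fragment in a dataset with multiplier 1.
#' @param decoys_per_snp Number of decoy (non-eQTL) genes paired with each
#'   SNP in the association table.
#' @param tested_decoy_fraction Fraction of decoy pairs that also receive a
#'   Hi-C contact, so they reach the eQTL stage and give the FDR correction
#'   a realistic denominator.
#' @param decoy_p_min Lower bound of the Uniform distribution used for decoy
#'   and non-significant p-values (0 = standard uniform).
#' @param sig_p_range Range of planted significant nominal p-values (drawn
#'   log-uniformly).
#' @param noise_free If `TRUE`, decoy p-values are drawn from
#'   Uniform(0.1, 1), so no decoy can survive FDR < 0.05 and the pipeline
#'   recovers the planted truth exactly.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 6L,
                       chrom_length = 2.5e6,
                       fragment_mean_length = 4000,
                       n_genes = 3000L,
                       gene_length_range = c(1000, 5000),
                       phenotypes = c(GS = 179L, MG = 18L, MS = 285L,
                                      ALS = 135L),
                       gwas_p_threshold = 5e-6,
                       planted_eqtl_fraction = NULL,
                       planted_shared_egenes = NULL,
                       cis_fraction = 0.95,
                       n_tissues = 48L,
                       n_pathways = 536L,
                       pathway_size_range = c(10L, 60L),
                       planted_pathway_cooccurrence = NULL,
                       planted_pathway_hits = 15L,
                       druggable_fraction = 0.13,
                       n_haplotypes = 1000L,
                       ld_block_length = 50000,
                       ld_block_flip = 0.15,
                       planted_ld_flip = 0.01,
                       planted_ld_pairs = 1L,
                       datasets = list(cellline = 1.0, muscle = 0.1),
                       dataset_specific_fraction = 0.2,
                       background_contacts_per_fragment = 2,
                       decoys_per_snp = 10L,
                       tested_decoy_fraction = 0.6,
                       decoy_p_min = 0,
                       sig_p_range = c(1e-10, 1e-6),
                       noise_free = FALSE) {
  if (isTRUE(noise_free) && missing(decoy_p_min)) decoy_p_min <- 0.1
  ph_names <- names(phenotypes)
  if (is.null(planted_eqtl_fraction)) {
    # ~80% of GS/MG/MS SNPs are eQTLs, under 50% for ALS
    planted_eqtl_fraction <- setNames(rep(0.8, length(phenotypes)),
                                      ph_names)
    if ("ALS" %in% ph_names) planted_eqtl_fraction[["ALS"]] <- 0.45
  }
  if (is.null(planted_shared_egenes)) {
    std <- list("GS:MG" = 4L, "GS:MS" = 30L, "GS:ALS" = 5L, "MG:MS" = 4L,
                "MS:ALS" = 2L, "MG:ALS" = 1L, "GS:MS:ALS" = 2L)
    keep <- vapply(names(std), function(cmb)
      all(parse_combo(cmb) %in% ph_names), logical(1L))
    planted_shared_egenes <- std[keep]
    if (!length(planted_shared_egenes) && length(phenotypes) >= 2L) {
      planted_shared_egenes <- setNames(list(2L),
                                        combo_label(ph_names[1:2]))
    }
  }
  if (is.null(planted_pathway_cooccurrence)) {
    planted_pathway_cooccurrence <- if (length(phenotypes) >= 2L) {
      setNames(list(3L), combo_label(ph_names))
    } else {
      list()
    }
  }
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length,
    fragment_mean_length = fragment_mean_length,
    n_genes = as.integer(n_genes), gene_length_range = gene_length_range,
    phenotypes = phenotypes, gwas_p_threshold = gwas_p_threshold,
    planted_eqtl_fraction = planted_eqtl_fraction,
    planted_shared_egenes = planted_shared_egenes,
    cis_fraction = cis_fraction, n_tissues = as.integer(n_tissues),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    planted_pathway_cooccurrence = planted_pathway_cooccurrence,
    planted_pathway_hits = as.integer(planted_pathway_hits),
    druggable_fraction = druggable_fraction,
    n_haplotypes = as.integer(n_haplotypes),
    ld_block_length = ld_block_length,
    ld_block_flip = ld_block_flip, planted_ld_flip = planted_ld_flip,
    planted_ld_pairs = as.integer(planted_ld_pairs),
    datasets = datasets,
    dataset_specific_fraction = dataset_specific_fraction,
    background_contacts_per_fragment = background_contacts_per_fragment,
    decoys_per_snp = as.integer(decoys_per_snp),
    tested_decoy_fraction = tested_decoy_fraction,
    decoy_p_min = decoy_p_min, sig_p_range = sig_p_range,
    noise_free = isTRUE(noise_free)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_count(cfg$n_chromosomes, "n_chromosomes")
  assert_count(cfg$chrom_length, "chrom_length")
  assert_count(cfg$n_genes, "n_genes")
  assert_count(cfg$n_tissues, "n_tissues")
  assert_count(cfg$n_pathways, "n_pathways")
  assert_count(cfg$n_haplotypes, "n_haplotypes")
  if (cfg$n_haplotypes %% 2L != 0L) {
    stop("`n_haplotypes` must be even (haplotypes are paired into samples)",
         call. = FALSE)
  }
  if (is.null(names(cfg$phenotypes)) || any(names(cfg$phenotypes) == "")) {
    stop("`phenotypes` must be a named vector of SNP counts", call. = FALSE)
  }
  assert_count(cfg$phenotypes, "phenotypes")
  assert_prob(cfg$gwas_p_threshold, "gwas_p_threshold")
  assert_prob(cfg$planted_eqtl_fraction, "planted_eqtl_fraction",
              open_zero = FALSE)
  assert_prob(cfg$druggable_fraction, "druggable_fraction",
              open_zero = FALSE)
  assert_prob(cfg$cis_fraction, "cis_fraction", open_zero = FALSE)
  assert_prob(cfg$dataset_specific_fraction, "dataset_specific_fraction",
              open_zero = FALSE)
  assert_prob(cfg$tested_decoy_fraction, "tested_decoy_fraction",
              open_zero = FALSE)
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L]) {
    stop("`pathway_size_range` must be an increasing pair", call. = FALSE)
  }
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1L] > cfg$gene_length_range[2L]) {
    stop("`gene_length_range` must be an increasing pair", call. = FALSE)
  }
  if (is.null(names(cfg$datasets)) || !length(cfg$datasets)) {
    stop("`datasets` must be a named list of density multipliers",
         call. = FALSE)
  }
  ne <- planted_egene_counts(cfg)
  for (cmb in names(cfg$planted_shared_egenes)) {
    members <- parse_combo(cmb)
    if (!all(members %in% names(cfg$phenotypes))) {
      stop(sprintf("combination '%s' names unknown phenotypes", cmb),
           call. = FALSE)
    }
    shared_tot <- shared_count_per_phenotype(cfg)
    over <- names(shared_tot)[shared_tot > ne[names(shared_tot)]]
    if (length(over)) {
      stop(sprintf(
        "planted shared eGene counts exceed planted eGene count for: %s",
        paste(over, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(cfg)
}

# planted true-eQTL SNP count (== planted eGene count) per phenotype
planted_egene_counts <- function(cfg) {
  frac <- cfg$planted_eqtl_fraction
  if (length(frac) == 1L) {
    frac <- setNames(rep(frac, length(cfg$phenotypes)),
                     names(cfg$phenotypes))
  }
  miss <- setdiff(names(cfg$phenotypes), names(frac))
  if (length(miss)) {
    stop(sprintf("planted_eqtl_fraction has no entry for: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  round(frac[names(cfg$phenotypes)] * cfg$phenotypes)
}

shared_count_per_phenotype <- function(cfg) {
  tot <- setNames(rep(0L, length(cfg$phenotypes)), names(cfg$phenotypes))
  for (cmb in names(cfg$planted_shared_egenes)) {
    for (m in parse_combo(cmb)) {
      tot[m] <- tot[m] + cfg$planted_shared_egenes[[cmb]]
    }
  }
  tot
}

# density multiplier of dataset `ds` for phenotype `ph` (scalar or named)
dataset_multiplier <- function(cfg, ds, ph) {
  m <- cfg$datasets[[ds]]
  if (length(m) == 1L && is.null(names(m))) return(as.numeric(m))
  if (!ph %in% names(m)) {
    stop(sprintf("dataset '%s' multiplier has no entry for phenotype '%s'",
                 ds, ph), call. = FALSE)
  }
  as.numeric(m[[ph]])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosomes x %g bp, %d genes, fragments ~%g bp\n",
              x$n_chromosomes, x$chrom_length, x$n_genes,
              x$fragment_mean_length))
  cat(sprintf("  phenotypes: %s\n",
              paste(sprintf("%s=%d", names(x$phenotypes), x$phenotypes),
                    collapse = ", ")))
  cat(sprintf("  datasets: %s\n", paste(names(x$datasets), collapse = ", ")))
  cat(sprintf("  seed %d | noise_free %s\n", x$seed, x$noise_free))
  invisible(x)
}
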