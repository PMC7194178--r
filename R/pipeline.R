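# End-to-end orchestration: simulate -> map -> eqtl -> overlap -> pathways
# -> annotate, from one validated config, with a machine-readable report
# and bit-reproducible outputs under a fixed seed.

#' Build a pipeline run configuration
#'
#' Thresholds default to the analysis' standard values: suggestive GWAS
#' threshold 5e-6, FDR 0.05, cis window 1 Mb, 10,000 bootstrap replicates,
#' LD r-squared threshold 0.8.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param input_dir Directory holding the pipeline inputs (genes.tsv,
#'   fragments.bed, snps_*.tsv, contacts_*.tsv, eqtl_associations.tsv,
#'   pathways.gmt, dgi.tsv, haplotypes.vcf). Ignored when `simulate` is
#'   `TRUE`, in which case inputs are generated under `out_dir/inputs`.
#' @param simulate Generate synthetic inputs first.
#' @param sim A [sim_config()] used when `simulate` is `TRUE`.
#' @param alpha_fdr FDR threshold for eQTL calls and pathway enrichment.
#' @param gwas_alpha SNP inclusion threshold.
#' @param cis_window cis/trans window in bp.
#' @param n_boot Bootstrap replicates for overlap nulls.
#' @param ld_threshold r-squared threshold for LD screening.
#' @param seed Master seed for every stochastic stage.
#' @param self_contact Apply the self-fragment rule in spatial mapping.
#' @param bh_scope BH correction scope, `"joint"` or `"per_tissue"`.
#' @return A validated `run_config` object.
#' @export
run_config <- function(out_dir, input_dir = NULL, simulate = is.null(input_dir),
                       sim = sim_config(seed = seed), alpha_fdr = 0.05,
                       gwas_alpha = 5e-6, cis_window = 1e6,
                       n_boot = 10000L, ld_threshold = 0.8, seed = 1L,
                       self_contact = TRUE,
                       bh_scope = c("joint", "per_tissue")) {
  bh_scope <- match.arg(bh_scope)
  assert_prob(alpha_fdr, "alpha_fdr")
  assert_prob(gwas_alpha, "gwas_alpha")
  assert_prob(ld_threshold, "ld_threshold")
  stopifnot(cis_window > 0, n_boot >= 1)
  if (!simulate && is.null(input_dir)) {
    stop("supply `input_dir` or set `simulate = TRUE`", call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, input_dir = input_dir, simulate = simulate,
    sim = sim, alpha_fdr = alpha_fdr, gwas_alpha = gwas_alpha,
    cis_window = cis_window, n_boot = as.integer(n_boot),
    ld_threshold = ld_threshold, seed = as.integer(seed),
    self_contact = isTRUE(self_contact), bh_scope = bh_scope
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys map to [run_config()] arguments; an optional `sim`
#' section maps to [sim_config()] arguments. Arguments supplied via `...`
#' (e.g. from CLI flags) override file values.
#'
#' @param path YAML file path.
#' @param ... Overrides for individual config keys.
#' @export
load_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$sim) && is.list(raw$sim)) {
    sim_args <- raw$sim
    if (is.null(sim_args$seed) && !is.null(raw$seed)) {
      sim_args$seed <- raw$seed
    }
    if (!is.null(sim_args$phenotypes)) {
      sim_args$phenotypes <- unlist(sim_args$phenotypes)
    }
    raw$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, raw)
}

#' Referential-integrity validation of pipeline inputs
#'
#' Checks coordinates, id resolution and file consistency across all input
#' files. Issues are classified `fatal` (malformed records that would
#' corrupt the analysis: coordinates out of bounds, unresolvable fragment
#' ids, broken fragment tiling) or `warning` (recoverable: GMT or DGI
#' entries naming unknown genes, which are dropped downstream).
#'
#' @param input_dir Directory of pipeline inputs.
#' @return data.table with `severity` and `message`; zero rows for a clean
#'   input set.
#' @export
validate_inputs <- function(input_dir) {
  issues <- list()
  note <- function(severity, msg) {
    issues[[length(issues) + 1L]] <<- data.table::data.table(
      severity = severity, message = msg)
  }
  genes <- read_genes(file.path(input_dir, "genes.tsv"))
  fragments <- read_fragments_bed(file.path(input_dir, "fragments.bed"))
  if (any(genes$start >= genes$end)) {
    bad <- which(genes$start >= genes$end)
    note("fatal", sprintf("gene table line %d: start >= end", bad[1L]))
  }
  for (cn in unique(fragments$chrom)) {
    fc <- fragments[chrom == cn][order(start)]
    if (fc$start[1L] != 0L ||
        (nrow(fc) > 1L && any(fc$start[-1L] != fc$end[-nrow(fc)]))) {
      note("fatal", sprintf("fragment map does not tile %s", cn))
    }
  }
  chrom_ends <- fragments[, .(end = max(end)), by = chrom]
  ends <- setNames(chrom_ends$end, chrom_ends$chrom)
  snp_files <- list.files(input_dir, pattern = "^snps_.*\\.tsv$",
                          full.names = TRUE)
  all_snps <- data.table::rbindlist(lapply(snp_files, read_snps))
  for (i in seq_len(nrow(all_snps))) {
    cn <- all_snps$chrom[i]
    if (!cn %in% names(ends)) {
      note("fatal", sprintf("SNP %s on unknown chromosome %s (line %d)",
                            all_snps$rsid[i], cn, i))
    } else if (all_snps$pos[i] < 0L || all_snps$pos[i] >= ends[[cn]]) {
      note("fatal", sprintf("SNP %s beyond chromosome end (line %d)",
                            all_snps$rsid[i], i))
    }
  }
  contact_files <- list.files(input_dir, pattern = "^contacts_.*\\.tsv$",
                              full.names = TRUE)
  frag_ids <- fragments$frag_id
  for (cf in contact_files) {
    ct <- read_contacts(cf)
    unknown <- setdiff(unique(c(ct$frag_a, ct$frag_b)), frag_ids)
    if (length(unknown)) {
      note("fatal", sprintf("%s: unknown fragment id %s", basename(cf),
                            unknown[1L]))
    }
  }
  gmt_path <- file.path(input_dir, "pathways.gmt")
  if (file.exists(gmt_path)) {
    pw <- read_gmt(gmt_path)
    unknown <- setdiff(unique(unlist(pw)), genes$gene_id)
    if (length(unknown)) {
      note("warning", sprintf(
        "pathways.gmt references %d unknown gene(s); they are dropped",
        length(unknown)))
    }
  }
  dgi_path <- file.path(input_dir, "dgi.tsv")
  if (file.exists(dgi_path)) {
    dgi <- read_dgi(dgi_path)
    unknown <- setdiff(unique(dgi$gene_id), genes$gene_id)
    if (length(unknown)) {
      note("warning", sprintf(
        "dgi.tsv references %d unknown gene(s)", length(unknown)))
    }
  }
  assoc_path <- file.path(input_dir, "eqtl_associations.tsv")
  if (file.exists(assoc_path)) {
    assoc <- read_eqtl_table(assoc_path)
    if (any(assoc$pval_nominal <= 0 | assoc$pval_nominal > 1)) {
      note("fatal", "eqtl_associations.tsv: p-value outside (0, 1]")
    }
  }
  if (!length(issues)) {
    return(data.table::data.table(severity = character(),
                                  message = character()))
  }
  data.table::rbindlist(issues)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> validate -> spatial mapping -> eQTL +
#' FDR -> eGene overlap bootstrap (two backgrounds) -> pathway ORA,
#' overlap and classification -> druggability + LD screening, writing all
#' stage artifacts plus `report.json` and a `MANIFEST` under
#' `config$out_dir`. Rerunning with an identical config and seed
#' reproduces every stochastic output bit-identically. A stage failure
#' aborts with the failing stage named; completed artifacts are kept and
#' the MANIFEST records the incomplete state.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report list (also serialised to report.json).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "MANIFEST")
  done <- character(0)
  mark <- function(stage) {
    done <<- c(done, stage)
    writeLines(c(sprintf("stage\t%s\tcomplete", done)), manifest_path)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(sprintf("stage\t%s\tcomplete", done),
                   sprintf("stage\t%s\tFAILED", stage),
                   "run\tincomplete"), manifest_path)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  report <- list(software = "spatialmorbid",
                 version = as.character(utils::packageVersion("spatialmorbid")),
                 seed = config$seed)

  # -- inputs -----------------------------------------------------------
  input_dir <- config$input_dir
  if (config$simulate) {
    input_dir <- file.path(out_dir, "inputs")
    run_stage("simulate", simulate_dataset(config$sim, input_dir))
    mark("simulate")
  }
  req <- c("genes.tsv", "fragments.bed", "eqtl_associations.tsv")
  for (f in req) {
    if (!file.exists(file.path(input_dir, f))) {
      stop(sprintf("stage 'load' failed: missing input file %s",
                   file.path(input_dir, f)), call. = FALSE)
    }
  }
  loaded <- run_stage("load", {
    genes <- read_genes(file.path(input_dir, "genes.tsv"))
    fragments <- read_fragments_bed(file.path(input_dir, "fragments.bed"))
    snp_files <- list.files(input_dir, pattern = "^snps_.*\\.tsv$",
                            full.names = TRUE)
    if (!length(snp_files)) stop("no snps_*.tsv files found")
    snps <- data.table::rbindlist(lapply(snp_files, read_snps))
    contact_files <- list.files(input_dir, pattern = "^contacts_.*\\.tsv$",
                                full.names = TRUE)
    if (!length(contact_files)) stop("no contacts_*.tsv files found")
    contacts <- lapply(contact_files, read_contacts)
    names(contacts) <- sub("^contacts_(.*)\\.tsv$", "\\1",
                           basename(contact_files))
    assoc <- read_eqtl_table(file.path(input_dir, "eqtl_associations.tsv"))
    pathways <- read_gmt(file.path(input_dir, "pathways.gmt"))
    dgi <- read_dgi(file.path(input_dir, "dgi.tsv"))
    list(genes = genes, fragments = fragments, snps = snps,
         contacts = contacts, assoc = assoc, pathways = pathways,
         dgi = dgi)
  })
  mark("load")
  issues <- run_stage("validate", validate_inputs(input_dir))
  if (any(issues$severity == "fatal")) {
    stop(sprintf("stage 'validate' failed: %s",
                 issues[severity == "fatal"]$message[1L]), call. = FALSE)
  }
  for (msg in issues[severity == "warning"]$message) {
    warning(msg, call. = FALSE)
  }
  mark("validate")
  genes <- loaded$genes; fragments <- loaded$fragments
  snps <- loaded$snps; contacts <- loaded$contacts
  assoc <- loaded$assoc; pathway_list <- loaded$pathways
  dgi <- loaded$dgi
  phenos <- unique(snps$phenotype)
  ds_names <- names(contacts)
  report$inputs <- list(
    n_genes = nrow(genes), n_fragments = nrow(fragments),
    n_snps = as.list(table(snps$phenotype)[phenos]),
    n_contacts = lapply(contacts, nrow), n_assoc_rows = nrow(assoc),
    n_pathways = length(pathway_list), n_dgi_rows = nrow(dgi))

  # -- spatial mapping --------------------------------------------------
  spatial <- run_stage("map", {
    kept <- filter_snps_by_significance(snps, config$gwas_alpha)
    snp_frags <- assign_to_fragments(kept, fragments, what = "snp")
    gene_frags <- assign_to_fragments(genes, fragments, what = "gene")
    pairs <- call_spatial_pairs(snp_frags, gene_frags, contacts,
                                self_contact = config$self_contact,
                                fragments = fragments)
    pairs <- merge(pairs, kept[, .(rsid, phenotype)], by = "rsid")
    data.table::setorder(pairs, phenotype, rsid, gene_id)
    data.table::fwrite(pairs, file.path(out_dir, "spatial_pairs.tsv"),
                       sep = "\t")
    list(pairs = pairs, kept = kept)
  })
  mark("map")
  report$spatial <- list(
    n_snps_kept = nrow(spatial$kept), n_pairs = nrow(spatial$pairs),
    n_spatial_genes = length(spatial_gene_background(spatial$pairs)))

  # -- eQTL stage -------------------------------------------------------
  sources <- c(ds_names, "combined")
  eqtl <- run_stage("eqtl", {
    egene_sets <- list(); calls_list <- list(); all_calls <- list()
    for (ph in phenos) {
      ph_pairs <- spatial$pairs[phenotype == ph]
      for (src in sources) {
        res <- run_eqtl(ph_pairs, assoc, snps, genes, phenotype = ph,
                        hic_source = src, alpha = config$alpha_fdr,
                        cis_window = config$cis_window,
                        scope = config$bh_scope)
        key <- paste(ph, src, sep = "|")
        egene_sets[[key]] <- res$egenes
        calls_list[[key]] <- res$calls
        if (nrow(res$calls)) {
          tagged <- data.table::copy(res$calls)
          tagged[, `:=`(phenotype = ph, hic_source = src)]
          all_calls[[key]] <- tagged
        }
        write_gene_list(res$egenes$egenes,
                        file.path(out_dir,
                                  sprintf("egenes_%s_%s.txt", ph, src)))
      }
    }
    calls_dt <- data.table::rbindlist(all_calls)
    data.table::fwrite(calls_dt, file.path(out_dir, "eqtl_calls.tsv"),
                       sep = "\t")
    snp_tables <- split(spatial$kept, by = "phenotype")
    summary_dt <- summarize_proportions(egene_sets, snp_tables, calls_list)
    data.table::fwrite(summary_dt,
                       file.path(out_dir, "eqtl_summary.tsv"), sep = "\t")
    partition <- if (length(ds_names) == 2L) {
      per_ds <- egene_sets[vapply(egene_sets, function(e)
        e$hic_source != "combined", logical(1L))]
      partition_by_dataset(per_ds)
    } else NULL
    if (!is.null(partition)) {
      data.table::fwrite(partition,
                         file.path(out_dir, "eqtl_dataset_partition.tsv"),
                         sep = "\t")
    }
    list(egene_sets = egene_sets, summary = summary_dt,
         partition = partition)
  })
  mark("eqtl")
  combined_sets <- setNames(lapply(phenos, function(ph)
    eqtl$egene_sets[[paste(ph, "combined", sep = "|")]]$egenes), phenos)
  combined_snps <- setNames(lapply(phenos, function(ph)
    eqtl$egene_sets[[paste(ph, "combined", sep = "|")]]$eqtl_snps), phenos)
  report$eqtl <- list(
    summary = split(eqtl$summary, by = "phenotype"),
    n_egenes_combined = lapply(combined_sets, length),
    dataset_partition = eqtl$partition)

  # -- eGene overlap ----------------------------------------------------
  overlap <- run_stage("overlap", {
    bg_all_path <- file.path(input_dir, "background_all_egenes.txt")
    bg_all <- if (file.exists(bg_all_path)) read_gene_list(bg_all_path) else
      sort(unique(assoc$gene_id))
    bg_all <- union(bg_all, unlist(combined_sets))
    backgrounds <- list(
      all_egenes = bg_all,
      spatial_genes = spatial_gene_background(spatial$pairs))
    res <- run_both_backgrounds(combined_sets, backgrounds,
                                n_boot = config$n_boot,
                                seed = config$seed,
                                alpha = config$alpha_fdr)
    data.table::fwrite(res$table, file.path(out_dir, "overlaps.tsv"),
                       sep = "\t")
    res
  })
  mark("overlap")
  report$overlap <- list(table = overlap$table)

  # -- pathway stage ----------------------------------------------------
  pathways_res <- run_stage("pathways", {
    universe <- intersect(unique(unlist(pathway_list)), genes$gene_id)
    enrich <- list(); enriched_sets <- list()
    for (ph in phenos) {
      er <- suppressWarnings(
        ora_enrich(combined_sets[[ph]], pathway_list, universe,
                   alpha = config$alpha_fdr))
      enrich[[ph]] <- er
      enriched_sets[[ph]] <- sort(er[enriched == TRUE]$pathway_id)
      data.table::fwrite(er,
                         file.path(out_dir,
                                   sprintf("enrichment_%s.tsv", ph)),
                         sep = "\t")
    }
    ov <- pathway_overlaps(enriched_sets)
    pw_backgrounds <- list(
      all_pathways = names(pathway_list),
      egene_pathways = names(pathway_list)[vapply(pathway_list, function(g)
        length(intersect(g, unlist(combined_sets))) > 0L, logical(1L))])
    boot_rows <- list()
    for (i in seq_len(nrow(ov$combos))) {
      members <- parse_combo(ov$combos$combination[i])
      if (any(ov$sizes[members] == 0L)) next
      for (bl in names(pw_backgrounds)) {
        br <- bootstrap_pathway_overlap(
          ov$sizes[members], pw_backgrounds[[bl]],
          ov$combos$observed[i], n_boot = config$n_boot,
          seed = config$seed, background_label = bl)
        boot_rows[[length(boot_rows) + 1L]] <- data.table::data.table(
          combination = ov$combos$combination[i], background = bl,
          background_size = br$background_size,
          observed = br$observed, empirical_p = br$empirical_p)
      }
    }
    boot_dt <- if (length(boot_rows)) data.table::rbindlist(boot_rows) else
      data.table::data.table(combination = character(),
                             background = character(),
                             background_size = integer(),
                             observed = integer(),
                             empirical_p = numeric())
    ov_out <- merge(ov$combos, boot_dt, by = "combination",
                    all.x = TRUE, sort = FALSE)
    data.table::fwrite(ov_out,
                       file.path(out_dir, "pathway_overlaps.tsv"),
                       sep = "\t")
    class_rows <- list()
    records <- list()
    for (i in seq_len(nrow(ov$combos))) {
      members <- parse_combo(ov$combos$combination[i])
      shared_pw <- Reduce(intersect, enriched_sets[members])
      for (pid in shared_pw) {
        rec <- classify_shared_pathway(pid, pathway_list[[pid]], members,
                                       combined_sets, enriched_sets)
        records[[length(records) + 1L]] <- rec
        class_rows[[length(class_rows) + 1L]] <- data.table::data.table(
          pathway_id = pid, combination = ov$combos$combination[i],
          driver_class = rec$driver_class)
      }
    }
    class_dt <- if (length(class_rows)) data.table::rbindlist(class_rows)
      else data.table::data.table(pathway_id = character(),
                                  combination = character(),
                                  driver_class = character())
    data.table::fwrite(class_dt,
                       file.path(out_dir, "shared_pathway_classes.tsv"),
                       sep = "\t")
    list(enrich = enrich, enriched_sets = enriched_sets,
         overlaps = ov_out, classes = class_dt, records = records)
  })
  mark("pathways")
  report$pathways <- list(
    n_enriched = lapply(pathways_res$enriched_sets, length),
    overlaps = pathways_res$overlaps,
    driver_classes = as.list(table(pathways_res$classes$driver_class)))

  # -- annotation -------------------------------------------------------
  annot <- run_stage("annotate", {
    drg <- annotate_druggable(combined_sets, dgi)
    dr_dt <- data.table::rbindlist(lapply(names(drg$druggable),
      function(ph) {
        g <- drg$druggable[[ph]]
        if (!length(g)) return(NULL)
        data.table::data.table(phenotype = ph, gene_id = g)
      }))
    if (is.null(dr_dt) || !nrow(dr_dt)) {
      dr_dt <- data.table::data.table(phenotype = character(),
                                      gene_id = character())
    }
    data.table::fwrite(dr_dt, file.path(out_dir, "druggable_egenes.tsv"),
                       sep = "\t")
    dpw <- druggable_pathways(pathways_res$enriched_sets, pathway_list,
                              drg$druggable)
    dpw_dt <- data.table::rbindlist(lapply(names(dpw$druggable_pathways),
      function(ph) {
        p <- dpw$druggable_pathways[[ph]]
        if (!length(p)) return(NULL)
        data.table::data.table(phenotype = ph, pathway_id = p)
      }))
    if (is.null(dpw_dt) || !nrow(dpw_dt)) {
      dpw_dt <- data.table::data.table(phenotype = character(),
                                       pathway_id = character())
    }
    data.table::fwrite(dpw_dt,
                       file.path(out_dir, "druggable_pathways.tsv"),
                       sep = "\t")
    haplo <- read_haplotypes(file.path(input_dir, "haplotypes.vcf"))
    ld <- screen_ld_confounding(combined_snps, haplo$haps, haplo$snps,
                                threshold = config$ld_threshold)
    data.table::fwrite(ld, file.path(out_dir, "ld_pairs.tsv"), sep = "\t")
    list(druggable = drg, druggable_pathways = dpw, ld = ld)
  })
  mark("annotate")
  report$annotation <- list(
    druggable_fraction = annot$druggable$fraction,
    n_egenes_union = annot$druggable$n_union,
    n_druggable_pathways = lapply(annot$druggable_pathways$druggable_pathways,
                                  length),
    n_shared_druggable_pathway_without_shared_gene =
      nrow(annot$druggable_pathways$no_shared_gene),
    n_ld_pairs = nrow(annot$ld))

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  writeLines(c(sprintf("stage\t%s\tcomplete", done), "run\tcomplete"),
             manifest_path)
  invisible(report)
}
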