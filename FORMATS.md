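# File formats

All tables are tab-separated with a header row unless stated otherwise.
Coordinates are 0-based half-open internally; the two exceptions at the
I/O boundary are noted below.

## Pipeline inputs (written by `simulate_dataset()`, read by `run_all()`)

`genes.tsv` — GTF-like gene model, **1-based inclusive** coordinates on
disk (converted by `read_genes()`/`write_genes()`):
`gene_id  symbol  chrom  start  end`

`fragments.bed` — restriction-fragment map, BED4, no header, native BED
0-based half-open: `chrom  start  end  frag_id`. Fragments tile each
chromosome exactly.

`snps_<phenotype>.tsv` — one file per phenotype:
`rsid  chrom  pos  phenotype  assoc_p` (pos 0-based; assoc_p at or below
the suggestive threshold).

`contacts_<dataset>.tsv` — Hi-C fragment-pair contact list in canonical
unordered form (`frag_a <= frag_b`, one row per pair):
`frag_a  frag_b  count` (counts are carried but not thresholded).

`eqtl_associations.tsv` — GTEx-like association table:
`rsid  gene_id  tissue  pval_nominal`

`pathways.gmt` — standard GMT: `name <tab> description <tab> gene ...`

`dgi.tsv` — drug–gene interactions: `gene_id  drug  source`

`haplotypes.vcf` — VCF 4.2, phased GT only; haplotypes 2i−1 and 2i form
sample i. One site per SNP.

`background_all_egenes.txt` — one gene id per line; all genes appearing in
the association table (the stand-in for an external all-eGenes
background).

`truth.tsv` — planted ground truth, flat with a role column:
`role  group  id1  id2  info`, where role is one of
`egene` (group = phenotype, id1 = gene), `eqtl_snp` (id1 = rsid),
`pair` (group = phenotype, id1 = rsid, id2 = gene, info = supporting
datasets comma-joined), `shared_egene` (group = combination label
"A:B"), `cooccur_pathway` (group = combination, id1 = pathway id),
`ld_pair` (group = "phA:phB", id1/id2 = rsids).

## Pipeline outputs (under the run's `out_dir`)

`spatial_pairs.tsv` — `rsid  gene_id  datasets  phenotype` (datasets
comma-joined, sorted).

`eqtl_calls.tsv` — all tested triples with
`gene_id  rsid  tissue  pval_nominal  q  significant  cis_trans distance
phenotype  hic_source` (distance in bp, empty for inter-chromosomal).

`egenes_<phenotype>_<source>.txt` — one gene id per line; `<source>` is a
Hi-C dataset label or `combined`.

`eqtl_summary.tsv` — per phenotype × source: SNP counts, eQTL SNP counts
and fraction, eGene counts, cis/trans partition.

`eqtl_dataset_partition.tsv` — per phenotype: eQTL SNPs specific to each
of the two Hi-C sources, or found in both.

`overlaps.tsv` — per combination × background: observed inclusive
intersection, bootstrap `empirical_p`, `analytic_p` (pairwise only),
significance flags.

`enrichment_<phenotype>.tsv` — ORA table: `pathway_id k K n N p q
enriched`.

`pathway_overlaps.tsv` — pathway-overlap counts with bootstrap results
against both pathway backgrounds.

`shared_pathway_classes.tsv` — `pathway_id  combination  driver_class`
(`shared_egenes` / `condition_specific` / `mixed`).

`druggable_egenes.tsv`, `druggable_pathways.tsv`, `ld_pairs.tsv` —
annotation outputs; LD rows are cross-phenotype same-chromosome pairs
with r² above the threshold.

`report.json` — machine-readable digest of every stage; `MANIFEST` —
stage completion markers.
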