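# spatialmorbid

Spatial regulatory eQTL mapping and cross-phenotype eGene overlap analysis.

## The problem

GWAS variants for related phenotypes rarely coincide, yet the phenotypes can
still share biology: different SNPs may regulate the *same genes* through
long-range chromatin contacts, or condition-specific target genes may
co-occur in the *same pathways*. `spatialmorbid` implements, as a tested and
reusable R pipeline, the multimorbid spatial-regulatory analysis that probes
this: per-phenotype GWAS SNPs are linked to candidate target genes through
Hi-C restriction-fragment contacts, confirmed as regulatory with an eQTL
association table, and the resulting per-phenotype eGene sets and enriched
pathways are compared across phenotypes with calibrated null models. It is
aimed at statistical geneticists who want the whole chain — mapping, FDR,
overlap significance, pathway classification, druggability and LD
annotation — reproducible from one seed, and exercised end-to-end on
synthetic data with planted ground truth.

## The method

For each phenotype with SNPs retained at the suggestive threshold
*p* ≤ 5 × 10⁻⁶:

1. **Spatial mapping.** Each SNP maps to the restriction fragment containing
   it; a (SNP, gene) pair is *spatially connected* when any Hi-C dataset
   records a contact between the SNP's fragment and a fragment overlapping
   the gene (a SNP inside a gene's own fragment counts by the self-fragment
   rule, since proximity ligation cannot report within-fragment contacts).
2. **eQTL calling.** Spatial pairs are joined to a GTEx-like association
   table over (variant, gene, tissue). One joint Benjamini–Hochberg
   correction is applied across all tested triples per phenotype and Hi-C
   source; genes with any call at FDR *q* < 0.05 are the phenotype's
   *eGenes*, and calls are classified cis (same chromosome, ≤ 1 Mb,
   inclusive) or trans.
3. **Overlap significance.** For every combination of phenotypes, the
   inclusive intersection of eGene sets is compared against a bootstrap
   null: 10,000 replicates draw independent uniform random sets of the same
   sizes from a background (all eGenes, and more conservatively only
   spatially contacted genes), with the add-one empirical p-value
   (1 + #{null ≥ obs}) / (1 + B). Pairwise overlaps also get the exact
   hypergeometric tail P(X ≥ obs), X ~ Hypergeom(N, n₁, n₂).
4. **Pathways.** Per-phenotype hypergeometric over-representation (ORA) of
   eGenes against a GMT collection with BH correction; cross-phenotype
   pathway overlaps get the same bootstrap over pathway space; each shared
   pathway is classified by whether its co-occurrence is driven by shared
   eGenes, condition-specific eGenes, or both.
5. **Annotation.** eGenes are flagged druggable from a drug–gene interaction
   table; cross-phenotype eQTL pairs on a chromosome are screened for
   linkage disequilibrium, with r² computed exactly from phased haplotypes
   (r² = D² / (p_A(1−p_A) p_B(1−p_B))), annotating overlaps that LD alone
   might explain.

A synthetic-data generator (`sim_config()` / `simulate_dataset()`) emulates
every input — genome, fragment map, SNP tables, two Hi-C contact lists of
very different density, association table, pathway collection, drug table,
phased VCF — with planted true eGenes, shared eGenes, co-occurring pathways
and high-LD pairs written to a truth table, so the entire pipeline is
testable against known ground truth.

## Worked example

```r
library(spatialmorbid)
cfg <- sim_config(seed = 1)          # the default four-phenotype study
rc  <- run_config(out_dir = "demo", simulate = TRUE, sim = cfg,
                  n_boot = 10000, seed = 1)
report <- run_all(rc)
```

The run writes every stage artifact under `demo/`. The eQTL summary
(`eqtl_summary.tsv`, combined Hi-C sources):

```
   phenotype hic_source n_snps n_eqtl_snps  fraction n_egenes n_cis n_trans
1:       ALS   combined    135          65 0.4814815       65   109      11
2:        GS   combined    179         147 0.8212291      155   261      22
3:        MG   combined     18          14 0.7777778       14    25      10
4:        MS   combined    285         229 0.8035088      238   447      33
```

About 80% of GS/MG/MS SNPs and under half of ALS SNPs are eQTLs (the
generator's planted fractions), and ~92% of significant calls are cis.
Pairwise eGene overlaps against the all-eGenes background
(`overlaps.tsv`), with the bootstrap and the analytic hypergeometric tail
agreeing closely:

```
   combination observed empirical_p   analytic_p
1:      ALS:GS        7  0.07899210 7.887584e-02
2:      ALS:MG        1  0.29097090 2.917630e-01
3:      ALS:MS        5  0.70722928 6.992687e-01
4:       GS:MG        4  0.00619938 6.854168e-03
5:       GS:MS       33  0.00009999 8.278184e-07
6:       MG:MS        4  0.03009699 2.986570e-02
```

The 33 GS:MS shared eGenes (30 planted plus chance) are far beyond the
null (p < 10⁻⁴ is the bootstrap's resolution at B = 10,000). Three pathways
contain co-occurring eGenes from all four phenotypes; 12.4% of the 420
identified eGenes are druggable (planted rate 13%); and the LD screen
reports exactly the planted cross-phenotype pair:

```
      rsid_a    rsid_b phenotype_a phenotype_b        r2
1: rs7421463 rs0039632          MG          MS 0.9026603
```

A thin CLI over the same functions is installed at
`inst/scripts/pipeline.R` (`simulate`, `run-all`, `validate` subcommands).

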