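---
title: "Methods: spatial eQTL mapping and cross-phenotype overlap statistics"
author: "spatialmorbid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial eQTL mapping and cross-phenotype overlap statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`spatialmorbid` asks whether phenotypes with disjoint GWAS signals share
regulatory biology. The chain is: SNP → restriction fragment → Hi-C
contact → candidate target gene → eQTL test → FDR → per-phenotype eGene
set, followed by cross-phenotype overlap statistics at the gene and
pathway level, druggability annotation, and LD screening. This vignette
records the statistical models, the parameter choices and their
rationale, the design decisions taken where the procedure was genuinely
open, and what the synthetic study does and does not establish.

# Spatial mapping

A SNP belongs to exactly one fragment: fragments are half-open intervals
`[start, end)` tiling each chromosome, so a SNP sitting precisely on a
boundary belongs to the right-hand fragment — an arbitrary but fixed
tie-break. A gene maps to every fragment overlapping its body.

A (SNP, gene) pair is supported by a Hi-C dataset when that dataset's
contact list contains the unordered fragment pair {frag(SNP), any gene
fragment}. Two deliberate choices:

* **Self-fragment rule** (default on, `self_contact = FALSE` to disable):
  a SNP whose fragment itself overlaps a gene is treated as spatially
  connected to that gene without requiring a contact row. Proximity
  ligation cannot observe within-fragment contacts, so requiring one
  would systematically drop promoter and intragenic SNPs.
* **No adjacency rule**: neighbouring fragments are *not* assumed in
  contact; only recorded Hi-C contacts (plus the self-fragment rule)
  confer support. Contact counts are treated as presence/absence — no
  count threshold is applied, and none is assumed by downstream stages.

The implementation is checked against an exhaustive enumeration of all
(SNP, gene, dataset) triples on randomized toy genomes, and is invariant
to contact row order and fragment-pair orientation; adding contacts can
only add pairs.

# eQTL calling and FDR

Spatial pairs are joined to the association table over (variant, gene,
tissue). The Benjamini–Hochberg step-up correction is applied **jointly
across all tested triples of one phenotype × Hi-C source run** — the
conservative reading when the correction scope is otherwise unspecified;
`scope = "per_tissue"` is available for sensitivity analysis. A gene is
an eGene if any of its triples reaches q < `alpha_fdr` (default 0.05); an
eQTL SNP is a SNP with at least one significant triple, and the
eQTL:non-eQTL proportion uses post-threshold SNP counts as denominators.

Cis/trans: a call is cis when SNP and gene share a chromosome and the
distance is at most the window (default 1 Mb, boundary inclusive).
Distance is anchored at the **nearest gene-body edge** (0 inside the
gene), not the TSS — with no stated anchor convention, the gene-edge
choice is symmetric for upstream and downstream SNPs; `anchor = "tss"`
switches. Inter-chromosomal distance is reported as missing.

`bh_adjust()` delegates to `stats::p.adjust(method = "BH")`; the test
suite holds it to a literal implementation of the step-up definition
(element-wise to 1e-12 on 1,000 random vectors, ties included).

# Overlap significance

For every combination of phenotypes the **inclusive** intersection is
used (an element in all four sets also counts in every pairwise and
triple combination); this is the convention under which drawing
independent random sets of the observed sizes is the natural null. An
exclusive (UpSet-style) count is available for display but carries no
significance test.

The bootstrap null draws, independently per phenotype, a uniform random
subset of the background without replacement, of the observed set size;
B = 10,000 replicates by default. The empirical p-value is the add-one
estimator (1 + #{null ≥ obs}) / (1 + B): never exactly zero, smallest
reportable value just under 1/B, ties counted in the tail. Each
combination gets its own RNG stream derived by a stable polynomial hash
of the sorted combination label and the master seed, so results are
independent of evaluation order and of which other combinations are run.

Two backgrounds are evaluated: *all eGenes* (every gene in the
association table — the stand-in for an external database-wide eGene
list) and the stricter *spatially contacted genes* (every gene in at
least one called spatial pair). Shrinking the background densifies the
null and can only raise the expected tail probability; combinations
whose verdict changes between backgrounds are flagged.

For pairwise combinations the intersection under this null is exactly
hypergeometric, so the analytic tail `phyper`-based
`hypergeom_overlap_p()` serves as a cross-check: the suite requires the
bootstrap to sit within three Monte-Carlo standard errors of it across
randomized configurations, and requires bootstrap p-values to be
uniform under a no-sharing null (KS test over 200 replicate draws).

# Pathway analysis

Per-phenotype enrichment is plain hypergeometric ORA: k eGenes among the
pathway's K universe members, drawn n from N, upper tail, BH across all
pathways within one phenotype run. The universe is **all genes annotated
to at least one pathway** intersected with the gene model — the standard
conservative ORA universe; pass `universe =` to widen it. Impact- or
topology-aware enrichment is out of scope by design.

Pathway overlaps reuse the set machinery with pathway ids as elements,
bootstrapped against all pathways and against the restricted background
of pathways containing at least one identified eGene, sampling pathway
ids uniformly (no size weighting).

Each shared pathway is classified by what drives the co-occurrence:
within the combination, a hit gene is "shared" if it belongs to at least
two member eGene sets; `condition_specific` = no shared hit,
`shared_egenes` = only shared hits, `mixed` otherwise. The trichotomy is
total and exclusive. Under noisy defaults an occasional false-positive
eGene can land in a planted pathway and appear shared, moving a truly
condition-specific pathway to `mixed`; the noise-free configuration
recovers the planted class exactly, which is what the acceptance test
asserts.

# Druggability and LD

A gene is druggable if it has any drug–gene interaction row; the global
fraction is over the union of all phenotypes' eGenes. A pathway is
druggable for a phenotype when it is enriched for it *and* contains one
of that phenotype's druggable eGenes; shared druggable pathways with
zero shared druggable genes are flagged explicitly, since they are drug
targets of joint interest that no single gene explains.

LD is computed exactly from phased haplotypes,
r² = D²/(p_A(1−p_A) p_B(1−p_B)), with no EM genotype phasing step —
the input VCF is phased, which removes estimation ambiguity. Monomorphic
SNPs give an undefined r², reported as missing with a warning. The
screen covers every cross-phenotype eQTL pair on the same chromosome
(a superset of screening one locus of interest) and **annotates** rather
than filters: LD is a post-hoc explanation for an overlap, not grounds
for removal. Pairs must exceed the threshold strictly (default 0.8).

# The synthetic study

The generator's defaults are the study conditions, fixed once:

* Four phenotypes, 179 (GS), 18 (MG), 285 (MS), 135 (ALS) SNPs, all at
  the suggestive threshold 5 × 10⁻⁶, pairwise disjoint.
* Planted eQTL fractions 0.8, except 0.45 for ALS.
* Two Hi-C datasets: `cellline` (density multiplier 1.0) and `muscle`
  (0.1, roughly ten-fold sparser); 20% of planted pairs are confined to
  a single dataset to exercise the dataset-partition summary; a
  multiplier of zero removes a dataset's support for a phenotype
  entirely.
* Planted shared eGenes per combination:
  GS:MG 4, GS:MS 30, GS:ALS 5, MG:MS 4, MS:ALS 2, MG:ALS 1, GS:MS:ALS 2 —
  small against the per-phenotype sets, large against the null.
* 48 tissues; significant nominal p-values log-uniform on
  [1e-10, 1e-6]; decoy pairs uniform on (0, 1) (10 decoy genes per SNP,
  60% of them given a Hi-C contact so the FDR denominator is realistic).
* 536 pathways with 10–60 genes; 3 planted pathways containing ~15
  condition-specific eGenes from each phenotype and no shared eGenes.
* Druggable fraction 0.13 per gene; 1,000 phased haplotypes with 50 kb
  LD blocks (within-block copy error 0.15, background r² ≈ 0.25) and one
  planted MG×MS high-LD pair (copy error 0.01, expected
  r² = 0.98⁴ ≈ 0.92).
* Genome: 6 × 2.5 Mb chromosomes, 3,000 non-overlapping genes,
  fragments ~4 kb. Sized so ~500 eGenes leave the overlap and ORA nulls
  sparse enough for planted signals to be detectable, while a full run
  takes seconds.

Every stage seeds its own RNG stream from the master seed via the stable
hash, so identical configurations are byte-identical on disk and
individual generator stages are reproducible in isolation.

**What the generator does not emulate:** Hi-C distance decay and
TAD/compartment structure (contacts are uniform over fragment pairs plus
planted rows); realistic allele-frequency spectra and recombination
maps (LD blocks are rectangular); correlated eQTL effects across
tissues; gene-density and gene-length biases in pathway membership; any
nucleotide sequence. Passing tests therefore establish the pipeline's
*correctness and calibration* — exact truth recovery without noise,
uniform p-values without signal, detection of planted signal — not that
real Hi-C/eQTL data would yield comparable power.

`noise_free = TRUE` raises the decoy p-value floor to 0.1, above the FDR
threshold, so no decoy can become an eGene and the pipeline must recover
the planted truth *exactly*; this is the configuration the planted-truth
acceptance test runs at full default scale.

# Numerical and degenerate-input choices

* p-values must lie in (0, 1]; zero is rejected rather than clamped.
* An empty post-threshold SNP table, an empty eGene set, or a pathway
  with no universe members are all legal and propagate as empty results,
  not errors; an empty ORA universe is an error.
* Impossible observed overlaps (above the smaller set, below the
  inclusion-exclusion floor) are errors in the analytic tail.
* Equal-seed reruns of `run_all()` are bit-identical, including
  `report.json` (no timestamps in outputs).
* Oracle comparisons in the suite use 1e-12 tolerances for closed forms
  and 3 Monte-Carlo SE for stochastic agreement. Test problem sizes —
  toy genomes up to 50 SNPs × 50 genes for the spatial oracle, N ≤ 30
  for exhaustive hypergeometric enumeration, B = 10,000 bootstrap
  replicates, 200 null replicates for KS calibration — were chosen as
  the smallest instances that exercise every code path and tie-break
  while keeping the default suite fast.

# Known limitations

* The bootstrap null ignores gene length, LD between nearby genes, and
  pathway size when sampling; this matches the stated procedure but
  means the null is liberal for sets with strong length or locus
  clustering (the LD screen exists precisely to annotate that failure
  mode at the SNP level).
* ORA is not an impact analysis: pathway topology and perturbation
  propagation are out of scope, so enriched-pathway counts are not
  comparable to topology-aware tools.
* The dataset partition currently supports exactly two Hi-C sources.
* r² from haplotypes assumes correct phasing; unphased genotype input is
  not supported.
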