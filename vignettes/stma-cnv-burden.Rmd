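---
title: "StMA gene burden in CNV regions: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{StMA gene burden in CNV regions: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmaburden)
```

## The scientific question

A stochastic monoallelically expressed (StMA) gene chooses which of its two
alleles to express at random, early in development, and clonal descendants
inherit that choice. The resulting mosaic of allelic expression across a
tissue is a candidate mechanism for dosage-sensitive neurodevelopmental
phenotypes. This package asks a burden question: are StMA genes — defined
operationally from clonal neural stem cell allelic-expression assays —
over-represented among the genes affected by copy-number variants (CNVs)
found in autism and schizophrenia cohorts, relative to CNVs from population
controls?

The pipeline has four computational stages, each exposed as package
functions and driven end to end by the scripts under `analysis/`:

1. **Allelic classification** (`call_alleles()`, `classify_genes()`,
   `merge_gene_lists()`)
2. **CNV region construction and gene mapping** (`merge_maximal()`,
   `minimal_overlap_regions()`, `map_genes()`)
3. **Burden measures and contingency tests** (`stma_metrics()`,
   `fold_vs_control()`, `contingency_test()`, `build_table1()`)
4. **Transcriptome-resampling permutation null** (`permutation_null()`)

A synthetic-cohort generator (`synthetic_spec()` and the `generate_*()`
functions) plants known truth through all four stages.

## Allelic classification

A clone is called monoallelic for a gene when the higher-expressed allele
exceeds the lower more than 2.33-fold (`mono_fold_threshold`, strictly
greater: a ratio of exactly 2.33 is biallelic). The ratio is computed as
max/min of the two intensities, which makes the rule symmetric in the
alleles by construction. One silent allele (zero) with the other expressed
is the strongest monoallelic evidence and is called mono; both alleles at
zero is an undefined ratio and yields `no_call`.

Gene status is then decided per cell source from the sister-clone calls:

* **StMA** — at least one monoallelic clone *and* a genetically identical
  sister clone with a different informative state (biallelic, or
  monoallelic for the other allele). Variable allelic choice across
  genetically identical clones is the defining observation.
* **Biallelic (BA)** — at least `min_clones_for_ba` (default 3)
  informative clones, all biallelic.
* **Consistent-MA** — two or more clones, all monoallelic for the *same*
  allele. This is the imprinting-like / cis-variant-like pattern and is
  excluded from the StMA list.
* **Unclassified** — anything else, including a single monoallelic clone
  with no informative sister.

Per-source lists are merged by union into global StMA and BA lists. A gene
StMA in one source but BA in another goes to the StMA list only:
demonstrated allelic variability anywhere overrides biallelic behaviour
elsewhere. The source data do not dictate this resolution; the package
logs every such conflict so the choice is auditable. The 2.33-fold rule is
applied to the supplied expression values as-is; no transformation is
assumed.

## CNV regions and gene mapping

Coordinates are 0-based half-open internally (1-based inclusive inputs can
be converted on read). Overlapping CNVs within a dataset are merged into
**maximal regions** — the potentially maximally affected span — using
interval reduction; merging requires at least one shared base, so abutting
intervals stay separate (the conservative reading of "overlapping").
**Minimal (critical) overlap regions** are the maximal sub-intervals
covered by two or more member CNVs within an overlap cluster, with
single-CNV clusters passing through unchanged; this depth-2 construction
is a documented package choice (the original analysis reports results for
minimal regions but not their construction), and its semantics are pinned
by a per-base coverage oracle in the test suite.

Control CNV sets carry a large excess of very short variants, so a size
selection retains only control CNVs strictly longer than 100 kb
(`min_control_cnv_length`), applied before merging; disease sets pass
unfiltered. A gene is attached to a region when any of its annotated
intervals shares at least one base with it (no minimum-fraction rule), and
a dataset's gene set is the union over its regions, so a gene spanning two
regions counts once in dataset totals. CNV type (gain/loss) is ignored —
deletions and duplications are pooled.

## Burden measures and tests

Because disease CNVs are systematically larger than control CNVs, raw StMA
counts are confounded by size. Three measures are therefore reported per
dataset: StMA occurrence per 1000 CNV-mapped genes, StMA genes per megabase
of merged region, and the percentage of regions containing at least one
StMA gene. Fold enrichments relative to the merged control dataset are
computed from the underlying counts at full precision, never from rounded
rates (the printed rates 16.2 and 3.2 would suggest 5.06; the count-based
fold is 5.00).

Association is tested on the 2×2 table of (StMA, non-StMA) × (test set,
control set) — and analogously (regions with, regions without an StMA
gene) at the region level — using the chi-squared test with Yates'
continuity correction. Whenever any expected cell count falls below 5
(the condition under which the chi-squared approximation is flagged as
unreliable), the two-sided Fisher exact test is used instead, with the
point-probability rule: the p-value sums the probabilities of all tables
with the observed margins whose probability does not exceed the observed
table's. The Yates correction term is capped at |O − E| so small tables
cannot produce negative corrected deviations. These conventions reproduce
every gene-level p-value in the published summary table from its printed
count rows, and six of the seven region-level p-values; the seventh
(printed 0.0148) is inconsistent with its own printed counts under either
test variant at higher precision (Fisher gives 0.0142) and is checked at a
correspondingly relaxed tolerance.

For candidate gene lists from association studies, observed StMA hits are
compared with the expectation obtained by apportioning all hits by the
StMA:BA list-size ratio (`association_enrichment()`); the reported table
precisions use half-up rounding.

## Permutation null

The StMA list derives from neural stem cell assays, so an apparent CNV
enrichment could simply reflect the neural transcriptome. The null
replaces the StMA list, in each of `n_permutations` (default 10,000)
iterations, with a uniform sample — without replacement, since a gene list
has no duplicates — from the assayed expressed-gene pool. The sample size
defaults to the size of the StMA list restricted to the pool, the only
choice that makes the surrogate like-for-like; the source analysis does
not state its sample size, so this is a documented package decision. One
shared sample per iteration serves all case datasets, so their permutation
columns correlate exactly as one resampled list implies. Per-iteration
contingency tests are Bonferroni-adjusted by the number of case datasets
tested simultaneously; medians over iterations summarise each dataset, and
`empirical_p()` provides the add-one upper-tail permutation p-value for an
observed count.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not human genome biology:

* **Genome** — `n_chromosomes` × `chrom_length` (default 20 × 500 Mb)
  with `n_genes` (default 20,000) non-overlapping fixed-length 10 kb genes
  placed uniformly. Fixed gene length keeps per-gene and per-Mb metrics
  analytically relatable.
* **Clones** — exactly `round(frac_stma * n_genes)` genes are planted StMA
  and `round(frac_ba * n_genes)` biallelic (defaults 5% and 90%); the
  remainder is consistent-MA. Three cell sources with `n_clones` (default
  3) sister clones each. Expressed alleles have mean intensity 100,
  silenced alleles mean 2 — near zero but positive, so calling exercises
  the fold-ratio rule rather than the division-by-zero branch — with
  multiplicative log-normal noise (`noise_sd`, default 0.15). At that
  default the probability that noise pushes a biallelic clone past the
  2.33-fold threshold is about 6×10⁻⁵, giving near-perfect but not
  trivially perfect recovery (roughly ten false StMA genes per 18,000
  biallelic ones); at `noise_sd = 0` recovery is exact. StMA genes choose
  an expressed allele per clone at random, constrained to include at least
  one discordant sister per source — the defining StMA observation — so
  planted labels are recoverable by the classifier's own definition.
* **CNVs** — exponential length model (closed-form expectations for
  tests), mean 0.78 Mb for 650 case CNVs and 0.49 Mb for 2000 control
  CNVs, mirroring the published case/control size asymmetry and sized on
  the largest published case dataset (the 650-region developmental
  disability morbidity map). Control CNVs are placed uniformly. Each case
  CNV is either anchored on a distinct, randomly chosen true-StMA gene
  (probability π) or placed uniformly, with π chosen in closed form so
  that the expected StMA fraction among case-covered genes is exactly
  `planted_enrichment` times the genome-wide rate (see
  `?generate_cnvs`). Anchoring on *distinct* genes matters: weighting
  whole CNV placements by their StMA content instead concentrates the
  planted signal on a few loci, and gene deduplication then erases much of
  it.

The cohort geometry is deliberate in one further respect. The gene-level
test compares two large gene sets sampled from a finite gene universe;
when the sets are a substantial fraction of the universe, or overlap
heavily, the two-sample binomial variance that the chi-squared test
assumes overstates the truth and the test becomes markedly conservative.
With 20,000 genes, case and control sets near 1,100 and 1,900 genes, and
expected StMA counts of roughly 55 and 95, the Yates-corrected test
operates near — though, as for any continuity-corrected test at finite
counts, slightly below — its nominal level: its measured type-I error at
α = 0.05 is ≈ 3.5%. Shrinking the universe to a few thousand genes drives
that below 2%, which is why the defaults are not smaller.

What the generator does **not** emulate: gene-density gradients, CNV
hotspots and segmental duplications, heavy-tailed CNV length
distributions, gain/loss asymmetry, assay dropout (every simulated gene is
assayed), and allelic choice bias. Passing tests on synthetic data
therefore validate the pipeline's arithmetic and statistical behaviour
under its stated assumptions, not its robustness to those real-data
features.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` run everything at sizes chosen
as a compromise between Monte-Carlo resolution and turnaround: null
calibration over 500 seeds (200 in the acceptance script) at
`planted_enrichment = 1`; planted-fold recovery for folds 2 and 5 as
medians over 50 seeds (25 in the script); permutation checks at 2,000
iterations rather than the 10,000 the analysis default uses (the
`analysis/05_permutation.R` driver runs the full 10,000); brute-force
oracle comparisons at up to 50 intervals on 10 kb toy chromosomes and
contingency margins up to 60, where exhaustive enumeration is exact.

## A worked example

```{r example, eval = FALSE}
res <- run_burden_pipeline(synthetic_spec(rng_seed = 20131227))
res$report$fold_per_1000[1]   # ~5: the planted enrichment, recovered
res$report$gene_test_p[1]     # far below 0.05

# the published-count arithmetic
contingency_test(14, 852, 9, 2772)$p_value   # 7.77e-05
```

## Known limitations

* The mapping of GWAS SNPs to genes via LD regions is out of scope; the
  association-study interface consumes ready gene lists.
* The minimal-region construction and the cross-source conflict rule are
  documented package choices where the source analysis is silent; both are
  pinned by tests so any alternative definition would be a visible change.
* Fisher/Yates tests on overlapping gene sets from a finite universe are
  intrinsically somewhat conservative (see above); empirical permutation
  p-values (`empirical_p()`) are the remedy when exact calibration
  matters.
* The permutation sample size and replacement policy are package
  decisions; results for strongly unbalanced pools should be read with
  that in mind.
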