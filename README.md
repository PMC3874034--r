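# stmaburden

Burden analysis of **stochastic monoallelically expressed (StMA) genes**
in disease-associated copy-number variant (CNV) regions.

Some genes choose which allele to express at random early in development;
clonal descendants keep that choice. Because allelic status correlates with
overall transcript level, such genes are candidates for dosage sensitivity.
This package implements, end to end, the analysis asking whether StMA genes
— identified from clonal neural stem cell allelic-expression assays — are
over-represented among genes affected by CNVs from autism and schizophrenia
cohorts, relative to population-control CNVs.

## What it computes

* **Allelic classification.** A clone is monoallelic when one allele
  exceeds the other more than 2.33-fold (max/min, strictly greater). A
  gene is **StMA** when a monoallelic clone has a genetically identical
  sister clone in a different informative state (biallelic or the opposite
  allele); **biallelic (BA)** when ≥ 3 informative clones are all
  biallelic; **consistent-MA** (imprinting-like, excluded) when all clones
  silence the same allele. Per-source lists merge by union into global
  StMA/BA lists.
* **CNV regions.** Overlapping CNVs merge into maximal regions; minimal
  (critical) regions are the sub-intervals covered by ≥ 2 CNVs. Control
  CNVs ≤ 100 kb are discarded first. Genes map to regions by ≥ 1 bp
  overlap (half-open coordinates).
* **Three size-aware burden measures** per dataset *D* with gene set
  *G(D)*, merged size *S(D)* Mb and StMA list *M*:
  * StMA per 1000 genes: `1000·|G(D) ∩ M| / |G(D)|`
  * StMA per Mb: `|G(D) ∩ M| / S(D)`
  * % regions containing ≥ 1 StMA gene

  with fold enrichment relative to the merged control set computed from
  raw counts, and association tested on the 2×2 count table by chi-squared
  with Yates' continuity correction — or the two-sided Fisher exact test
  whenever any expected cell is below 5.
* **Permutation null.** The StMA list is replaced by equal-size random
  samples of assayed expressed genes (10,000 iterations, one shared sample
  per iteration across datasets, per-iteration Bonferroni adjustment) to
  exclude a neural-transcriptome artefact.
* **Synthetic cohorts.** `synthetic_spec()` + `generate_*()` plant known
  allelic statuses and a known case-CNV enrichment, so every stage — and
  the pipeline's calibration — is testable without any external data.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
cohort (20,000 genes, 650 case CNVs with a planted five-fold StMA
enrichment, 2,000 control CNVs) and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_alleles.R
Rscript analysis/03_cnv_regions.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_permutation.R
```

Output of the run shipped with this repository:

```
simulated 20000 genes (1000 StMA, 18000 biallelic, 1000 consistent-MA),
650 case and 2000 control CNVs; planted gene-level enrichment 5.0
calls: biallelic=161990 mono_a=8888 mono_b=9122
global lists: 1010 StMA, 17990 biallelic
planted StMA recovered: 1000/1000 (false positives: 10)
size selection: kept 1634/2000 control CNVs (> 100 kb)
case maximal regions: n=619, total 485.2 Mb, 1180 genes mapped
control maximal regions: n=1497, total 926.9 Mb, 1884 genes mapped
synthetic cohort: fold (per 1000 genes) = 5.04 [planted 5], chi2_yates p = 1.41e-60
observed 303 StMA genes in case regions; permutation median 59 (fold 1.00, median p 0.574)
empirical p for the observed count: 0.0001
```

Read: classification recovers all 1,000 planted StMA genes (10 false
positives from measurement noise among 18,000 biallelic genes); the
case-versus-control fold estimate (5.04) recovers the planted five-fold
enrichment; and replacing the StMA list with random expressed-gene samples
gives no enrichment (median fold 1.00, median p 0.57) while the observed
count sits far outside the permutation distribution (empirical p = 1e-4) —
the signal belongs to the StMA genes, not the transcriptome they came
from.

In an R session, the same arithmetic that reproduces the published
summary-table statistics from its printed counts:

```r
library(stmaburden)
contingency_test(14, 852, 9, 2772)$p_value       # 7.77e-05 (chi-squared, Yates)
contingency_test(2, 83, 9, 2772)$p_value         # 0.0402   (Fisher; expected < 5)
(14 / 866) / (9 / 2781)                          # 5.00 fold vs controls
```

`analysis/04_enrichment.R` rebuilds every derived row of the published
summary table (rates, folds, both p-value rows) from its printed count
rows into `results/published_table1_derived.tsv`.

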