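#!/usr/bin/env Rscript

# Stage 1: simulate a full synthetic cohort — clonal allelic-expression
# measurements with planted gene statuses, a toy genome annotation, and
# case/control CNV datasets with a planted five-fold StMA enrichment —
# and write every input file the downstream stages consume.

suppressMessages(library(stmaburden))

out_dir <- "results/synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(rng_seed = 20131227)

annotation <- generate_genome(spec)
clones <- generate_clones(spec)
cnvs <- generate_cnvs(spec, annotation, clones$truth)

write.table(clones$measurements, file.path(out_dir, "clone_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(annotation, file.path(out_dir, "gene_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_cnv_bed(cnvs$case, file.path(out_dir, "case_cnvs.bed"))
write_cnv_bed(cnvs$control, file.path(out_dir, "control_cnvs.bed"))
write.table(clones$truth, file.path(out_dir, "truth_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d genes (%d StMA, %d biallelic, %d consistent-MA),\n%d case and %d control CNVs; planted gene-level enrichment %.1f\n",
  spec$n_genes, sum(clones$truth$status == "stma"),
  sum(clones$truth$status == "ba"),
  sum(clones$truth$status == "consistent_ma"),
  nrow(cnvs$case), nrow(cnvs$control), spec$planted_enrichment
))
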