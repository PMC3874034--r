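#!/usr/bin/env Rscript

# Stage 2: call per-clone allelic status with the 2.33-fold rule, classify
# each gene per cell source, merge the per-source lists into the global
# StMA and biallelic gene lists, and check them against the planted truth.

suppressMessages(library(stmaburden))

in_dir <- "results/synthetic"
measurements <- read_clone_table(file.path(in_dir, "clone_expression.tsv"))
truth <- read.delim(file.path(in_dir, "truth_labels.tsv"))

calls <- call_alleles(measurements)
classifications <- classify_genes(calls)
lists <- merge_gene_lists(classifications)

write_gene_list(lists$stma, file.path(in_dir, "stma_genes.txt"))
write_gene_list(lists$ba, file.path(in_dir, "ba_genes.txt"))

planted <- truth$gene[truth$status == "stma"]
cat(sprintf(
  "calls: %s\nglobal lists: %d StMA, %d biallelic\nplanted StMA recovered: %d/%d (false positives: %d)\n",
  paste(sprintf("%s=%d", names(table(calls$call)), table(calls$call)),
        collapse = " "),
  length(lists$stma), length(lists$ba),
  length(intersect(lists$stma, planted)), length(planted),
  length(setdiff(lists$stma, planted))
))
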