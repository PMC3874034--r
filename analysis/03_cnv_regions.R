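#!/usr/bin/env Rscript

# Stage 3: apply the >100 kb size selection to the control CNVs, merge each
# dataset's CNVs into maximal regions (and minimal/critical overlap
# regions), map annotated genes onto the regions, and write region tables.

suppressMessages(library(stmaburden))

in_dir <- "results/synthetic"
annotation <- read_gene_annotation(file.path(in_dir, "gene_annotation.tsv"))
case_cnvs <- read_cnv_bed(file.path(in_dir, "case_cnvs.bed"))
control_cnvs <- read_cnv_bed(file.path(in_dir, "control_cnvs.bed"))

control_kept <- filter_min_length(control_cnvs)
cat(sprintf("size selection: kept %d/%d control CNVs (> 100 kb)\n",
            nrow(control_kept), nrow(control_cnvs)))

for (kind in c("maximal", "minimal")) {
  build <- if (kind == "maximal") merge_maximal else minimal_overlap_regions
  for (set in c("case", "control")) {
    cnvs <- if (set == "case") case_cnvs else control_kept
    regions <- map_genes(build(cnvs), annotation)
    stats <- region_stats(regions)
    cat(sprintf("%s %s regions: n=%d, total %.1f Mb, %d genes mapped\n",
                set, kind, stats$n_regions, stats$total_size_mb,
                length(region_gene_set(regions))))
    flat <- regions
    flat$genes <- vapply(flat$genes, paste, "", collapse = ",")
    write.table(flat, file.path(in_dir, sprintf("%s_regions_%s.tsv", set, kind)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
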