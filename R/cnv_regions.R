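# CNV interval handling. Intervals are tibbles with columns chrom, start,
# end (0-based, half-open) and optionally label; interval arithmetic is
# delegated to GenomicRanges/IRanges on a 1-based closed view of the same
# bases, so "overlap" always means >= 1 shared base and abutting intervals
# (end == start) neither overlap nor merge.

intervals_to_gr <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

gr_to_intervals <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

validate_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end &
                   nzchar(intervals$chrom)))
  if (length(bad) > 0) {
    stop("invalid intervals (need 0 <= start < end, non-empty chrom) at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(intervals)
}

#' Read a BED-like CNV coordinate file
#'
#' Whitespace-separated, at least three columns: chrom, start, end; an
#' optional fourth column is kept as `label`. Coordinates are taken as
#' 0-based half-open (BED convention) unless `one_based = TRUE`, in which
#' case 1-based inclusive coordinates (spreadsheet exports) are converted by
#' `start - 1`. Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @param one_based Input is 1-based inclusive; convert on read.
#' @return Tibble with `chrom`, `start`, `end`, `label`.
#' @export
read_cnv_bed <- function(path, one_based = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("no records in ", path)
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), label = character(0)))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop("fewer than 3 columns at line(s): ",
         paste(utils::head(lineno[n_fields < 3], 5), collapse = ", "))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  label <- ifelse(n_fields >= 4, vapply(fields, function(f) f[4], ""), NA_character_)
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinates at line(s): ",
         paste(utils::head(lineno[is.na(start) | is.na(end)], 5), collapse = ", "))
  }
  if (one_based) start <- start - 1
  bad <- !(start >= 0 & start < end)
  if (any(bad)) {
    stop("start >= end (or negative start) at line(s): ",
         paste(utils::head(lineno[bad], 5), collapse = ", "))
  }
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), label = label)
}

#' Write intervals as BED
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @export
write_cnv_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- intervals[, intersect(c("chrom", "start", "end", "label"), names(intervals))]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Drop short CNVs
#'
#' Retains intervals whose length strictly exceeds
#' `params$min_control_cnv_length`. Intended for control datasets, which
#' contain a large excess of very short variants; disease datasets pass
#' through unfiltered by the pipeline.
#'
#' @param intervals Interval tibble.
#' @param params [stma_params()].
#' @return Filtered tibble.
#' @export
filter_min_length <- function(intervals, params = stma_params()) {
  validate_intervals(intervals)
  intervals[(intervals$end - intervals$start) > params$min_control_cnv_length, ]
}

#' Merge overlapping CNVs into maximal regions
#'
#' Overlapping CNVs (sharing at least one base, on the same chromosome) are
#' merged into a single maximal region spanning their union — the
#' potentially maximally affected region. Abutting intervals are not merged.
#'
#' @param intervals Interval tibble.
#' @return Tibble of disjoint regions with `chrom`, `start`, `end`,
#'   `n_members` (number of source CNVs merged) and `kind = "maximal"`,
#'   sorted by chromosome then start.
#' @export
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(100, 150), end = c(200, 300))
#' merge_maximal(x)
merge_maximal <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_members = integer(0),
                          kind = character(0)))
  }
  gr <- intervals_to_gr(intervals)
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
  out <- gr_to_intervals(merged)
  out$n_members <- GenomicRanges::countOverlaps(merged, gr)
  out$kind <- "maximal"
  out[order(out$chrom, out$start), ]
}

#' Minimal (critical) overlap regions
#'
#' Within each cluster of mutually overlapping CNVs, emits the maximal
#' sub-intervals covered by at least two member CNVs — the presumed
#' dosage-critical core shared across patients. A cluster with a single
#' member passes through unchanged. Output spans are always contained in the
#' corresponding maximal regions.
#'
#' @param intervals Interval tibble.
#' @return Tibble of regions as in [merge_maximal()], `kind = "minimal"`.
#' @export
minimal_overlap_regions <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), n_members = integer(0),
                          kind = character(0)))
  }
  gr <- GenomicRanges::sort(intervals_to_gr(intervals))
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  members_per_cluster <- GenomicRanges::countOverlaps(clusters, gr)

  # clusters of one CNV: the CNV itself
  singleton <- clusters[members_per_cluster == 1]

  # clusters of >= 2: maximal runs of coverage depth >= 2
  cov <- GenomicRanges::coverage(gr)
  deep <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2, rangesOnly = TRUE))
  multi <- clusters[members_per_cluster >= 2]
  deep <- deep[GenomicRanges::countOverlaps(deep, multi) > 0]

  res <- GenomicRanges::sort(c(singleton, deep))
  out <- gr_to_intervals(res)
  out$n_members <- GenomicRanges::countOverlaps(res, gr)
  out$kind <- "minimal"
  out[order(out$chrom, out$start), ]
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `symbol`, `chrom`, `start`, `end`
#' (0-based half-open unless `one_based`). Several intervals per symbol are
#' allowed (transcript isoforms).
#'
#' @param path File path.
#' @param one_based Convert 1-based inclusive input with `start - 1`.
#' @return Tibble with `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("symbol", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (one_based) df$start <- df$start - 1
  validate_intervals(df)
  if (any(!nzchar(df$symbol))) stop("empty gene symbols in ", path)
  tibble::as_tibble(df)
}

#' Map annotated genes onto regions
#'
#' A gene symbol is attached to a region when any of its intervals shares at
#' least one base with the region (no minimum-fraction rule); each symbol is
#' counted once per region. The dataset-level gene set is the union over
#' regions, so a symbol spanning two regions counts once in dataset totals.
#'
#' @param regions Region tibble ([merge_maximal()] or
#'   [minimal_overlap_regions()]).
#' @param annotation Tibble from [read_gene_annotation()] or
#'   [generate_genome()].
#' @return `regions` with a list-column `genes` of symbol vectors.
#' @export
map_genes <- function(regions, annotation) {
  validate_intervals(regions)
  if (nrow(annotation) == 0) {
    warning("empty annotation; all regions get empty gene sets")
    regions$genes <- replicate(nrow(regions), character(0), simplify = FALSE)
    return(regions)
  }
  validate_intervals(annotation)
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(regions),
                                      intervals_to_gr(annotation),
                                      minoverlap = 1L)
  gene_sets <- replicate(nrow(regions), character(0), simplify = FALSE)
  if (length(hits) > 0) {
    by_region <- split(annotation$symbol[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    idx <- as.integer(names(by_region))
    gene_sets[idx] <- lapply(by_region, function(s) sort(unique(s)))
  }
  regions$genes <- gene_sets
  regions
}

#' Union of gene symbols mapped to a region set
#'
#' @param regions Output of [map_genes()].
#' @return Sorted character vector of unique symbols.
#' @export
region_gene_set <- function(regions) {
  sort(unique(unlist(regions$genes)))
}

#' Summary statistics of a merged region set
#'
#' @param regions Region tibble (disjoint, post-merge).
#' @return List with `total_size_mb`, `mean_size_mb` (`NA` when empty) and
#'   `n_regions`.
#' @export
region_stats <- function(regions) {
  n <- nrow(regions)
  total <- if (n == 0) 0 else sum(regions$end - regions$start) / 1e6
  list(
    total_size_mb = total,
    mean_size_mb = if (n == 0) NA_real_ else total / n,
    n_regions = n
  )
}
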