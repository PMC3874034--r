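#' Two-by-two contingency test with automatic method selection
#'
#' Tests association in the table
#' \preformatted{        in test set   in control set
#'   StMA        a              c
#'   other       b              d}
#' using the chi-squared test with Yates' continuity correction (the
#' correction term is capped at |O - E|, so small tables cannot yield
#' negative corrected deviations), falling back to the two-sided Fisher
#' exact test — point-probability rule: the p-value sums all tables with
#' fixed margins whose probability does not exceed the observed table's —
#' whenever any expected cell count is below 5, the condition under which
#' the chi-squared approximation becomes unreliable.
#'
#' @param a,b,c,d Non-negative counts; `a + b > 0` and `c + d > 0`.
#'
#' @return List with `method` (`"chi2_yates"` or `"fisher_exact"`),
#'   `p_value` (two-sided), `p_one_sided` (Fisher upper tail, enrichment
#'   direction), `fold_enrichment` = (a/(a+b))/(c/(c+d)) and
#'   `min_expected`.
#' @export
#' @examples
#' contingency_test(14, 852, 9, 2772)  # chi-squared with Yates
#' contingency_test(2, 83, 9, 2772)    # Fisher (expected a < 5)
contingency_test <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0) {
    stop("empty margin: a + b and c + d must be positive")
  }
  m <- matrix(c(a, c, b, d), nrow = 2, byrow = TRUE,
              dimnames = list(c("stma", "other"), c("test", "control")))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  min_expected <- min(expected)
  if (min_expected < 5) {
    method <- "fisher_exact"
    p <- stats::fisher.test(m)$p.value
  } else {
    method <- "chi2_yates"
    p <- suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
  }
  p_one <- stats::fisher.test(m, alternative = "greater")$p.value
  fold <- if (c == 0) {
    if (a == 0) NA_real_ else Inf
  } else {
    (a / (a + b)) / (c / (c + d))
  }
  list(method = method, p_value = unname(p), p_one_sided = unname(p_one),
       fold_enrichment = unname(fold), min_expected = unname(min_expected))
}

#' Build an enrichment report row from counts
#'
#' The three size-aware burden measures for one CNV dataset: StMA occurrence
#' per 1000 CNV-mapped genes, StMA genes per megabase of merged CNV region,
#' and the percentage of regions containing at least one StMA gene. Rates
#' are `NA` when their denominator is zero.
#'
#' @param dataset Dataset label.
#' @param total_genes Number of genes mapped to the dataset's regions.
#' @param stma_genes Number of those genes on the StMA list.
#' @param total_mb Total merged region size in Mb (`NA` if unknown).
#' @param n_regions Number of merged regions (`NA` if unknown).
#' @param n_regions_with_stma Regions containing at least one StMA gene.
#'
#' @return One-row tibble.
#' @export
enrichment_report <- function(dataset, total_genes, stma_genes,
                              total_mb = NA_real_, n_regions = NA_integer_,
                              n_regions_with_stma = NA_integer_) {
  stopifnot(stma_genes <= total_genes,
            is.na(n_regions_with_stma) || is.na(n_regions) ||
              n_regions_with_stma <= n_regions)
  tibble::tibble(
    dataset = dataset,
    total_genes = as.integer(total_genes),
    stma_genes = as.integer(stma_genes),
    stma_per_1000 = if (total_genes > 0) 1000 * stma_genes / total_genes else NA_real_,
    total_mb = as.numeric(total_mb),
    stma_per_mb = if (!is.na(total_mb) && total_mb > 0) stma_genes / total_mb else NA_real_,
    genes_per_mb = if (!is.na(total_mb) && total_mb > 0) total_genes / total_mb else NA_real_,
    n_regions = as.integer(n_regions),
    n_regions_with_stma = as.integer(n_regions_with_stma),
    pct_regions_with_stma = if (!is.na(n_regions) && n_regions > 0)
      100 * n_regions_with_stma / n_regions else NA_real_
  )
}

#' Enrichment report for a mapped region set
#'
#' Computes the burden measures of [enrichment_report()] directly from a
#' gene-mapped region set and the global StMA gene list.
#'
#' @param dataset Dataset label.
#' @param regions Output of [map_genes()].
#' @param stma_list Character vector of StMA gene symbols.
#'
#' @return One-row tibble as in [enrichment_report()].
#' @export
stma_metrics <- function(dataset, regions, stma_list) {
  stopifnot(!is.null(regions$genes))
  genes <- region_gene_set(regions)
  stats <- region_stats(regions)
  enrichment_report(
    dataset = dataset,
    total_genes = length(genes),
    stma_genes = length(intersect(genes, stma_list)),
    total_mb = stats$total_size_mb,
    n_regions = stats$n_regions,
    n_regions_with_stma = sum(vapply(regions$genes,
                                     function(g) any(g %in% stma_list),
                                     logical(1)))
  )
}

#' Enrichment of a report relative to the merged control dataset
#'
#' Fold enrichments are computed at full precision from the underlying
#' counts, never from rounded rates. Adds the gene-level contingency test
#' (StMA vs non-StMA genes, test vs control dataset) and, when region counts
#' are available, the region-level test (regions with vs without an StMA
#' gene).
#'
#' @param report,control One-row tibbles from [enrichment_report()] /
#'   [stma_metrics()].
#'
#' @return `report` with columns `fold_per_1000`, `fold_per_mb`,
#'   `gene_test_method`, `gene_test_p`, `region_test_method`,
#'   `region_test_p`.
#' @export
fold_vs_control <- function(report, control) {
  stopifnot(nrow(report) == 1, nrow(control) == 1)
  if (control$total_genes == 0 || control$stma_genes == 0) {
    stop("control rates undefined (no genes or no StMA genes in control)")
  }
  report$fold_per_1000 <-
    (report$stma_genes / report$total_genes) /
    (control$stma_genes / control$total_genes)
  report$fold_per_mb <- if (!is.na(report$stma_per_mb) && !is.na(control$stma_per_mb))
    report$stma_per_mb / control$stma_per_mb else NA_real_

  gt <- contingency_test(report$stma_genes,
                         report$total_genes - report$stma_genes,
                         control$stma_genes,
                         control$total_genes - control$stma_genes)
  report$gene_test_method <- gt$method
  report$gene_test_p <- gt$p_value

  if (!is.na(report$n_regions) && !is.na(control$n_regions)) {
    rt <- contingency_test(report$n_regions_with_stma,
                           report$n_regions - report$n_regions_with_stma,
                           control$n_regions_with_stma,
                           control$n_regions - control$n_regions_with_stma)
    report$region_test_method <- rt$method
    report$region_test_p <- rt$p_value
  } else {
    report$region_test_method <- NA_character_
    report$region_test_p <- NA_real_
  }
  report
}

#' Observed vs expected StMA hits in a candidate gene list
#'
#' Counts candidate-list hits in the StMA and biallelic lists; the expected
#' StMA hit count apportions the total hits by the StMA:biallelic list-size
#' ratio. Association is tested on the 2x2 of (hit, not hit) x (StMA,
#' biallelic).
#'
#' @param candidates Character vector of candidate gene symbols (from an
#'   association study).
#' @param stma,ba Disjoint StMA and biallelic gene lists.
#'
#' @return List with `observed_stma`, `observed_ba`, `hits`,
#'   `expected_stma`, `fold` (`NA` when there are no hits) and `test`
#'   ([contingency_test()] result).
#' @export
#' @examples
#' association_enrichment(c("g1", "g2"), stma = c("g1", "g3"),
#'                        ba = c("g2", "g4", "g5"))
association_enrichment <- function(candidates, stma, ba) {
  if (length(intersect(stma, ba)) > 0) stop("stma and ba lists must be disjoint")
  candidates <- unique(candidates)
  observed_stma <- length(intersect(candidates, stma))
  observed_ba <- length(intersect(candidates, ba))
  hits <- observed_stma + observed_ba
  expected_stma <- hits * length(stma) / (length(stma) + length(ba))
  fold <- if (hits == 0 || expected_stma == 0) NA_real_ else observed_stma / expected_stma
  test <- if (hits == 0) NULL else
    contingency_test(observed_stma, length(stma) - observed_stma,
                     observed_ba, length(ba) - observed_ba)
  list(observed_stma = observed_stma, observed_ba = observed_ba, hits = hits,
       expected_stma = expected_stma, fold = fold, test = test)
}

# Half-up rounding at the precision used in the published summary table
# (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble the summary table of CNV burden reports
#'
#' Lays out one column per dataset (control last) with the standard row set:
#' gene counts, StMA counts, per-1000 and per-Mb rates, folds relative to
#' the control, test p-values, region counts and sizes — and, when
#' permutation results are supplied, the matching permutation rows. Rates
#' are rounded half-up at the conventional precisions (one decimal for
#' per-1000 and genes-per-Mb, three for StMA-per-Mb, two for Mb sizes and
#' folds); p-values are reported to three significant digits.
#'
#' @param reports List of one-row tibbles from [fold_vs_control()] (cases)
#'   — the control report itself should be passed as `control`.
#' @param control Control report from [enrichment_report()] /
#'   [stma_metrics()].
#' @param permutation Optional named list of permutation results from
#'   [permutation_null()], one per case dataset.
#'
#' @return Tibble with a `row` label column and one column per dataset.
#' @export
build_table1 <- function(reports, control, permutation = NULL) {
  stopifnot(length(reports) >= 1)
  control$fold_per_1000 <- 1
  control$fold_per_mb <- if (is.na(control$stma_per_mb)) NA_real_ else 1
  control$gene_test_p <- NA_real_
  control$region_test_p <- NA_real_
  all_reports <- c(reports, list(control))

  fmt_p <- function(p) ifelse(is.na(p), "-", signif(p, 3))
  col_for <- function(r, perm) {
    vals <- c(
      "Total genes mapped to CNV regions" = r$total_genes,
      "StMA genes" = r$stma_genes,
      "Permutation StMA genes" =
        if (is.null(perm)) NA else round_half_up(perm$median_count),
      "StMA/1000 CNV genes" = round_half_up(r$stma_per_1000, 1),
      "Permutation genes/1000 CNV genes" =
        if (is.null(perm)) NA else round_half_up(perm$median_per_1000, 1),
      "Enrichment relative to controls (per 1000 genes)" =
        round_half_up(r$fold_per_1000, 2),
      "StMA enrichment test p-value" = fmt_p(r$gene_test_p),
      "Permutation test p-value (median)" =
        if (is.null(perm)) NA else fmt_p(perm$median_p),
      "CNV region total size (Mb)" = round_half_up(r$total_mb, 2),
      "CNV region mean size (Mb)" =
        round_half_up(r$total_mb / r$n_regions, 2),
      "Number of CNV regions" = r$n_regions,
      "CNV regions containing StMA" = sprintf(
        "%d (%s%%)", r$n_regions_with_stma,
        round_half_up(r$pct_regions_with_stma, 1)),
      "StMA CNV enrichment test p-value" = fmt_p(r$region_test_p),
      "Genes/Mb CNV region" = round_half_up(r$genes_per_mb, 1),
      "StMA genes/Mb CNV region" = round_half_up(r$stma_per_mb, 3),
      "Enrichment relative to controls (per Mb)" =
        round_half_up(r$fold_per_mb, 1)
    )
    as.character(vals)
  }

  cols <- lapply(all_reports, function(r) {
    perm <- if (!is.null(permutation)) permutation[[r$dataset]] else NULL
    col_for(r, perm)
  })
  out <- tibble::tibble(row = c(
    "Total genes mapped to CNV regions", "StMA genes",
    "Permutation StMA genes", "StMA/1000 CNV genes",
    "Permutation genes/1000 CNV genes",
    "Enrichment relative to controls (per 1000 genes)",
    "StMA enrichment test p-value", "Permutation test p-value (median)",
    "CNV region total size (Mb)", "CNV region mean size (Mb)",
    "Number of CNV regions", "CNV regions containing StMA",
    "StMA CNV enrichment test p-value", "Genes/Mb CNV region",
    "StMA genes/Mb CNV region", "Enrichment relative to controls (per Mb)"
  ))
  for (i in seq_along(all_reports)) {
    out[[all_reports[[i]]$dataset]] <- cols[[i]]
  }
  if (is.null(permutation)) {
    out <- out[!grepl("^Permutation", out$row), ]
  }
  out
}
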