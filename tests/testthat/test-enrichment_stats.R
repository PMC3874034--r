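test_that("contingency test reproduces the published gene-level statistics", {
  # autism CNV database set: 14 StMA of 866 genes vs 9 of 2781 control genes
  bbgre <- contingency_test(14, 852, 9, 2772)
  expect_identical(bbgre$method, "chi2_yates")
  expect_equal(round(bbgre$p_value, 6), 0.000078)
  expect_equal(round(bbgre$fold_enrichment, 2), 5)

  # schizophrenia-cohort CNV subset: 2 of 85 genes; low expected count
  sz <- contingency_test(2, 83, 9, 2772)
  expect_identical(sz$method, "fisher_exact")
  expect_lt(sz$min_expected, 5)
  expect_equal(round(sz$p_value, 4), 0.0402)
  expect_equal(round(sz$fold_enrichment, 2), 7.27)
})

test_that("perfectly balanced table gives Fisher p = 1", {
  t <- contingency_test(1, 1, 1, 1)
  expect_identical(t$method, "fisher_exact")
  expect_equal(t$p_value, 1)
  expect_equal(t$fold_enrichment, 1)
})

test_that("degenerate margins are rejected", {
  expect_error(contingency_test(0, 0, 1, 1), "margin")
  expect_error(contingency_test(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher branch matches brute-force hypergeometric enumeration", {
  set.seed(5)
  for (i in 1:200) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    c <- sample(0:20, 1); d <- sample(0:20, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    res <- contingency_test(a, b, c, d)
    if (res$method == "fisher_exact") {
      expect_equal(res$p_value, oracle_fisher_two_sided(a, b, c, d),
                   tolerance = 1e-10,
                   info = sprintf("table %d %d %d %d", a, b, c, d))
    }
  }
})

test_that("Yates branch matches the closed-form normal survival function", {
  set.seed(6)
  checked <- 0
  while (checked < 50) {
    a <- sample(5:60, 1); b <- sample(5:60, 1)
    c <- sample(5:60, 1); d <- sample(5:60, 1)
    res <- contingency_test(a, b, c, d)
    if (res$method != "chi2_yates") next
    expect_equal(res$p_value, oracle_yates_p(a, b, c, d), tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("method selection fires Fisher exactly when an expected cell is below 5", {
  set.seed(8)
  for (i in 1:200) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    if (a + b == 0 || c + d == 0) next
    m <- matrix(c(a, c, b, d), 2, byrow = TRUE)
    want_fisher <- min(outer(rowSums(m), colSums(m)) / sum(m)) < 5
    expect_identical(contingency_test(a, b, c, d)$method,
                     if (want_fisher) "fisher_exact" else "chi2_yates")
  }
})

test_that("one-sided enrichment p is monotone decreasing in a", {
  for (b in c(10, 40)) {
    for (c in c(3, 12)) {
      p <- vapply(0:15, function(a) contingency_test(a, b, c, 50)$p_one_sided,
                  numeric(1))
      expect_true(all(diff(p) <= 1e-12))
    }
  }
})

test_that("burden rates reproduce the published report arithmetic", {
  r <- enrichment_report("controls", total_genes = 2781, stma_genes = 9,
                         total_mb = 215.18, n_regions = 440,
                         n_regions_with_stma = 9)
  expect_equal(round(r$stma_per_1000, 1), 3.2)
  expect_equal(round(r$pct_regions_with_stma, 1), 2)

  r2 <- enrichment_report("bbgre", 866, 14, total_mb = 84.15,
                          n_regions = 69, n_regions_with_stma = 13)
  expect_equal(round(r2$stma_per_1000, 1), 16.2)
  expect_equal(round(r2$stma_per_mb, 3), 0.166)
  expect_equal(round(r2$genes_per_mb, 1), 10.3)
  expect_equal(round(r2$pct_regions_with_stma, 1), 18.8)

  empty <- enrichment_report("none", 0, 0)
  expect_true(is.na(empty$stma_per_1000))
})

test_that("folds against control come from full-precision counts", {
  control <- enrichment_report("controls", 2781, 9, 215.18, 440, 9)
  bbgre <- fold_vs_control(enrichment_report("bbgre", 866, 14, 84.15, 69, 13),
                           control)
  # 16.2 / 3.2 from the rounded rates would give 5.06; the count-based fold is 5.00
  expect_equal(round(bbgre$fold_per_1000, 2), 5)
  expect_equal(round(bbgre$fold_per_mb, 1), 4)
  expect_equal(round(bbgre$gene_test_p, 6), 0.000078)
  expect_identical(bbgre$region_test_method, "fisher_exact")
  expect_equal(signif(bbgre$region_test_p, 3), 3.33e-7)

  self <- fold_vs_control(control, control)
  expect_equal(self$fold_per_1000, 1)
  expect_equal(self$fold_per_mb, 1)
})

test_that("association-study enrichment counts observed vs expected hits", {
  # 2 observed vs 0.6 expected is a three-fold enrichment
  stma <- sprintf("s%02d", 1:30)
  ba <- sprintf("b%03d", 1:120)
  cand <- c(stma[1:2], ba[1:8])  # 10 hits, expected stma = 10 * 30/150 = 2
  res <- association_enrichment(cand, stma, ba)
  expect_equal(res$observed_stma, 2)
  expect_equal(res$expected_stma, 2)
  expect_equal(res$fold, 1)

  expect_equal(round(2 / 0.6, 2), 3.33)   # reported observed/expected folds
  expect_equal(round(3 / 1.54, 2), 1.95)

  none <- association_enrichment(c("x1", "x2"), stma, ba)
  expect_equal(none$hits, 0)
  expect_true(is.na(none$fold))
  expect_null(none$test)
  expect_error(association_enrichment(cand, stma, c(stma[1], ba)), "disjoint")
})

test_that("summary table lays out one column per dataset with control folds of 1", {
  control <- enrichment_report("controls", 2781, 9, 215.18, 440, 9)
  case <- fold_vs_control(enrichment_report("bbgre", 866, 14, 84.15, 69, 13),
                          control)
  tab <- build_table1(list(case), control)
  expect_identical(names(tab), c("row", "bbgre", "controls"))
  get <- function(row, col) tab[[col]][tab$row == row]
  expect_identical(get("StMA/1000 CNV genes", "bbgre"), "16.2")
  expect_identical(get("Enrichment relative to controls (per 1000 genes)", "controls"), "1")
  expect_identical(get("CNV regions containing StMA", "bbgre"), "13 (18.8%)")
  expect_identical(get("StMA genes/Mb CNV region", "bbgre"), "0.166")
  expect_identical(get("StMA enrichment test p-value", "controls"), "-")
})

test_that("a hand-computed five-region fixture flows through metrics correctly", {
  # two case regions (1 Mb + 2 Mb) with genes {gA,gB} and {gC};
  # three control regions of 1 Mb each with genes {gD},{gE,gF},{}
  case_regions <- tibble::tibble(
    chrom = "chr1", start = c(0, 5e6), end = c(1e6, 7e6),
    n_members = 1L, kind = "maximal",
    genes = list(c("gA", "gB"), "gC"))
  control_regions <- tibble::tibble(
    chrom = "chr2", start = c(0, 2e6, 4e6), end = c(1e6, 3e6, 5e6),
    n_members = 1L, kind = "maximal",
    genes = list("gD", c("gE", "gF"), character(0)))
  stma <- c("gA", "gE")

  case <- stma_metrics("case", case_regions, stma)
  ctrl <- stma_metrics("control", control_regions, stma)
  expect_equal(case$total_genes, 3)
  expect_equal(case$stma_genes, 1)
  expect_equal(case$stma_per_1000, 1000 / 3)
  expect_equal(case$total_mb, 3)
  expect_equal(case$stma_per_mb, 1 / 3)
  expect_equal(case$pct_regions_with_stma, 50)
  expect_equal(ctrl$stma_per_1000, 1000 / 3)

  both <- fold_vs_control(case, ctrl)
  expect_equal(both$fold_per_1000, 1)      # (1/3)/(1/3)
  expect_equal(both$fold_per_mb, (1 / 3) / (1 / 3))
})
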