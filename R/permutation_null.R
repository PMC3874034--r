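#' Transcriptome-resampling permutation null
#'
#' Tests whether an apparent StMA enrichment could arise simply because the
#' StMA list was derived from the neural stem cell transcriptome. Each
#' iteration replaces the StMA list with a uniform sample (without
#' replacement) of `sample_size` genes from the expressed-gene pool, counts
#' the sample's hits in each case dataset's gene set and in the control
#' gene set, and runs the gene-level contingency test. The same sample is
#' used across all datasets within an iteration, so dataset columns are
#' correlated exactly as a single resampled gene list implies. Per-iteration
#' p-values are Bonferroni-adjusted by the number of case datasets tested
#' simultaneously.
#'
#' @param expressed_genes Character vector: the resampling pool (genes
#'   measured in the allelic-expression assay).
#' @param sample_size Number of genes drawn per iteration; conventionally
#'   the size of the StMA list restricted to the pool, so the permutation is
#'   a like-for-like surrogate.
#' @param case_gene_sets Named list of character vectors, one per case
#'   dataset (genes mapped to that dataset's CNV regions).
#' @param control_gene_set Character vector: genes mapped to the merged
#'   control regions.
#' @param params [stma_params()]; uses `n_permutations` and `rng_seed`.
#' @param dataset_mb Optional named numeric vector of total region sizes
#'   (Mb) per case dataset, used for the per-Mb median; `NA` otherwise.
#' @param compute_tests Run the contingency test each iteration (set
#'   `FALSE` to collect counts only, e.g. for sampling diagnostics).
#'
#' @return Named list (one element per case dataset) of lists with fields
#'   `dataset`, `n_iter`, `sample_size`, `per_iter_counts`,
#'   `per_iter_control_counts`, `per_iter_p`, `per_iter_fold`,
#'   `median_count`, `median_per_1000`, `median_per_mb`, `median_fold`,
#'   `median_p`, `bonferroni_adjusted_p`, `median_adjusted_p`, `rng_seed`.
#' @export
permutation_null <- function(expressed_genes, sample_size, case_gene_sets,
                             control_gene_set, params = stma_params(),
                             dataset_mb = NULL, compute_tests = TRUE) {
  expressed_genes <- unique(expressed_genes)
  pool_n <- length(expressed_genes)
  if (sample_size > pool_n) {
    stop("sample_size (", sample_size, ") exceeds expressed-gene pool (", pool_n, ")")
  }
  stopifnot(length(case_gene_sets) >= 1, !is.null(names(case_gene_sets)))
  n_iter <- params$n_permutations
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)

  case_masks <- lapply(case_gene_sets, function(g) expressed_genes %in% g)
  control_mask <- expressed_genes %in% control_gene_set
  n_control <- length(unique(control_gene_set))
  n_case <- unname(vapply(case_gene_sets, function(g) length(unique(g)), integer(1)))
  k <- length(case_gene_sets)

  counts <- matrix(0L, nrow = n_iter, ncol = k,
                   dimnames = list(NULL, names(case_gene_sets)))
  control_counts <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    idx <- sample.int(pool_n, sample_size)
    control_counts[i] <- sum(control_mask[idx])
    for (j in seq_len(k)) counts[i, j] <- sum(case_masks[[j]][idx])
  }

  out <- vector("list", k)
  names(out) <- names(case_gene_sets)
  for (j in seq_len(k)) {
    dname <- names(case_gene_sets)[j]
    a <- counts[, j]
    p <- rep(NA_real_, n_iter)
    if (compute_tests) {
      for (i in seq_len(n_iter)) {
        p[i] <- contingency_test(a[i], n_case[j] - a[i],
                                 control_counts[i],
                                 n_control - control_counts[i])$p_value
      }
    }
    # per-iteration surrogate fold on the per-1000 basis; NA when the
    # control draw is empty
    fold <- ifelse(control_counts > 0,
                   (a / n_case[j]) / (control_counts / n_control), NA_real_)
    adj <- pmin(1, p * k)
    mb <- if (!is.null(dataset_mb) && dname %in% names(dataset_mb))
      dataset_mb[[dname]] else NA_real_
    out[[j]] <- list(
      dataset = dname,
      n_iter = n_iter,
      sample_size = sample_size,
      per_iter_counts = a,
      per_iter_control_counts = control_counts,
      per_iter_p = p,
      per_iter_fold = fold,
      median_count = stats::median(a),
      median_per_1000 = 1000 * stats::median(a) / n_case[j],
      median_per_mb = if (is.na(mb)) NA_real_ else stats::median(a) / mb,
      median_fold = stats::median(fold, na.rm = TRUE),
      median_p = if (compute_tests) stats::median(p) else NA_real_,
      bonferroni_adjusted_p = adj,
      median_adjusted_p = if (compute_tests) stats::median(adj) else NA_real_,
      rng_seed = params$rng_seed
    )
  }
  out
}

#' Empirical permutation p-value
#'
#' Upper-tail permutation p with the add-one correction:
#' `(1 + #\{iterations with count >= observed\}) / (n_iter + 1)`.
#'
#' @param observed_count Observed StMA hit count.
#' @param per_iter_counts Integer vector of permuted counts.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' empirical_p(10, rep(0, 9))  # 0.1
empirical_p <- function(observed_count, per_iter_counts) {
  stopifnot(length(per_iter_counts) >= 1)
  (1 + sum(per_iter_counts >= observed_count)) / (length(per_iter_counts) + 1)
}
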