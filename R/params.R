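#' Analysis parameters
#'
#' Bundles the tunable thresholds of the pipeline. The defaults implement the
#' published analysis: a clone is called monoallelic when one allele is
#' expressed more than 2.33-fold above the other; control CNVs shorter than
#' 100 kb are discarded before merging; the permutation null runs 10,000
#' iterations; a gene needs three informative biallelic sister clones to be
#' declared biallelic.
#'
#' @param mono_fold_threshold Fold difference between alleles above which a
#'   clone is called monoallelic (strictly greater). Must exceed 1.
#' @param min_control_cnv_length Minimum control CNV length in bp (strictly
#'   greater retained); applied to control datasets only.
#' @param n_permutations Number of permutation iterations.
#' @param rng_seed Integer seed for stochastic operations, or `NULL`.
#' @param min_clones_for_ba Minimum number of informative clones, all
#'   biallelic, required to classify a gene as biallelic.
#'
#' @return A list of class `stma_params`.
#' @export
#' @examples
#' stma_params()
stma_params <- function(mono_fold_threshold = 2.33,
                        min_control_cnv_length = 100000,
                        n_permutations = 10000,
                        rng_seed = NULL,
                        min_clones_for_ba = 3) {
  stopifnot(
    is.numeric(mono_fold_threshold), length(mono_fold_threshold) == 1,
    mono_fold_threshold > 1,
    is.numeric(min_control_cnv_length), min_control_cnv_length >= 0,
    is.numeric(n_permutations), n_permutations >= 1,
    is.null(rng_seed) || (is.numeric(rng_seed) && length(rng_seed) == 1),
    is.numeric(min_clones_for_ba), min_clones_for_ba >= 1
  )
  structure(
    list(
      mono_fold_threshold = mono_fold_threshold,
      min_control_cnv_length = min_control_cnv_length,
      n_permutations = as.integer(n_permutations),
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
      min_clones_for_ba = as.integer(min_clones_for_ba)
    ),
    class = "stma_params"
  )
}
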