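#' Call the allelic status of each clone
#'
#' Assigns each gene-by-clone measurement a call: `mono_a` or `mono_b` when
#' the higher-expressed allele exceeds the lower by more than
#' `params$mono_fold_threshold` (strictly greater; a ratio of exactly 2.33 is
#' biallelic), `biallelic` otherwise, and `no_call` when both alleles are
#' zero (the allelic ratio is undefined). A single expressed allele with the
#' other at zero is the strongest monoallelic signal and is called mono.
#'
#' @param measurements Data frame with columns `gene`, `clone_id`,
#'   `cell_source`, `expr_a`, `expr_b`. Expression values must be
#'   non-negative and finite; (gene, clone_id) must be unique within a cell
#'   source.
#' @param params [stma_params()].
#'
#' @return The input as a tibble with columns `allele_ratio`
#'   (max/min, `Inf` when one allele is silent, `NA` for no_call) and `call`.
#' @export
#' @examples
#' m <- tibble::tibble(gene = "g1", clone_id = "c1", cell_source = "cortex",
#'                     expr_a = 75, expr_b = 25)
#' call_alleles(m)$call
call_alleles <- function(measurements, params = stma_params()) {
  required <- c("gene", "clone_id", "cell_source", "expr_a", "expr_b")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurements is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  a <- measurements$expr_a
  b <- measurements$expr_b
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("expression columns must be numeric")
  }
  bad <- which(!is.finite(a) | !is.finite(b) | a < 0 | b < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite expression values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(measurements$cell_source, measurements$gene,
               measurements$clone_id, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup > 0) {
    stop("duplicated (gene, clone_id) within a cell source at row: ", dup)
  }

  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ratio <- hi / lo                       # Inf when lo == 0, hi > 0
  ratio[hi == 0] <- NA_real_
  thr <- params$mono_fold_threshold
  call <- rep("biallelic", length(a))
  call[which(ratio > thr & a > b)] <- "mono_a"
  call[which(ratio > thr & b > a)] <- "mono_b"
  call[hi == 0] <- "no_call"
  out <- tibble::as_tibble(measurements)
  out$allele_ratio <- ratio
  out$call <- call
  out
}

# Vectorised status rule shared by classify_gene() and classify_genes().
# Inputs are per-(gene, source) counts of informative call types.
status_from_counts <- function(n_mono_a, n_mono_b, n_bi, min_clones_for_ba) {
  n_inf <- n_mono_a + n_mono_b + n_bi
  n_mono <- n_mono_a + n_mono_b
  stma <- n_mono >= 1 & (n_bi >= 1 | (n_mono_a >= 1 & n_mono_b >= 1))
  ba <- !stma & n_inf >= min_clones_for_ba & n_bi == n_inf
  cma <- !stma & !ba & n_inf >= 2 & (n_mono_a == n_inf | n_mono_b == n_inf)
  dplyr::case_when(
    stma ~ "stma",
    ba ~ "ba",
    cma ~ "consistent_ma",
    TRUE ~ "unclassified"
  )
}

#' Classify one gene from its sister-clone calls
#'
#' A gene is `stma` (stochastic monoallelic) when at least one clone is
#' monoallelic and a genetically identical sister clone shows a different
#' informative state — biallelic, or monoallelic for the other allele. It is
#' `ba` (biallelic) when at least `params$min_clones_for_ba` informative
#' clones are available and every one is biallelic. It is `consistent_ma`
#' when two or more clones are all monoallelic for the same allele (the
#' imprinting-like pattern, excluded from the StMA list). Anything else —
#' including a single monoallelic clone with no informative sister — is
#' `unclassified`.
#'
#' @param calls Character vector of per-clone calls for one gene within one
#'   cell source (`mono_a`, `mono_b`, `biallelic`, `no_call`).
#' @param params [stma_params()].
#'
#' @return A single status string.
#' @export
#' @examples
#' classify_gene(c("mono_a", "biallelic"))          # "stma"
#' classify_gene(c("mono_a", "mono_a"))             # "consistent_ma"
classify_gene <- function(calls, params = stma_params()) {
  valid <- c("mono_a", "mono_b", "biallelic", "no_call")
  if (!all(calls %in% valid)) {
    stop("unknown call values: ", paste(setdiff(calls, valid), collapse = ", "))
  }
  informative <- calls[calls != "no_call"]
  if (length(informative) == 0) {
    warning("no informative calls; gene is unclassified")
    return("unclassified")
  }
  status_from_counts(
    sum(informative == "mono_a"),
    sum(informative == "mono_b"),
    sum(informative == "biallelic"),
    params$min_clones_for_ba
  )
}

#' Classify every gene in a call table
#'
#' Applies [classify_gene()] per gene within each cell source, vectorised
#' over the whole table.
#'
#' @param calls Output of [call_alleles()] (needs `gene`, `cell_source`,
#'   `call`).
#' @param params [stma_params()].
#'
#' @return Tibble with columns `cell_source`, `gene`, `status`, `n_clones`
#'   (informative clone count).
#' @export
classify_genes <- function(calls, params = stma_params()) {
  stopifnot(all(c("gene", "cell_source", "call") %in% names(calls)))
  src <- factor(calls$cell_source)
  gene <- factor(calls$gene)
  ng <- nlevels(gene)
  code <- (as.integer(src) - 1L) * ng + as.integer(gene)
  nbins <- nlevels(src) * ng
  n_a <- tabulate(code[calls$call == "mono_a"], nbins)
  n_b <- tabulate(code[calls$call == "mono_b"], nbins)
  n_bi <- tabulate(code[calls$call == "biallelic"], nbins)
  present <- which(tabulate(code, nbins) > 0)
  out <- tibble::tibble(
    cell_source = levels(src)[(present - 1L) %/% ng + 1L],
    gene = levels(gene)[(present - 1L) %% ng + 1L],
    status = status_from_counts(n_a[present], n_b[present], n_bi[present],
                                params$min_clones_for_ba),
    n_clones = (n_a + n_b + n_bi)[present]
  )
  n_uninformative <- sum(out$n_clones == 0)
  if (n_uninformative > 0) {
    warning(n_uninformative, " gene(s) had no informative calls and are unclassified")
  }
  out
}

#' Merge per-source classifications into global StMA and biallelic lists
#'
#' The global StMA list is the union of the per-source StMA lists; the
#' global biallelic list is the union of the per-source biallelic lists. A
#' gene that is StMA in one cell source and biallelic in another is assigned
#' to the StMA list only — demonstrated allelic variability in any source
#' overrides biallelic behaviour elsewhere — and the conflict is reported
#' via `message()`.
#'
#' @param classifications Tibble from [classify_genes()] (columns `gene`,
#'   `status`; `cell_source` optional).
#'
#' @return List with character vectors `stma` and `ba` (sorted, disjoint).
#' @export
merge_gene_lists <- function(classifications) {
  if (nrow(classifications) == 0) {
    return(list(stma = character(0), ba = character(0)))
  }
  stopifnot(all(c("gene", "status") %in% names(classifications)))
  stma <- sort(unique(classifications$gene[classifications$status == "stma"]))
  ba_raw <- sort(unique(classifications$gene[classifications$status == "ba"]))
  conflicts <- intersect(ba_raw, stma)
  if (length(conflicts) > 0) {
    message(length(conflicts),
            " gene(s) StMA in one source and biallelic in another; kept as StMA: ",
            paste(utils::head(conflicts, 10), collapse = ", "))
  }
  list(stma = stma, ba = setdiff(ba_raw, stma))
}

#' Read a clonal allelic-expression table
#'
#' Tab-separated with header columns `gene`, `clone_id`, `cell_source`,
#' `expr_a`, `expr_b`.
#'
#' @param path File path.
#' @return Tibble of measurements.
#' @export
read_clone_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "clone_id", "cell_source", "expr_a", "expr_b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("clone table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Read / write one-symbol-per-line gene lists
#'
#' @param path File path.
#' @return `read_gene_list()`: character vector of unique symbols, blank
#'   lines dropped.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(trimws(x[nzchar(trimws(x))]))
}

#' @rdname read_gene_list
#' @param genes Character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
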