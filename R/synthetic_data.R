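# Synthetic cohort generator. Plants known allelic statuses and a known
# case-CNV enrichment so every pipeline stage can be validated end to end
# with no external data. Each generator derives its stream from
# spec$rng_seed plus a fixed offset, so the three stages are individually
# reproducible and mutually independent.

#' Specification of a synthetic cohort
#'
#' Defaults mirror the published study conditions where those are stated:
#' three sister clones from each of three neural stem cell sources, a
#' measurement-noise level well inside the 2.33-fold calling margin, and
#' the case/control CNV size asymmetry of the published datasets (cases
#' larger). The default cohort is sized on the largest published case
#' dataset — the developmental-disability CNV morbidity map (650 merged
#' regions of mean 0.78 Mb) against a merged control set of ~1600 retained
#' CNVs of mean 0.49 Mb — on a 20 x 500 Mb synthetic genome carrying
#' 20,000 fixed-length (10 kb) genes. That geometry is deliberate: the
#' expected StMA counts in both datasets are large (tens to low hundreds),
#' and each dataset's gene set is a small fraction of the gene universe,
#' which are jointly the conditions under which the Yates-corrected
#' chi-squared test operates near its nominal level; and the annotation is
#' sparse (2 genes/Mb), which keeps a five-fold per-gene enrichment
#' geometrically achievable within single CNVs (see [generate_cnvs()]).
#' The planted enrichment defaults to 5, the strongest published
#' gene-level fold.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes,chrom_length Genome shape (bp per chromosome).
#' @param frac_stma,frac_ba Fractions of genes planted StMA and biallelic
#'   (must sum to at most 1; the remainder is consistently monoallelic).
#' @param n_clones Sister clones per cell source.
#' @param noise_sd SD of multiplicative log-normal measurement noise on
#'   each allele intensity.
#' @param n_case_cnvs,n_control_cnvs CNV counts per dataset.
#' @param case_cnv_mean_mb,control_cnv_mean_mb Mean CNV length (Mb;
#'   exponential length model).
#' @param planted_enrichment Target fold inflation of the per-gene StMA
#'   rate among case-CNV-covered genes relative to the genome-wide rate
#'   (>= 1; requires `planted_enrichment * frac_stma < 1`).
#' @param rng_seed Integer seed.
#'
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20000,
                           n_chromosomes = 20,
                           chrom_length = 500e6,
                           frac_stma = 0.05,
                           frac_ba = 0.90,
                           n_clones = 3,
                           noise_sd = 0.15,
                           n_case_cnvs = 650,
                           n_control_cnvs = 2000,
                           case_cnv_mean_mb = 0.78,
                           control_cnv_mean_mb = 0.49,
                           planted_enrichment = 5,
                           rng_seed = 1) {
  stopifnot(
    n_genes >= 1, n_chromosomes >= 1, chrom_length > 0,
    frac_stma >= 0, frac_ba >= 0, frac_stma + frac_ba <= 1,
    n_clones >= 1, noise_sd >= 0,
    n_case_cnvs >= 0, n_control_cnvs >= 0,
    case_cnv_mean_mb > 0, control_cnv_mean_mb > 0,
    planted_enrichment >= 1,
    planted_enrichment * frac_stma < 1
  )
  structure(
    list(n_genes = as.integer(n_genes),
         n_chromosomes = as.integer(n_chromosomes),
         chrom_length = chrom_length,
         frac_stma = frac_stma, frac_ba = frac_ba,
         n_clones = as.integer(n_clones), noise_sd = noise_sd,
         n_case_cnvs = as.integer(n_case_cnvs),
         n_control_cnvs = as.integer(n_control_cnvs),
         case_cnv_mean_mb = case_cnv_mean_mb,
         control_cnv_mean_mb = control_cnv_mean_mb,
         planted_enrichment = planted_enrichment,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
}

GENE_LENGTH_BP <- 10000L
EXPRESSED_MEAN <- 100
SILENCED_MEAN <- 2  # near zero, so calls go through the fold-ratio path

#' Generate a toy genome annotation
#'
#' Places `n_genes` fixed-length (10 kb) genes uniformly at random and
#' non-overlapping across the chromosomes, allocating genes to chromosomes
#' as evenly as possible. Deterministic under `rng_seed`.
#'
#' @param spec [synthetic_spec()].
#' @return Annotation tibble (`symbol`, `chrom`, `start`, `end`; 0-based
#'   half-open).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$rng_seed + 1L)
  per_chrom <- diff(floor(seq(0, spec$n_genes, length.out = spec$n_chromosomes + 1)))
  if (max(per_chrom) * GENE_LENGTH_BP > spec$chrom_length) {
    stop("cannot place ", spec$n_genes, " non-overlapping 10 kb genes on ",
         spec$n_chromosomes, " chromosome(s) of ", spec$chrom_length, " bp")
  }
  pieces <- lapply(seq_len(spec$n_chromosomes), function(ci) {
    n <- per_chrom[ci]
    if (n == 0) return(NULL)
    slack <- spec$chrom_length - n * GENE_LENGTH_BP
    # sorted uniform offsets into the slack keep genes disjoint
    start <- floor(sort(stats::runif(n, 0, slack))) +
      (seq_len(n) - 1) * GENE_LENGTH_BP
    tibble::tibble(chrom = paste0("chr", ci),
                   start = as.numeric(start),
                   end = as.numeric(start + GENE_LENGTH_BP))
  })
  out <- dplyr::bind_rows(pieces)
  out$symbol <- sprintf("g%05d", seq_len(nrow(out)))
  out[, c("symbol", "chrom", "start", "end")]
}

#' Generate clonal allelic-expression measurements with known truth
#'
#' Assigns each gene a true status (StMA, biallelic, or consistent
#' monoallelic, in proportions `frac_stma` / `frac_ba` / remainder) and
#' simulates per-allele intensities for `n_clones` sister clones in each of
#' three cell sources. Biallelic genes express both alleles at the same
#' mean; StMA genes pick an expressed allele at random per clone, with the
#' silenced allele near (not exactly) zero so calls exercise the fold-ratio
#' rule; the clone allele pattern is constrained to include at least one
#' discordant sister (the defining StMA observation) whenever `n_clones >=
#' 2`. Consistent-MA genes fix one allele across all clones and sources.
#' All intensities carry multiplicative log-normal noise with SD
#' `noise_sd`.
#'
#' @param spec [synthetic_spec()].
#' @return List with `measurements` (tibble: `gene`, `clone_id`,
#'   `cell_source`, `expr_a`, `expr_b`) and `truth` (tibble: `gene`,
#'   `status`).
#' @export
generate_clones <- function(spec) {
  set.seed(spec$rng_seed + 2L)
  n <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  n_stma <- round(spec$frac_stma * n)
  n_ba <- round(spec$frac_ba * n)
  status <- sample(c(rep("stma", n_stma), rep("ba", n_ba),
                     rep("consistent_ma", n - n_stma - n_ba)))
  truth <- tibble::tibble(gene = genes, status = status)

  sources <- c("cortex", "striatum", "spinal_cord")
  nc <- spec$n_clones
  # allele fixed per gene for consistent-MA (imprinting-like, gene-intrinsic)
  cma_allele <- sample(c("a", "b"), n, replace = TRUE)

  grids <- lapply(sources, function(src) {
    g <- tidyr_expand(genes, nc)
    g$cell_source <- src
    g$clone_id <- paste0(substr(src, 1, 3), "_c", g$clone)
    # which allele is expressed ("a", "b", or "both")
    expressed <- rep("both", nrow(g))
    is_stma <- status[g$gene_idx] == "stma"
    if (any(is_stma)) {
      pick <- sample(c("a", "b"), sum(is_stma), replace = TRUE)
      expressed[is_stma] <- pick
      if (nc >= 2) {
        # force at least one discordant sister clone per (gene, source)
        m <- matrix(expressed, nrow = nc)  # clones x genes (column-major by gene)
        stma_cols <- which(status == "stma")
        for (col in stma_cols) {
          if (length(unique(m[, col])) == 1) {
            flip <- sample.int(nc, 1)
            m[flip, col] <- if (m[flip, col] == "a") "b" else "a"
          }
        }
        expressed <- as.vector(m)
      }
    }
    is_cma <- status[g$gene_idx] == "consistent_ma"
    expressed[is_cma] <- cma_allele[g$gene_idx[is_cma]]
    g$expressed <- expressed
    g
  })
  df <- dplyr::bind_rows(grids)

  mean_a <- rep(SILENCED_MEAN, nrow(df))
  mean_a[df$expressed != "b"] <- EXPRESSED_MEAN
  mean_b <- rep(SILENCED_MEAN, nrow(df))
  mean_b[df$expressed != "a"] <- EXPRESSED_MEAN
  nrows <- nrow(df)
  df$expr_a <- mean_a * stats::rlnorm(nrows, 0, spec$noise_sd)
  df$expr_b <- mean_b * stats::rlnorm(nrows, 0, spec$noise_sd)

  measurements <- tibble::tibble(
    gene = df$gene, clone_id = df$clone_id, cell_source = df$cell_source,
    expr_a = df$expr_a, expr_b = df$expr_b
  )
  list(measurements = measurements, truth = truth)
}

# clone-major expansion: all clones of gene 1, then gene 2, ... so that
# matrix(x, nrow = n_clones) has one gene per column
tidyr_expand <- function(genes, n_clones) {
  n <- length(genes)
  tibble::tibble(
    gene_idx = rep(seq_len(n), each = n_clones),
    gene = rep(genes, each = n_clones),
    clone = rep(seq_len(n_clones), times = n)
  )
}

#' Generate case and control CNV datasets with a planted enrichment
#'
#' Control CNVs are placed uniformly (chromosome uniform — all chromosomes
#' share one length — centre uniform) with exponentially distributed
#' lengths of mean `control_cnv_mean_mb`. Case CNVs use mean
#' `case_cnv_mean_mb`; each one is independently either anchored (with
#' probability `pi`) — centred at a uniform point inside a distinct,
#' randomly chosen true-StMA gene — or placed uniformly. Writing `e` for
#' `planted_enrichment`, `q` for `frac_stma` and `a` for the expected
#' number of genes a uniformly placed case CNV covers (gene density times
#' mean length), the anchoring probability
#' `pi = a q (e - 1) / (1 - e q)` makes the expected StMA fraction among
#' case-covered genes `(a q + pi) / (a + pi) = e q`, i.e. the per-gene
#' StMA rate in case CNVs is inflated `e`-fold over the genome-wide rate.
#' Anchors are drawn without replacement, so the planted excess is spread
#' over distinct StMA genes rather than piled on a few loci (`pi` is capped
#' at 1; the cap binds only when `e` approaches the geometric maximum
#' `(a q + 1) / (q (a + 1))`). With `e = 1`, `pi = 0` and placement is
#' uniform.
#'
#' @param spec [synthetic_spec()].
#' @param annotation Tibble from [generate_genome()].
#' @param truth Truth tibble from [generate_clones()] (`gene`, `status`).
#' @return List with interval tibbles `case` and `control`.
#' @export
generate_cnvs <- function(spec, annotation, truth) {
  set.seed(spec$rng_seed + 3L)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))

  draw_uniform <- function(n, mean_mb) {
    if (n == 0) {
      return(tibble::tibble(chrom = character(0), start = numeric(0),
                            end = numeric(0)))
    }
    chrom <- sample(chroms, n, replace = TRUE)
    len <- pmax(1000, round(stats::rexp(n, rate = 1 / (mean_mb * 1e6))))
    len <- pmin(len, spec$chrom_length)
    center <- stats::runif(n, 0, spec$chrom_length)
    start <- pmax(0, round(center - len / 2))
    end <- pmin(spec$chrom_length, start + len)
    start <- pmax(0, end - len)
    tibble::tibble(chrom = chrom, start = start, end = end)
  }

  control <- draw_uniform(spec$n_control_cnvs, spec$control_cnv_mean_mb)
  control$label <- sprintf("ctrl_%04d", seq_len(nrow(control)))

  e <- spec$planted_enrichment
  q <- spec$frac_stma
  n_case <- spec$n_case_cnvs
  if (n_case == 0) {
    case <- tibble::tibble(chrom = character(0), start = numeric(0),
                           end = numeric(0), label = character(0))
    return(list(case = case, control = control))
  }
  stma_ann <- annotation[annotation$symbol %in%
                           truth$gene[truth$status == "stma"], ]
  if (e == 1 || q == 0 || nrow(stma_ann) == 0) {
    case <- draw_uniform(n_case, spec$case_cnv_mean_mb)
  } else {
    genome_mb <- spec$n_chromosomes * spec$chrom_length / 1e6
    a <- (spec$n_genes / genome_mb) * spec$case_cnv_mean_mb
    pi_anchor <- min(1, a * q * (e - 1) / (1 - e * q))
    anchored <- stats::runif(n_case) < pi_anchor
    case <- draw_uniform(n_case, spec$case_cnv_mean_mb)
    n_anchor <- sum(anchored)
    if (n_anchor > 0) {
      anchor_idx <- sample.int(nrow(stma_ann), n_anchor,
                               replace = n_anchor > nrow(stma_ann))
      g <- stma_ann[anchor_idx, ]
      center <- stats::runif(n_anchor, g$start, g$end)
      len <- case$end[anchored] - case$start[anchored]
      start <- pmax(0, round(center - len / 2))
      end <- pmin(spec$chrom_length, start + len)
      case$chrom[anchored] <- g$chrom
      case$start[anchored] <- pmax(0, end - len)
      case$end[anchored] <- end
    }
  }
  case$label <- sprintf("case_%04d", seq_len(nrow(case)))
  list(case = case, control = control)
}
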