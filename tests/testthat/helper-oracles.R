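# Independent brute-force oracles. These deliberately share no code with
# the package implementation: direct definitions, O(n^2) closures and
# per-base counting at toy scale.

# Truth-table implementation of the gene-status definitions.
oracle_classify <- function(calls, min_clones_for_ba = 3) {
  inf <- calls[calls != "no_call"]
  if (length(inf) == 0) return("unclassified")
  has_mono <- any(inf %in% c("mono_a", "mono_b"))
  discordant <- has_mono && (
    any(inf == "biallelic") ||
      (any(inf == "mono_a") && any(inf == "mono_b"))
  )
  if (discordant) return("stma")
  if (length(inf) >= min_clones_for_ba && all(inf == "biallelic")) return("ba")
  if (length(inf) >= 2 && length(unique(inf)) == 1 &&
      inf[1] %in% c("mono_a", "mono_b")) return("consistent_ma")
  "unclassified"
}

# Pairwise-closure interval merge: repeatedly fuse any overlapping pair
# until a fixed point.
oracle_merge <- function(df) {
  items <- lapply(seq_len(nrow(df)), function(i)
    list(chrom = df$chrom[i], start = df$start[i], end = df$end[i], n = 1L))
  repeat {
    fused <- FALSE
    for (i in seq_along(items)) {
      for (j in seq_along(items)) {
        if (j <= i) next
        a <- items[[i]]; b <- items[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          items[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                             end = max(a$end, b$end), n = a$n + b$n)
          items[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
      if (fused) break
    }
    if (!fused) break
  }
  out <- do.call(rbind, lapply(items, function(x)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               n_members = x$n)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Per-base coverage counter for minimal (depth >= 2) regions, with
# singleton-cluster passthrough. Coordinates must be small.
oracle_minimal <- function(df) {
  merged <- oracle_merge(df)
  rows <- list()
  for (i in seq_len(nrow(merged))) {
    cl <- merged[i, ]
    members <- df[df$chrom == cl$chrom & df$start < cl$end & df$end > cl$start, ]
    if (nrow(members) == 1) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cl$chrom, start = members$start, end = members$end)
      next
    }
    depth <- integer(cl$end - cl$start)  # base b = position cl$start + b - 1
    for (k in seq_len(nrow(members))) {
      lo <- max(members$start[k], cl$start) - cl$start + 1
      hi <- min(members$end[k], cl$end) - cl$start
      depth[lo:hi] <- depth[lo:hi] + 1L
    }
    deep <- depth >= 2
    if (!any(deep)) next
    runs <- rle(deep)
    pos <- cumsum(c(0, runs$lengths))
    for (k in which(runs$values)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cl$chrom,
        start = cl$start + pos[k],
        end = cl$start + pos[k + 1])
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Two-sided Fisher p by full enumeration of tables with fixed margins,
# point-probability rule.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # test-set margin
  n <- c + d          # control margin
  k <- a + c          # StMA margin
  probs <- vapply(max(0, k - n):min(m, k), function(x)
    dhyper(x, m, n, k), numeric(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form Yates-corrected chi-squared p via the normal survival
# function (1-df chi-squared is a squared standard normal).
oracle_yates_p <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)
  x <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  2 * pnorm(-sqrt(x))
}

random_intervals <- function(n, chrom_pool = c("chrA", "chrB"), max_pos = 10000) {
  start <- sample.int(max_pos - 200, n, replace = TRUE)
  len <- sample.int(500, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chrom_pool, n, replace = TRUE),
    start = start,
    end = pmin(start + len, max_pos)
  )
}
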