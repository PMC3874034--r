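iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)

test_that("BED reader parses, validates and reports line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000\tpat1", "chr2 200 900"), f)
  b <- read_cnv_bed(f)
  expect_equal(b$chrom, c("chr1", "chr2"))
  expect_equal(b$start, c(1000L, 200L))
  expect_equal(b$end, c(5000L, 900L))
  expect_equal(b$label, c("pat1", NA))

  writeLines(c("chr1\t1000\t5000", "chr1\t5000\t1000"), f)
  expect_error(read_cnv_bed(f), "line.*2")
  writeLines("chr1\tabc\t5000", f)
  expect_error(read_cnv_bed(f), "non-numeric")
  writeLines(character(0), f)
  expect_warning(empty <- read_cnv_bed(f), "no records")
  expect_equal(nrow(empty), 0)
})

test_that("one-based input tables are shifted to half-open on read", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("chr1\t1001\t5000", f)
  expect_equal(read_cnv_bed(f, one_based = TRUE)$start, 1000L)
})

test_that("control size selection keeps strictly greater than 100 kb", {
  x <- iv("chr1", c(0, 0, 0), c(100001, 100000, 99999))
  kept <- filter_min_length(x)
  expect_equal(kept$end, 100001)
})

test_that("maximal merge fuses overlapping CNVs into disjoint regions", {
  m <- merge_maximal(iv("chr1", c(100, 150), c(200, 300)))
  expect_equal(m[, c("start", "end", "n_members")],
               tibble::tibble(start = 100L, end = 300L, n_members = 2L))

  # different chromosomes never merge
  m2 <- merge_maximal(iv(c("chr1", "chr2"), c(100, 100), c(200, 200)))
  expect_equal(nrow(m2), 2)

  # abutting intervals do not overlap and stay separate
  m3 <- merge_maximal(iv("chr1", c(100, 200), c(200, 300)))
  expect_equal(nrow(m3), 2)
})

test_that("maximal merge is idempotent and order-invariant", {
  set.seed(7)
  for (i in 1:20) {
    x <- random_intervals(sample(2:50, 1))
    m1 <- merge_maximal(x)
    expect_equal(merge_maximal(m1[, c("chrom", "start", "end")])[, 1:3], m1[, 1:3])
    expect_equal(merge_maximal(x[sample(nrow(x)), ]), m1)
  }
})

test_that("maximal merge equals the pairwise-closure oracle on random fixtures", {
  set.seed(13)
  for (i in 1:25) {
    x <- random_intervals(sample(2:50, 1))
    got <- as.data.frame(merge_maximal(x)[, c("chrom", "start", "end", "n_members")])
    want <- oracle_merge(as.data.frame(x))
    rownames(got) <- rownames(want) <- NULL
    got$start <- as.integer(got$start); want$start <- as.integer(want$start)
    got$end <- as.integer(got$end); want$end <- as.integer(want$end)
    got$n_members <- as.integer(got$n_members)
    want$n_members <- as.integer(want$n_members)
    expect_equal(got, want)
  }
})

test_that("every input interval lies in exactly one merged region and spans are preserved", {
  set.seed(29)
  x <- random_intervals(40)
  m <- merge_maximal(x)
  containing <- vapply(seq_len(nrow(x)), function(i) {
    sum(m$chrom == x$chrom[i] & m$start <= x$start[i] & m$end >= x$end[i])
  }, integer(1))
  expect_true(all(containing == 1))
  expect_equal(sum(m$end - m$start),
               sum(merge_maximal(x)$end - merge_maximal(x)$start))
  expect_equal(sum(m$n_members), nrow(x))
})

test_that("minimal overlap regions follow the depth-2 construction", {
  # pairwise intersection
  m <- minimal_overlap_regions(iv("chr1", c(100, 200), c(300, 400)))
  expect_equal(m[, c("start", "end")], tibble::tibble(start = 200L, end = 300L))

  # singleton cluster passes through unchanged
  m2 <- minimal_overlap_regions(iv("chr1", 100, 200))
  expect_equal(m2[, c("start", "end")], tibble::tibble(start = 100L, end = 200L))

  # adjacent depth-2 runs merge across the chain
  m3 <- minimal_overlap_regions(iv("chr1", c(100, 200, 250), c(300, 400, 500)))
  expect_equal(m3[, c("start", "end")], tibble::tibble(start = 200L, end = 400L))
})

test_that("minimal regions equal the per-base coverage oracle and nest in maximal regions", {
  set.seed(17)
  for (i in 1:25) {
    x <- random_intervals(sample(2:40, 1))
    got <- as.data.frame(minimal_overlap_regions(x)[, c("chrom", "start", "end")])
    want <- oracle_minimal(as.data.frame(x))
    rownames(got) <- rownames(want) <- NULL
    got$start <- as.integer(got$start); got$end <- as.integer(got$end)
    want$start <- as.integer(want$start); want$end <- as.integer(want$end)
    expect_equal(got, want)

    maxi <- merge_maximal(x)
    inside <- vapply(seq_len(nrow(got)), function(k) {
      any(maxi$chrom == got$chrom[k] & maxi$start <= got$start[k] &
            maxi$end >= got$end[k])
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("gene mapping attaches symbols on >= 1 bp overlap, half-open", {
  regions <- merge_maximal(iv("chr1", 100, 300))
  ann <- tibble::tibble(symbol = c("gA", "gB"), chrom = "chr1",
                        start = c(250, 300), end = c(400, 400))
  mapped <- map_genes(regions, ann)
  expect_equal(mapped$genes[[1]], "gA")  # gB abuts at 300: no shared base
  expect_equal(region_gene_set(mapped), "gA")
})

test_that("a symbol in two regions counts once in the dataset gene set", {
  regions <- merge_maximal(iv("chr1", c(0, 500), c(100, 600)))
  ann <- tibble::tibble(symbol = "gX", chrom = "chr1",
                        start = c(50, 550), end = c(60, 560))
  mapped <- map_genes(regions, ann)
  expect_equal(lengths(mapped$genes), c(1L, 1L))
  expect_equal(region_gene_set(mapped), "gX")
  expect_warning(map_genes(regions, ann[0, ]), "empty annotation")
})

test_that("region stats report totals in Mb and handle the empty set", {
  r <- merge_maximal(iv("chr1", 0, 1e6))
  s <- region_stats(r)
  expect_equal(s$total_size_mb, 1)
  expect_equal(s$mean_size_mb, 1)
  expect_equal(s$n_regions, 1)

  s0 <- region_stats(merge_maximal(iv(character(0), numeric(0), numeric(0))))
  expect_equal(s0$total_size_mb, 0)
  expect_true(is.na(s0$mean_size_mb))
})
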