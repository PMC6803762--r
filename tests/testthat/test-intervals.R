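test_that("normalization merges overlapping and touching intervals and conserves coverage", {
  expect_equal(normalize_intervals(intervals("chr1", c(100, 150), c(160, 200))),
               tibble::tibble(chrom = "chr1", start = 100, end = 200))
  expect_equal(normalize_intervals(intervals("chr1", c(100, 150), c(150, 200))),
               tibble::tibble(chrom = "chr1", start = 100, end = 200))
  disjoint <- intervals("chr1", c(0, 100), c(50, 150))
  expect_equal(normalize_intervals(disjoint)[, c("start", "end")],
               disjoint[, c("start", "end")])
  expect_error(normalize_intervals(tibble::tibble(chrom = "chr1", start = 200, end = 100)),
               "malformed interval")

  set.seed(101)
  for (i in 1:50) {
    x <- random_interval_set(sample(1:10, 1))
    nx <- normalize_intervals(x)
    expect_equal(nx, normalize_intervals(nx))                 # idempotent
    expect_equal(nx[, c("chrom", "start", "end")],
                 oracle_normalize_one(x, 600))
    gaps <- nx$start[-1] - nx$end[-nrow(nx)]
    if (nrow(nx) > 1) expect_true(all(gaps > 0))              # disjoint, non-touching
  }
})

test_that("net intersection length equals the per-base oracle", {
  reg <- intervals("chr1", 100, 200)
  expect_equal(net_intersection_length(reg, intervals("chr1", 150, 250)), 50)
  expect_equal(net_intersection_length(reg, intervals("chr1", c(90, 180), c(120, 300))), 40)
  expect_equal(net_intersection_length(reg, intervals("chr1", c(100, 150), c(160, 200))), 100)
  expect_equal(net_intersection_length(reg, intervals("chr2", 0, 1000)), 0)

  set.seed(202)
  for (i in 1:300) {
    region <- random_interval_set(1)
    peaks <- random_interval_set(sample(0:10, 1))
    got <- net_intersection_length(region, peaks)
    expect_identical(got, as.numeric(oracle_net_intersection(region, peaks, 600)))
    expect_true(got >= 0 && got <= region$end - region$start)
  }
})

test_that("genome tiling covers every base exactly once", {
  t1 <- tile_genome(c(chr1 = 250), 100)
  expect_equal(t1$start, c(0, 100, 200))
  expect_equal(t1$end, c(100, 200, 250))
  expect_equal(tile_genome(c(chr1 = 100), 100)$end, 100)
  expect_error(tile_genome(c(chr1 = 0), 100), "positive")
  expect_error(tile_genome(c(chr1 = 100), 0), "width")

  sizes <- c(chrA = 1234, chrB = 999, chrC = 100)
  tiles <- tile_genome(sizes, 97)
  expect_equal(sum(tiles$end - tiles$start), sum(sizes))
  for (ch in names(sizes)) {
    tt <- tiles[tiles$chrom == ch, ]
    expect_equal(tt$start[-1], tt$end[-nrow(tt)])  # contiguous, non-overlapping
    expect_equal(max(tt$end), unname(sizes[ch]))
  }
})

test_that("jaccard index matches the per-base oracle and is symmetric", {
  a <- intervals("chr1", 0, 100)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, intervals("chr1", 200, 300)), 0)
  expect_equal(interval_jaccard(a, intervals("chr1", 50, 150)), 1 / 3)
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  expect_equal(interval_jaccard(empty, empty), 0)

  set.seed(303)
  for (i in 1:100) {
    A <- random_interval_set(sample(1:8, 1))
    B <- random_interval_set(sample(1:8, 1))
    j <- interval_jaccard(A, B)
    expect_equal(j, oracle_jaccard(A, B, 600))
    expect_equal(j, interval_jaccard(B, A))
  }
})

test_that("distance to interval is 0 inside, gap outside, Inf across chromosomes", {
  reg <- intervals("chr1", 100, 200)
  expect_equal(distance_to_interval(150, reg), 0)
  expect_equal(distance_to_interval(50, reg), 50)
  expect_equal(distance_to_interval(1500000, intervals("chr1", 2000000, 2010000)), 500000)
  expect_equal(distance_to_interval(150, reg, pos_chrom = "chr2"), Inf)
  # boundary semantics of the half-open interval
  expect_equal(distance_to_interval(c(99, 100, 199, 200), reg), c(1, 0, 0, 1))
})

test_that("projection overlap statistics match binomial arithmetic", {
  # 10 query midpoints, 3 inside a reference covering 10% of a 1 kb genome
  q <- intervals("chr1", c(10, 50, 90, 210, 310, 410, 510, 610, 710, 810),
                 c(20, 60, 100, 220, 320, 420, 520, 620, 720, 820))
  ref <- intervals("chr1", 0, 100)
  st <- projection_overlap_stats(q, ref, c(chr1 = 1000))
  expect_equal(st$observed, 3L)
  expect_equal(st$expected, 1)
  expect_equal(st$ratio, 3)
  expect_equal(st$p_value, sum(dbinom(3:10, 10, 0.1)), tolerance = 1e-12)

  # reference = whole genome
  st2 <- projection_overlap_stats(q, intervals("chr1", 0, 1000), c(chr1 = 1000))
  expect_equal(st2$ratio, 1)
  expect_equal(st2$p_value, 1)

  # empty query reported as missing ratio
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  st3 <- projection_overlap_stats(empty, ref, c(chr1 = 1000))
  expect_identical(st3$observed, 0L)
  expect_true(is.na(st3$ratio))
})

test_that("uniformly placed query midpoints give ratio near 1", {
  set.seed(404)
  genome <- c(chr1 = 1e6)
  ref <- intervals("chr1", seq(0, 9e5, by = 1e5), seq(0, 9e5, by = 1e5) + 3e4)
  pos <- sample.int(1e6 - 10, 3000) - 1
  q <- tibble::tibble(chrom = "chr1", start = pos, end = pos + 10)
  st <- projection_overlap_stats(q, ref, genome)
  expect_equal(st$ratio, 1, tolerance = 0.1)
})
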