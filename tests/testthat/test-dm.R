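make_status <- function(rows, samples) {
  m <- tibble::tibble(region_id = sprintf("t%d", seq_len(nrow(rows))),
                      chrom = "chr1", start = (seq_len(nrow(rows)) - 1) * 100,
                      end = seq_len(nrow(rows)) * 100, kind = "tile")
  dplyr::bind_cols(m, rows)
}

sheet44 <- tibble::tibble(sample_id = c(paste0("c", 1:4), paste0("n", 1:4)),
                          group = rep(c("case", "control"), each = 4),
                          peaks_path = NA_character_)

test_that("tile scan applies Fisher per tile and skips uninformative margins", {
  rows <- tibble::as_tibble(setNames(as.data.frame(rbind(
    c(1, 1, 1, 1, 0, 0, 0, 0),   # fully separated
    c(1, 1, 1, 1, 1, 1, 1, 1),   # all methylated -> skipped
    c(0, 0, 0, 0, 0, 0, 0, 0),   # none methylated -> skipped
    c(1, 0, 1, 0, 0, 1, 0, 1))), sheet44$sample_id))
  st <- make_status(rows, sheet44)
  dm <- suppressMessages(scan_tiles(st, sheet44))
  expect_equal(nrow(dm), 2)
  expect_equal(attr(dm, "n_skipped"), 2L)
  expect_equal(dm$p_value[dm$region_id == "t1"], 2 / 70, tolerance = 1e-10)
  expect_equal(dm$p_value[dm$region_id == "t4"], 1)

  bad <- dplyr::mutate(st, c1 = 2)
  expect_error(suppressMessages(scan_tiles(bad, sheet44)), "binary")
  expect_error(suppressMessages(scan_tiles(st, dplyr::slice(sheet44, 1:4))),
               "control")
})

test_that("tile scan flags almost nothing on a null cohort", {
  set.seed(31)
  n_tiles <- 400
  rows <- tibble::as_tibble(setNames(as.data.frame(
    matrix(rbinom(n_tiles * 8, 1, 0.4), n_tiles, 8)), sheet44$sample_id))
  dm <- suppressMessages(scan_tiles(make_status(rows, sheet44), sheet44))
  expect_lt(sum(dm$direction != "none") / nrow(dm), 0.01)
})

test_that("per-SE Wilcoxon test recovers the worked example and classifies direction", {
  sheet33 <- tibble::tibble(sample_id = c("c1", "c2", "c3", "n1", "n2", "n3"),
                            group = rep(c("case", "control"), each = 3),
                            peaks_path = NA_character_)
  meth <- tibble::tibble(region_id = c("SE1", "SE2"), chrom = "chr1",
                         start = c(0, 1000), end = c(500, 1500), kind = "se",
                         c1 = c(500, 5), c2 = c(600, 5), c3 = c(700, 5),
                         n1 = c(0, 5), n2 = c(10, 5), n3 = c(20, 5))
  dm <- suppressMessages(se_differential(meth, sheet33))
  expect_equal(dm$p_value[1], 0.1)
  expect_equal(dm$q_value[1], 0.2)    # BH over 2 tests
  expect_equal(dm$mean_case[1] > dm$mean_control[1], TRUE)
  # SE2 is constant everywhere: degenerate
  expect_equal(dm$p_value[2], 1)
  expect_equal(dm$direction[2], "none")

  # rank tests are invariant to scaling a single SE's row
  meth2 <- meth
  meth2[1, sheet33$sample_id] <- meth[1, sheet33$sample_id] * 7
  dm2 <- suppressMessages(se_differential(meth2, sheet33))
  expect_equal(dm2$p_value, dm$p_value)

  expect_error(suppressMessages(
    se_differential(meth, dplyr::slice(sheet33, c(1, 2, 3, 4)))), "two samples")
})

test_that("direction goes hyper/hypo only for significant regions", {
  run <- shared_small_run()
  dm <- run$res$dm
  sig <- dm$q_value < attr(dm, "alpha")
  expect_true(all(dm$direction[!sig] == "none"))
  expect_true(all(dm$direction[sig & dm$mean_case > dm$mean_control] == "hyper"))
  expect_true(all(dm$direction[sig & dm$mean_case < dm$mean_control] == "hypo"))
  expect_setequal(unique(dm$direction), c("hyper", "hypo", "none"))
})

test_that("DM tiles vs SE catalog overlap delegates to projection statistics", {
  # DM tiles all inside SEs covering 10% of the genome -> ratio 10
  sizes <- c(chr1 = 10000)
  ses <- intervals("chr1", 0, 1000)
  tiles <- intervals("chr1", c(0, 100, 200), c(100, 200, 300))
  st <- dm_tiles_vs_se_overlap(tiles, ses, sizes)
  expect_equal(st$ratio, 10)
  st0 <- dm_tiles_vs_se_overlap(tiles[0, ], ses, sizes)
  expect_true(is.na(st0$ratio))
})
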