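dm_fixture <- tibble::tibble(
  region_id = c("SE1", "SE2"), chrom = c("chr1", "chr1"),
  start = c(2000000, 9000000), end = c(2010000, 9005000),
  direction = c("hyper", "hypo"))

genes_fixture <- tibble::tibble(
  gene_id = c("gNear", "gFar", "gInside", "gOther", "gChr2"),
  chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
  strand = "+",
  tss = c(1500000, 3500000, 2000005, 9100000, 2000005))

test_that("target assignment respects the 1 Mbp TSS window on the same chromosome", {
  pairs <- find_targets(dm_fixture, genes_fixture)
  p1 <- pairs[pairs$se_id == "SE1", ]
  expect_setequal(p1$gene_id, c("gNear", "gInside"))
  expect_equal(p1$tss_distance_bp[p1$gene_id == "gNear"], 500000)
  expect_equal(p1$tss_distance_bp[p1$gene_id == "gInside"], 0)
  expect_false("gFar" %in% pairs$gene_id)    # 1,490,001 bp away
  expect_false("gChr2" %in% pairs$gene_id)   # other chromosome
  expect_true(all(pairs$tss_distance_bp <= 1e6))
  # descriptive midpoint distance is reported alongside the edge distance
  expect_equal(pairs$midpoint_distance_bp[p1$gene_id == "gNear"], 505000)
  expect_error(find_targets(dm_fixture, genes_fixture, window = 0), "window")
})

test_that("duplicated SE catalog rows pair independently", {
  dup <- dplyr::bind_rows(dm_fixture[1, ],
                          dplyr::mutate(dm_fixture[1, ], region_id = "SE1b"))
  pairs <- find_targets(dup, genes_fixture)
  expect_equal(sum(pairs$gene_id == "gNear"), 2)
})

make_pair_data <- function(n = 12, seed = 5) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n))
  meth <- tibble::tibble(region_id = c("SE1", "SE2"), chrom = "chr1",
                         start = c(2000000, 9000000), end = c(2010000, 9005000),
                         kind = "se")
  m1 <- seq(0, 1100, by = 100)[seq_len(n)]
  meth[, samples] <- as.data.frame(rbind(m1, rep(500, n)))
  expr <- tibble::tibble(gene_id = c("gNeg", "gPos", "gNoise"))
  expr[, samples] <- as.data.frame(rbind(100 - 0.08 * m1 + rnorm(n, 0, 1),
                                         10 + 0.08 * m1 + rnorm(n, 0, 1),
                                         rnorm(n, 50, 5)))
  list(meth = meth, expr = expr, samples = samples)
}

test_that("pair screen passes only FDR-significant negative correlations", {
  d <- make_pair_data()
  pairs <- tibble::tibble(se_id = "SE1", chrom = "chr1", se_start = 2000000,
                          se_end = 2010000, se_direction = "hyper",
                          gene_id = c("gNeg", "gPos", "gNoise"),
                          tss = 1500000, tss_distance_bp = 500000,
                          midpoint_distance_bp = 505000)
  res <- suppressMessages(correlate_pairs(pairs, d$meth, d$expr))
  expect_equal(res$tau_se[res$gene_id == "gNeg"] < -0.8, TRUE)
  expect_true(res$passed[res$gene_id == "gNeg"])
  expect_false(res$passed[res$gene_id == "gPos"])   # sign filter
  expect_false(res$passed[res$gene_id == "gNoise"])
  expect_equal(res$expression_direction[res$gene_id == "gNeg"], "down")

  # constant methylation: degenerate, never passes
  pairs2 <- dplyr::mutate(pairs[1, ], se_id = "SE2")
  res2 <- suppressMessages(correlate_pairs(pairs2, d$meth, d$expr))
  expect_true(is.na(res2$tau_se))
  expect_equal(res2$p_se, 1)
  expect_false(res2$passed)
})

test_that("genes absent from the expression matrix are dropped with a warning", {
  d <- make_pair_data()
  pairs <- tibble::tibble(se_id = "SE1", chrom = "chr1", se_start = 2000000,
                          se_end = 2010000, se_direction = "hyper",
                          gene_id = c("gNeg", "gMissing"),
                          tss = 1500000, tss_distance_bp = 500000,
                          midpoint_distance_bp = 505000)
  expect_warning(res <- suppressMessages(correlate_pairs(pairs, d$meth, d$expr)),
                 "absent")
  expect_equal(nrow(res), 1)
})

test_that("FDR scope covers all candidate pairs jointly by default, per SE on request", {
  run <- shared_small_run()
  pairs <- run$res$pairs
  # joint: BH recomputed over every tested pair reproduces q_se
  expect_equal(pairs$q_se, bh_fdr(pairs$p_se))
  per_se <- suppressMessages(correlate_pairs(
    find_targets(dm_regions(run$res$dm),
                 read_gene_annotation(run$sim$files$genes)),
    run$res$se_meth, read_matrix_tsv(run$sim$files$expression, "expression"),
    fdr_scope = "per_se"))
  for (sid in unique(per_se$se_id)) {
    i <- per_se$se_id == sid
    expect_equal(per_se$q_se[i], bh_fdr(per_se$p_se[i]))
  }
})

test_that("promoter correlations are reported side by side without affecting pass/fail", {
  run <- shared_small_run()
  pairs <- run$res$pairs
  expect_true(all(c("tau_promoter", "p_promoter", "q_promoter") %in% names(pairs)))
  # unmethylated promoters yield degenerate correlations: p = 1, tau missing
  deg <- is.na(pairs$tau_promoter)
  expect_true(all(pairs$p_promoter[deg] == 1 | is.na(pairs$p_promoter[deg])))
  # passing is decided by the SE correlation alone
  expect_equal(pairs$passed,
               !is.na(pairs$tau_se) & pairs$q_se < 0.05 & pairs$tau_se < 0)
})

test_that("every emitted pair respects the eligibility window", {
  run <- shared_small_run()
  expect_true(all(run$res$pairs$tss_distance_bp <= 1e6))
})
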