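test_that("Fisher two-sided p matches enumeration oracle", {
  expect_equal(fisher_exact_2x2(3, 0, 0, 3)$p_value, 0.1)
  expect_equal(fisher_exact_2x2(4, 0, 0, 4)$p_value, 2 / 70)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_2x2(0, 0, 5, 5)$p_value, 1)  # zero margin
  expect_error(fisher_exact_2x2(-1, 0, 1, 1), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")

  set.seed(21)
  for (i in 1:200) {
    cell <- sample(0:7, 4, replace = TRUE)
    if (sum(cell) == 0) next
    m <- matrix(cell, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(cell[1], cell[2], cell[3], cell[4])$p_value,
                 oracle_fisher(cell[1], cell[2], cell[3], cell[4]),
                 tolerance = 1e-10)
  }
})

test_that("Wilcoxon exact branch matches labeling enumeration; approx matches permutation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(7, 7, 7), c(7, 7, 7))$p_value, 1)

  set.seed(22)
  for (i in 1:30) {
    nx <- sample(2:6, 1)
    ny <- sample(2:(12 - nx), 1)
    v <- sample(1000, nx + ny)  # no ties
    x <- v[seq_len(nx)]
    y <- v[-seq_len(nx)]
    r <- wilcoxon_rank_sum(x, y)
    expect_equal(r$method, "wilcoxon_exact")
    expect_equal(r$p_value, oracle_wilcox_exact(x, y), tolerance = 1e-10)
  }

  # ties-heavy fixture from the intersection-length world (many zeros):
  # the tie/continuity-corrected normal approximation tracks the exactly
  # enumerated permutation null to within its own approximation error at
  # this size (~0.02 at n = 14)
  x <- c(0, 0, 10, 20, 500, 600, 700)
  y <- c(0, 0, 0, 0, 10, 20, 20)
  r <- wilcoxon_rank_sum(x, y)
  expect_equal(r$method, "wilcoxon_normal")
  expect_lt(abs(r$p_value - oracle_wilcox_perm_exact(x, y)), 0.02)

  # on larger ties-heavy fixtures the approximation stays within 0.04 of a
  # Monte-Carlo permutation oracle
  set.seed(23)
  for (i in 1:5) {
    n1 <- sample(14:20, 1)
    n2 <- sample(14:20, 1)
    xx <- sample(0:5, n1, replace = TRUE)
    yy <- sample(0:5, n2, replace = TRUE)
    if (length(unique(c(xx, yy))) == 1) next
    expect_lt(abs(wilcoxon_rank_sum(xx, yy)$p_value -
                    oracle_wilcox_perm(xx, yy, 2e4)), 0.04)
  }
})

test_that("Kendall tau-b equals the pairwise-counting oracle", {
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic, 1 / 3)
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 3))$statistic,
               oracle_kendall_tau_b(c(1, 1, 2), c(1, 2, 3)))

  set.seed(24)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    x <- sample(0:6, n, replace = TRUE)     # heavy ties
    y <- sample(0:6, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    r <- kendall_tau(x, y)
    expect_equal(r$statistic, oracle_kendall_tau_b(x, y), tolerance = 1e-12)
    expect_true(r$statistic >= -1 && r$statistic <= 1)
    # antisymmetry under reversing the order relation of y
    expect_equal(kendall_tau(x, -y)$statistic, -r$statistic, tolerance = 1e-12)
  }
})

test_that("Kendall handles missing pairs and degenerate input", {
  r <- kendall_tau(c(1, 2, 3, 4, NA), c(4, 3, 2, NA, 1))
  expect_equal(r$n_effective, 3L)
  expect_equal(r$statistic, -1)
  r <- kendall_tau(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r$statistic))
  expect_equal(r$p_value, 1)
  r <- kendall_tau(c(1, 2), c(2, 1))
  expect_equal(r$p_value, 1)  # < 3 complete pairs
})

test_that("BH q-values equal the step-up definition", {
  expect_equal(bh_fdr(c(0.005, 0.03, 0.04, 0.8)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  q <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.04))  # m counts only observed p

  set.seed(25)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("null simulations keep type-I error near nominal", {
  set.seed(26)
  n_sim <- 400
  alpha <- 0.05
  rej_w <- mean(replicate(n_sim, {
    wilcoxon_rank_sum(sample(0:5, 15, TRUE), sample(0:5, 12, TRUE))$p_value
  }) < alpha)
  rej_k <- mean(replicate(n_sim, {
    kendall_tau(rnorm(30), rnorm(30))$p_value
  }) < alpha)
  expect_gt(rej_w, 0.02)
  expect_lt(rej_w, 0.09)
  expect_gt(rej_k, 0.02)
  expect_lt(rej_k, 0.09)
})
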