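# Brute-force oracles, independent of the implementation paths they check.

# per-base coverage of [0, limit) by an interval tibble
oracle_coverage <- function(x, limit) {
  cov <- logical(limit)
  for (i in seq_len(nrow(x))) {
    if (x$start[i] < limit) {
      cov[(x$start[i] + 1):min(x$end[i], limit)] <- TRUE
    }
  }
  cov
}

oracle_net_intersection <- function(region, peaks, limit = 10000) {
  peaks <- peaks[peaks$chrom == region$chrom, , drop = FALSE]
  cov <- oracle_coverage(peaks, limit)
  sum(cov[(region$start + 1):region$end])
}

# runs of covered bases -> normalized interval tibble (single chromosome)
oracle_normalize_one <- function(x, limit = 10000) {
  cov <- oracle_coverage(x, limit)
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = x$chrom[1], start = starts[r$values],
                 end = ends[r$values])
}

oracle_jaccard <- function(a, b, limit = 10000) {
  stopifnot(length(unique(c(a$chrom, b$chrom))) == 1)
  ca <- oracle_coverage(a, limit)
  cb <- oracle_coverage(b, limit)
  u <- sum(ca | cb)
  if (u == 0) 0 else sum(ca & cb) / u
}

# two-sided Fisher by full enumeration of tables with the observed margins,
# using the "probability at most observed" rule (with the same relative
# tolerance fisher.test applies when comparing table probabilities)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all group labelings
# (wilcox.test's doubling convention)
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  n <- length(all_v)
  W_of <- function(idx) sum(rank(all_v)[idx]) - nx * (nx + 1) / 2
  w_obs <- W_of(seq_len(nx))
  labelings <- utils::combn(n, nx)
  ws <- apply(labelings, 2, W_of)
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Monte-Carlo permutation tail for the rank-sum statistic
oracle_wilcox_perm <- function(x, y, B = 1e5) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- replicate(B, {
    idx <- sample(length(all_v), nx)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# exact permutation p (full labeling enumeration, ties allowed) — the
# reference the normal approximation is approximating
oracle_wilcox_perm_exact <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(utils::combn(length(all_v), nx), 2,
              function(i) sum(r[i]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# tau-b by pairwise counting with tie terms
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# BH step-up by definition: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

random_interval_set <- function(n, limit = 500, chrom = "chr1") {
  s <- sample.int(limit - 1, n, replace = TRUE) - 1
  len <- sample.int(60, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = s, end = pmin(s + len, limit))
}
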