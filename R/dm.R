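# Differential methylation calling.
#
# Tiles: per-tile 2x2 table (methylated/unmethylated x case/control), exact
# Fisher test, BH across tested tiles. Tiles with an uninformative margin
# (methylated in no sample or in every sample) are excluded before FDR so
# they do not dilute the correction; the exclusion count is reported.
#
# SEs: per-region Wilcoxon rank-sum on net intersection bp, BH across all
# regions (each scan corrected separately), significant regions classified
# hyper/hypo by group means (median breaks a mean tie; if both tie the
# direction stays "none").

split_groups <- function(mat, samples) {
  validate_sample_sheet(samples)
  missing <- setdiff(samples$sample_id, names(mat))
  if (length(missing) > 0) {
    abort(paste0("samples absent from matrix: ", paste(missing, collapse = ", ")))
  }
  list(case = samples$sample_id[samples$group == "case"],
       control = samples$sample_id[samples$group == "control"])
}

new_se_dm <- function(x, alpha, test, n_case, n_control, n_skipped = 0L) {
  structure(x,
            class = c("se_dm", class(tibble())),
            alpha = alpha, test = test,
            n_case = n_case, n_control = n_control, n_skipped = n_skipped)
}

classify_direction <- function(significant, mean_case, mean_control,
                               median_case, median_control) {
  dir <- rep("none", length(significant))
  diff <- mean_case - mean_control
  tie <- diff == 0
  diff[tie] <- (median_case - median_control)[tie]
  dir[significant & diff > 0] <- "hyper"
  dir[significant & diff < 0] <- "hypo"
  dir
}

#' Genome-tile differential methylation scan
#'
#' Exact Fisher test of methylation status against sample status per tile,
#' BH FDR across all informative tiles.
#'
#' @param status Binary status matrix from [tile_status_matrix()].
#' @param samples Sample sheet (>= 1 sample per group).
#' @param alpha FDR threshold for flagging (default 0.05).
#' @return An `se_dm` tibble: region_id, chrom, start, end, mean_case,
#'   mean_control (methylated fractions), p_value, q_value, direction.
#'   Uninformative tiles are dropped; their count is in `attr(, "n_skipped")`.
#' @export
scan_tiles <- function(status, samples, alpha = 0.05) {
  g <- split_groups(status, samples)
  if (length(g$case) < 1 || length(g$control) < 1) {
    abort("scan_tiles: need at least one case and one control sample")
  }
  ca <- as.matrix(status[, g$case, drop = FALSE])
  co <- as.matrix(status[, g$control, drop = FALSE])
  if (!all(ca %in% c(0, 1)) || !all(co %in% c(0, 1))) {
    abort("scan_tiles: status matrix must be binary")
  }
  a <- rowSums(ca)                      # cases methylated
  c_ <- rowSums(co)                     # controls methylated
  b <- length(g$case) - a
  d <- length(g$control) - c_
  informative <- (a + c_) > 0 & (b + d) > 0
  n_skipped <- sum(!informative)
  out <- tibble(region_id = status$region_id, chrom = status$chrom,
                start = status$start, end = status$end,
                mean_case = a / length(g$case),
                mean_control = c_ / length(g$control))[informative, ]
  ai <- a[informative]; bi <- b[informative]
  ci <- c_[informative]; di <- d[informative]
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    fisher_exact_2x2(ai[i], bi[i], ci[i], di[i])$p_value
  }, numeric(1))
  out$q_value <- bh_fdr(out$p_value)
  sig <- out$q_value < alpha
  out$direction <- classify_direction(sig, out$mean_case, out$mean_control,
                                      out$mean_case, out$mean_control)
  inform(sprintf(
    "scan_tiles: %d tiles tested, %d uninformative tiles skipped, %d flagged at q < %g (%d hyper, %d hypo)",
    nrow(out), n_skipped, sum(sig), alpha,
    sum(out$direction == "hyper"), sum(out$direction == "hypo")))
  new_se_dm(out, alpha = alpha, test = "fisher_exact",
            n_case = length(g$case), n_control = length(g$control),
            n_skipped = n_skipped)
}

#' Per-SE differential methylation test
#'
#' Wilcoxon rank-sum test of case versus control net methylation bp per SE,
#' BH FDR across all SEs, hyper/hypo classification by group means.
#'
#' @param meth bp matrix from [region_methylation_matrix()].
#' @param samples Sample sheet (>= 2 samples per group).
#' @param alpha FDR threshold (default 0.05).
#' @return An `se_dm` tibble: region_id, chrom, start, end, mean_case,
#'   mean_control, statistic, p_value, q_value, direction.
#' @export
se_differential <- function(meth, samples, alpha = 0.05) {
  g <- split_groups(meth, samples)
  if (length(g$case) < 2 || length(g$control) < 2) {
    abort("se_differential: need at least two samples per group")
  }
  ca <- as.matrix(meth[, g$case, drop = FALSE])
  co <- as.matrix(meth[, g$control, drop = FALSE])
  res <- vapply(seq_len(nrow(meth)), function(i) {
    r <- wilcoxon_rank_sum(ca[i, ], co[i, ])
    c(r$statistic, r$p_value)
  }, numeric(2))
  out <- tibble(region_id = meth$region_id, chrom = meth$chrom,
                start = meth$start, end = meth$end,
                mean_case = rowMeans(ca), mean_control = rowMeans(co),
                statistic = res[1, ], p_value = res[2, ])
  out$q_value <- bh_fdr(out$p_value)
  sig <- out$q_value < alpha
  out$direction <- classify_direction(
    sig, out$mean_case, out$mean_control,
    apply(ca, 1, median), apply(co, 1, median))
  ambiguous <- sum(sig & out$direction == "none")
  if (ambiguous > 0) {
    warn(sprintf("se_differential: %d significant region(s) with tied means and medians left direction = none",
                 ambiguous))
  }
  inform(sprintf(
    "se_differential: %d SEs tested, %d differentially methylated at q < %g (%d hyper, %d hypo)",
    nrow(out), sum(sig), alpha,
    sum(out$direction == "hyper"), sum(out$direction == "hypo")))
  new_se_dm(out, alpha = alpha, test = "wilcoxon_rank_sum",
            n_case = length(g$case), n_control = length(g$control))
}

#' Differentially methylated regions of an `se_dm` result
#'
#' @param x An `se_dm` tibble.
#' @return The rows with direction `hyper` or `hypo`.
#' @export
dm_regions <- function(x) {
  filter(as_tibble(x), .data$direction != "none")
}

#' Overlap of DM tiles with an SE catalog
#'
#' Midpoint-projection overlap statistics of differentially methylated tiles
#' (query) against the SE catalog (reference): are DM regions
#' overrepresented inside SEs relative to uniform placement?
#'
#' @param dm_tiles `se_dm` result from [scan_tiles()] (or any interval
#'   tibble of DM regions).
#' @param se_catalog Interval tibble of SEs.
#' @param sizes Chromosome sizes.
#' @return One-row tibble from [projection_overlap_stats()].
#' @export
dm_tiles_vs_se_overlap <- function(dm_tiles, se_catalog, sizes) {
  query <- if (inherits(dm_tiles, "se_dm")) dm_regions(dm_tiles) else dm_tiles
  projection_overlap_stats(query, se_catalog, sizes)
}
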