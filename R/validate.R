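# Array-based validation of SE-gene pairs in an independent cohort: probe
# beta values inside the SE stand in for region methylation. For each pair,
# the probe with the most negative Kendall tau against the gene's expression
# is selected; the pair validates when that probe's unadjusted p-value is
# below the cutoff (and, by default, its tau is negative, matching the
# repression model). Validation only annotates pairs; discovery pass/fail
# flags are never changed.

#' Beta value from methylated/unmethylated intensities
#'
#' `beta = M / (M + U)`; missing when `M + U = 0`.
#'
#' @param M,U Non-negative intensity vectors.
#' @return Numeric vector of beta values in `[0, 1]` (NA where M + U = 0).
#' @examples
#' compute_beta(75, 25)
#' @export
compute_beta <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    abort("compute_beta: intensities must be non-negative")
  }
  tot <- M + U
  ifelse(tot > 0, M / tot, NA_real_)
}

#' Validate SE-gene pairs in an array cohort
#'
#' @param pairs `se_pairs` tibble (typically the passed subset).
#' @param probes Probe map tibble: probe_id, chrom, pos (0-based bp).
#' @param betas Probe beta matrix (probe_id + sample columns).
#' @param expr Expression matrix for the validation cohort.
#' @param p_cut Unadjusted p-value cutoff (default 0.05; no FDR at this
#'   stage).
#' @param require_negative Also require the selected probe's tau < 0
#'   (default TRUE).
#' @return `pairs` with columns probe_id, tau_probe, p_probe, n_probes and
#'   `validated` (TRUE/FALSE, or NA when the SE contains no probe or the
#'   gene is absent from the validation expression matrix).
#' @export
validate_pairs <- function(pairs, probes, betas, expr, p_cut = 0.05,
                           require_negative = TRUE) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(probes))) {
    abort("validate_pairs: probes need columns probe_id, chrom, pos")
  }
  shared <- intersect(matrix_samples(betas), matrix_samples(expr))
  if (length(shared) < 3) {
    abort("validate_pairs: need at least 3 shared validation samples")
  }
  beta_m <- row_lookup(betas, "probe_id")[, shared, drop = FALSE]
  expr_m <- row_lookup(expr, "gene_id")[, shared, drop = FALSE]
  out <- pairs
  out$probe_id <- NA_character_
  out$tau_probe <- NA_real_
  out$p_probe <- NA_real_
  out$n_probes <- 0L
  out$validated <- NA
  for (i in seq_len(nrow(out))) {
    # half-open containment of the probe position in the SE interval
    in_se <- probes$chrom == out$chrom[i] &
      probes$pos >= out$se_start[i] & probes$pos < out$se_end[i]
    pids <- intersect(probes$probe_id[in_se], rownames(beta_m))
    out$n_probes[i] <- length(pids)
    gid <- out$gene_id[i]
    if (length(pids) == 0 || !gid %in% rownames(expr_m)) next
    stats <- vapply(pids, function(p) {
      kendall_tau_fast(beta_m[p, ], expr_m[gid, ])
    }, numeric(2))
    taus <- stats[1, ]
    if (all(is.na(taus))) next
    best <- which.min(taus)      # most negative correlation coefficient
    out$probe_id[i] <- pids[best]
    out$tau_probe[i] <- taus[best]
    out$p_probe[i] <- stats[2, best]
    out$validated[i] <- out$p_probe[i] < p_cut &&
      (!require_negative || out$tau_probe[i] < 0)
  }
  inform(sprintf(
    "validate_pairs: %d of %d pairs validated at p < %g (%d not assessable)",
    sum(out$validated, na.rm = TRUE), nrow(out), p_cut, sum(is.na(out$validated))))
  out
}
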