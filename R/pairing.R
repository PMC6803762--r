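# SE-to-gene assignment and methylation-expression correlation.
#
# Eligibility: a gene is a candidate target of a DM-SE when its TSS lies
# within 1 Mbp of the SE region, distance measured TSS-to-nearest-SE-edge
# (0 inside the SE). The TSS-to-SE-midpoint distance is reported alongside
# as a descriptive column. Pairs are screened by Kendall tau-b between SE
# methylation and expression: BH FDR across all candidate pairs (jointly by
# default, per SE behind `fdr_scope`), and positively correlated pairs are
# filtered out as artifacts regardless of significance.

new_se_pairs <- function(x, alpha, fdr_scope, n_samples) {
  structure(x, class = c("se_pairs", class(tibble())),
            alpha = alpha, fdr_scope = fdr_scope, n_samples = n_samples)
}

#' Candidate in-cis target genes of DM-SEs
#'
#' Emits one row per (SE, gene) combination on the same chromosome with
#' TSS-to-SE-edge distance at most `window`. Duplicated SE catalog rows pair
#' independently.
#'
#' @param dm_ses `se_dm` result (or interval tibble with `region_id` and
#'   optionally `direction`); typically the DM subset, see [dm_regions()].
#' @param genes Gene annotation tibble.
#' @param window Maximum TSS distance in bp (default 1 Mbp).
#' @return Tibble: se_id, chrom, se_start, se_end, se_direction, gene_id,
#'   tss, tss_distance_bp, midpoint_distance_bp.
#' @export
find_targets <- function(dm_ses, genes, window = 1e6) {
  if (!is.numeric(window) || window <= 0) abort("find_targets: window must be > 0")
  ses <- as_tibble(dm_ses)
  validate_intervals(ses, "dm_ses")
  if (!"region_id" %in% names(ses)) ses$region_id <- region_ids(ses)
  if (!"direction" %in% names(ses)) ses$direction <- NA_character_
  ses <- select(ses, se_id = "region_id", "chrom", se_start = "start",
                se_end = "end", se_direction = "direction")
  g <- select(genes, "gene_id", "chrom", "tss")
  pairs <- inner_join(ses, g, by = "chrom", relationship = "many-to-many")
  if (nrow(pairs) == 0) return(mutate(pairs, tss_distance_bp = numeric(0),
                                      midpoint_distance_bp = numeric(0)))
  inside <- pairs$tss >= pairs$se_start & pairs$tss < pairs$se_end
  pairs$tss_distance_bp <- ifelse(
    inside, 0,
    pmin(abs(pairs$tss - pairs$se_start), abs(pairs$tss - (pairs$se_end - 1))))
  pairs$midpoint_distance_bp <- abs(pairs$tss - floor((pairs$se_start + pairs$se_end) / 2))
  pairs <- filter(pairs, .data$tss_distance_bp <= window)
  arrange(pairs, .data$chrom, .data$se_start, .data$gene_id)
}

row_lookup <- function(mat, id_col) {
  samples <- matrix_samples(mat)
  m <- as.matrix(mat[, samples, drop = FALSE])
  rownames(m) <- mat[[id_col]]
  m
}

#' Correlate SE methylation with target gene expression
#'
#' Kendall tau-b per candidate pair between the SE's net methylation bp and
#' the gene's expression across shared samples; BH FDR across pairs;
#' `passed` = FDR-significant negative correlation. Positive correlations
#' are artifacts under the repression model and never pass.
#'
#' @param pairs Candidate pairs from [find_targets()].
#' @param se_meth SE methylation matrix ([region_methylation_matrix()]).
#' @param expr Expression matrix ([read_matrix_tsv()] style: gene_id +
#'   sample columns).
#' @param alpha FDR threshold (default 0.05).
#' @param fdr_scope `"joint"` (BH across all candidate pairs, default) or
#'   `"per_se"` (BH within each SE's pairs).
#' @return An `se_pairs` tibble: pair columns plus tau_se, p_se, q_se,
#'   expression_direction and passed. Genes absent from `expr` are dropped
#'   with a warning.
#' @export
correlate_pairs <- function(pairs, se_meth, expr, alpha = 0.05,
                            fdr_scope = c("joint", "per_se")) {
  fdr_scope <- match.arg(fdr_scope)
  shared <- intersect(matrix_samples(se_meth), matrix_samples(expr))
  if (length(shared) < 3) {
    abort("correlate_pairs: need at least 3 samples shared between matrices")
  }
  meth_m <- row_lookup(se_meth, "region_id")[, shared, drop = FALSE]
  expr_m <- row_lookup(expr, "gene_id")[, shared, drop = FALSE]
  missing <- setdiff(unique(pairs$gene_id), rownames(expr_m))
  if (length(missing) > 0) {
    warn(sprintf("correlate_pairs: dropping %d pair(s) for %d gene(s) absent from expression matrix",
                 sum(pairs$gene_id %in% missing), length(missing)))
    pairs <- filter(pairs, !.data$gene_id %in% missing)
  }
  bad_se <- setdiff(unique(pairs$se_id), rownames(meth_m))
  if (length(bad_se) > 0) {
    abort(paste0("correlate_pairs: SE ids absent from methylation matrix: ",
                 paste(head(bad_se, 3), collapse = ", ")))
  }
  out <- as_tibble(pairs)
  res <- vapply(seq_len(nrow(out)), function(i) {
    kendall_tau_fast(meth_m[out$se_id[i], ], expr_m[out$gene_id[i], ])
  }, numeric(2))
  out$tau_se <- res[1, ]
  out$p_se <- res[2, ]
  out$q_se <- if (fdr_scope == "joint") {
    bh_fdr(out$p_se)
  } else {
    stats::ave(out$p_se, out$se_id, FUN = bh_fdr)
  }
  inform(sprintf("correlate_pairs: %d candidate pairs entered %s FDR correction",
                 sum(!is.na(out$p_se)), fdr_scope))
  out$passed <- !is.na(out$tau_se) & out$q_se < alpha & out$tau_se < 0
  out$expression_direction <- dplyr::case_when(
    !out$passed ~ NA_character_,
    out$se_direction == "hyper" ~ "down",
    out$se_direction == "hypo" ~ "up",
    TRUE ~ NA_character_)
  inform(sprintf("correlate_pairs: %d of %d pairs passed (q < %g and tau < 0)",
                 sum(out$passed), nrow(out), alpha))
  new_se_pairs(out, alpha = alpha, fdr_scope = fdr_scope,
               n_samples = length(shared))
}

#' Correlate promoter methylation with target gene expression
#'
#' Same Kendall machinery applied to each pair's gene promoter methylation;
#' stored alongside the SE correlations (no role in pass/fail). FDR is
#' corrected across promoter tests separately.
#'
#' @param pairs An `se_pairs` (or candidate pair) tibble.
#' @param promoter_meth Promoter methylation matrix keyed by gene
#'   ([region_methylation_matrix()] over [promoter_intervals()], so
#'   region_id = gene_id).
#' @param expr Expression matrix.
#' @return `pairs` with tau_promoter, p_promoter, q_promoter columns added.
#' @export
correlate_promoters <- function(pairs, promoter_meth, expr) {
  shared <- intersect(matrix_samples(promoter_meth), matrix_samples(expr))
  if (length(shared) < 3) {
    abort("correlate_promoters: need at least 3 shared samples")
  }
  meth_m <- row_lookup(promoter_meth, "region_id")[, shared, drop = FALSE]
  expr_m <- row_lookup(expr, "gene_id")[, shared, drop = FALSE]
  out <- pairs
  res <- vapply(seq_len(nrow(out)), function(i) {
    gid <- out$gene_id[i]
    if (!gid %in% rownames(meth_m) || !gid %in% rownames(expr_m)) {
      return(c(NA_real_, NA_real_))
    }
    kendall_tau_fast(meth_m[gid, ], expr_m[gid, ])
  }, numeric(2))
  out$tau_promoter <- res[1, ]
  out$p_promoter <- res[2, ]
  out$q_promoter <- bh_fdr(out$p_promoter)
  out
}
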