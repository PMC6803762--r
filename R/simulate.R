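# Ground-truthed synthetic cohort generator.
#
# Emulates the statistical structure of the pipeline's inputs: a genome of a
# few long chromosomes carrying an SE catalog on a regular grid; per-sample
# MACS-style methylation peak BEDs in which each SE's covered fraction is
# drawn around its group mean (f0, or f0 +/- delta for planted hyper/hypo
# SEs) with Beta-distributed sample-to-sample jitter; background peaks
# outside SEs from a seeded point process; target gene expression negatively
# monotone in the SE's methylated fraction plus Gaussian noise, alongside
# positively-linked "artifact" genes and independent decoy genes; and an
# array-style validation cohort whose probe betas equal the per-sample SE
# fraction plus probe noise. Every output is reproducible from the seed.
#
# SEs sit on a regular grid (about one per 2.4 Mbp by default) and each SE's
# planted genes lie within +/-0.8 Mbp of their SE, so distinct SEs' 1 Mbp
# cis windows never overlap: the planted pair truth is identifiable, because
# a gene can only ever be a candidate target of the SE it was planted for.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions: a 47 case / 25 control
#' discovery cohort, 200 SEs of 5-20 kb (15% planted hypermethylated, 5%
#' hypomethylated, effect size `delta` = 0.3 on a baseline methylated
#' fraction `f0` = 0.3), 3 negatively-linked target genes, 1
#' positively-linked artifact gene and 2 independent decoy genes per SE, and
#' a 22 case / 6 control validation cohort with 4 probes per SE.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_case,n_control Discovery cohort sizes.
#' @param n_chrom,chrom_length Genome shape (identical chromosome lengths).
#' @param n_se Number of SEs in the catalog.
#' @param se_length_range Min/max SE length in bp.
#' @param frac_hyper,frac_hypo Fractions of SEs planted hyper-/hypomethylated
#'   (the rest are null).
#' @param f0 Baseline methylated fraction per SE per sample.
#' @param delta Group effect size: case mean fraction is `f0 + delta` for
#'   hyper SEs and `f0 - delta` for hypo SEs.
#' @param jitter_concentration Beta concentration of per-sample jitter around
#'   the group mean fraction (larger = tighter).
#' @param mean_peak_length Mean length of methylation peaks inside SEs (bp).
#' @param background_rate_per_mb Poisson rate of background peaks per Mbp
#'   outside SEs.
#' @param background_peak_length Typical background peak length (bp).
#' @param targets_per_se,artifacts_per_se,decoys_per_se Planted genes per SE.
#' @param expr_intercept,expr_slope,expr_sd Expression model: target
#'   expression = intercept - slope x fraction + N(0, sd), clipped at 0
#'   (artifacts use + slope).
#' @param promoter_hyper_frac Fraction of genes given a methylated promoter.
#' @param probes_per_se Array probes placed uniformly inside each SE.
#' @param probe_sd Gaussian noise sd added to probe betas.
#' @param n_case_val,n_control_val Validation cohort sizes.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_case = 47, n_control = 25,
                       n_chrom = 4, chrom_length = 120e6,
                       n_se = 200, se_length_range = c(5000, 20000),
                       frac_hyper = 0.15, frac_hypo = 0.05,
                       f0 = 0.3, delta = 0.3,
                       jitter_concentration = 30,
                       mean_peak_length = 1000,
                       background_rate_per_mb = 5,
                       background_peak_length = 500,
                       targets_per_se = 3, artifacts_per_se = 1, decoys_per_se = 2,
                       expr_intercept = 10, expr_slope = 8, expr_sd = 1.3,
                       promoter_hyper_frac = 0.1,
                       probes_per_se = 4, probe_sd = 0.05,
                       n_case_val = 22, n_control_val = 6) {
  cfg <- as.list(environment())
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("sim_config: a single integer seed is required")
  }
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_chrom, cfg$n_se,
              cfg$targets_per_se, cfg$artifacts_per_se, cfg$decoys_per_se,
              cfg$probes_per_se, cfg$n_case_val, cfg$n_control_val)
  if (any(counts < 0)) abort("sim_config: counts must be non-negative")
  if (cfg$frac_hyper < 0 || cfg$frac_hypo < 0 ||
      cfg$frac_hyper + cfg$frac_hypo > 1) {
    abort("sim_config: class fractions must be non-negative and sum to at most 1")
  }
  lo <- cfg$f0 - cfg$delta
  hi <- cfg$f0 + cfg$delta
  if (cfg$f0 < 0 || cfg$f0 > 1 || lo < 0 || hi > 1) {
    abort("sim_config: f0 and f0 +/- delta must lie in [0, 1]")
  }
  if (cfg$se_length_range[1] < 1000 || diff(cfg$se_length_range) < 0) {
    abort("sim_config: invalid SE length range")
  }
  structure(cfg, class = "sim_config")
}

# non-overlapping peaks inside [se_start, se_start + L) covering exactly
# `meth` bp, split into ~meth/mean_len pieces with random gaps
se_peaks_one <- function(se_start, L, meth, mean_len) {
  if (meth <= 0) return(NULL)
  k <- max(1L, min(as.integer(round(meth / mean_len)), as.integer(meth)))
  lens <- if (k == 1) meth else as.vector(rmultinom(1, meth, rep(1, k)))
  gaps <- as.vector(rmultinom(1, L - meth, rep(1, k + 1)))
  starts <- se_start + cumsum(gaps[seq_len(k)]) + c(0, cumsum(lens[seq_len(k - 1)]))
  keep <- lens > 0
  cbind(starts[keep], starts[keep] + lens[keep])
}

draw_fractions <- function(mean_mat, concentration) {
  m <- as.vector(mean_mat)
  f <- numeric(length(m))
  inner <- m > 0 & m < 1          # boundary means are degenerate: no jitter
  f[inner] <- rbeta(sum(inner), shape1 = m[inner] * concentration,
                    shape2 = (1 - m[inner]) * concentration)
  f[!inner] <- m[!inner]
  matrix(f, nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
}

group_mean_matrix <- function(class, sample_group, f0, delta) {
  eff <- ifelse(class == "hyper", delta, ifelse(class == "hypo", -delta, 0))
  m <- outer(eff, as.numeric(sample_group == "case")) + f0
  m
}

expression_matrix_for <- function(genes_truth, frac, cfg, sample_ids) {
  a <- cfg$expr_intercept
  b <- cfg$expr_slope
  n_s <- length(sample_ids)
  vals <- matrix(NA_real_, nrow(genes_truth), n_s)
  for (i in seq_len(nrow(genes_truth))) {
    role <- genes_truth$role[i]
    f <- frac[genes_truth$se_id[i], ]
    vals[i, ] <- switch(role,
      target = pmax(0, a - b * f + rnorm(n_s, 0, cfg$expr_sd)),
      artifact = pmax(0, (a - b) + b * f + rnorm(n_s, 0, cfg$expr_sd)),
      decoy = pmax(0, rnorm(n_s, a - b * cfg$f0, 1.5 * cfg$expr_sd)))
  }
  out <- as_tibble(as.data.frame(vals))
  names(out) <- sample_ids
  bind_cols(tibble(gene_id = genes_truth$gene_id), out)
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes every input the pipeline consumes (chromosome sizes, SE catalog
#' BED, per-sample peak BEDs plus sample sheet, gene annotation, expression
#' matrix, validation probe map / beta matrix / expression matrix, and the
#' ground truth tables) under `out_dir`, and returns the truth.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, a named list `files` of the written
#'   paths, and `truth` (list of tibbles `se` and `pairs`, plus the config).
#' @export
simulate_cohort <- function(config, out_dir) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  cfg <- config
  set.seed(as.integer(cfg$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "validation"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)

  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  sizes <- tibble(chrom = chroms, length = rep(cfg$chrom_length, cfg$n_chrom))

  ## --- SE catalog on a regular grid ------------------------------------
  per_chrom <- diff(round(seq(0, cfg$n_se, length.out = cfg$n_chrom + 1)))
  se <- bind_rows(lapply(seq_len(cfg$n_chrom), function(ci) {
    np <- per_chrom[ci]
    if (np == 0) return(NULL)
    slot <- cfg$chrom_length / np
    center <- (seq_len(np) - 0.5) * slot
    len <- round(runif(np, cfg$se_length_range[1], cfg$se_length_range[2]))
    # genes are planted within +/-span of the SE centre; capped at 45% of the
    # grid slot so neighbouring SEs' cis windows stay disjoint at full scale
    tibble(chrom = chroms[ci], start = round(center - len / 2),
           end = round(center - len / 2) + len, center = round(center),
           span = min(8e5, 0.45 * slot))
  }))
  se$se_id <- sprintf("SE%03d", seq_len(nrow(se)))
  n_hyper <- round(cfg$n_se * cfg$frac_hyper)
  n_hypo <- round(cfg$n_se * cfg$frac_hypo)
  class <- sample(c(rep("hyper", n_hyper), rep("hypo", n_hypo),
                    rep("null", cfg$n_se - n_hyper - n_hypo)))
  se$class <- class

  ## --- samples and per-SE per-sample methylated fractions ---------------
  disc <- tibble(
    sample_id = c(sprintf("case%02d", seq_len(cfg$n_case)),
                  sprintf("ctrl%02d", seq_len(cfg$n_control))),
    group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control)))
  mean_disc <- group_mean_matrix(se$class, disc$group, cfg$f0, cfg$delta)
  dimnames(mean_disc) <- list(se$se_id, disc$sample_id)
  frac_disc <- draw_fractions(mean_disc, cfg$jitter_concentration)

  ## --- genes -------------------------------------------------------------
  roles <- c(rep("target", cfg$targets_per_se),
             rep("artifact", cfg$artifacts_per_se),
             rep("decoy", cfg$decoys_per_se))
  genes_truth <- bind_rows(lapply(seq_len(nrow(se)), function(j) {
    if (length(roles) == 0) return(NULL)
    tag <- c(target = "T", artifact = "A", decoy = "D")[roles]
    idx <- stats::ave(seq_along(roles), roles, FUN = seq_along)
    tibble(se_id = se$se_id[j],
           gene_id = sprintf("G_%s_%s%d", se$se_id[j], tag, idx),
           role = roles,
           chrom = se$chrom[j],
           tss = pmax(0, pmin(cfg$chrom_length - 1,
                              round(runif(length(roles), se$center[j] - se$span[j],
                                          se$center[j] + se$span[j])))),
           strand = sample(c("+", "-"), length(roles), replace = TRUE))
  }))
  genes <- select(genes_truth, "gene_id", "chrom", "strand", "tss")

  ## --- promoter-methylated subset (promoters clear of any SE) -----------
  prom <- promoter_intervals(genes, sizes)
  prom_clear <- net_intersection_length(prom, se) == 0
  eligible <- which(prom_clear)
  n_prom_hyper <- round(cfg$promoter_hyper_frac * nrow(genes))
  prom_hyper_idx <- sort(sample(eligible, min(n_prom_hyper, length(eligible))))

  ## --- background peak slots (shared across samples) ---------------------
  pad <- 1000
  se_padded <- mutate(se, start = pmax(0, .data$start - pad),
                      end = pmin(cfg$chrom_length, .data$end + pad))
  bg_gaps <- bind_rows(lapply(chroms, function(ch) {
    occ <- normalize_intervals(filter(se_padded, .data$chrom == ch))
    edges <- c(0, rbind(occ$start, occ$end), cfg$chrom_length)
    gs <- edges[seq(1, length(edges), 2)]
    ge <- edges[seq(2, length(edges), 2)]
    tibble(chrom = ch, start = gs, end = ge)[ge - gs > 3 * cfg$background_peak_length, ]
  }))
  gap_len <- bg_gaps$end - bg_gaps$start
  mb_free <- sum(gap_len) / 1e6

  write_peaks_for <- function(frac, sample_ids, dir) {
    paths <- character(length(sample_ids))
    for (s in seq_along(sample_ids)) {
      sid <- sample_ids[s]
      ## SE peaks with exact per-SE coverage
      mats <- lapply(seq_len(nrow(se)), function(j) {
        L <- se$end[j] - se$start[j]
        se_peaks_one(se$start[j], L, round(frac[j, s] * L), cfg$mean_peak_length)
      })
      nrows <- vapply(mats, function(m) if (is.null(m)) 0L else nrow(m), 0L)
      se_chrom <- rep(se$chrom, nrows)
      m <- do.call(rbind, mats[nrows > 0])
      if (is.null(m)) m <- matrix(numeric(0), ncol = 2)
      ## background peaks
      n_bg <- rpois(1, cfg$background_rate_per_mb * mb_free)
      gi <- sample.int(nrow(bg_gaps), n_bg, replace = TRUE, prob = gap_len)
      bl <- round(runif(n_bg, 0.5, 1.5) * cfg$background_peak_length)
      bs <- bg_gaps$start[gi] + floor(runif(n_bg) * (gap_len[gi] - bl))
      bg <- tibble(chrom = bg_gaps$chrom[gi], start = bs, end = bs + bl)
      ## promoter peaks for the hypermethylated-promoter subset
      pp <- NULL
      if (length(prom_hyper_idx) > 0) {
        pw <- prom[prom_hyper_idx, ]
        wlen <- pw$end - pw$start
        cov <- rbeta(nrow(pw), 0.6 * cfg$jitter_concentration,
                     0.4 * cfg$jitter_concentration)
        plen <- pmax(1, round(cov * wlen))
        poff <- floor(runif(nrow(pw)) * (wlen - plen + 1))
        pp <- tibble(chrom = pw$chrom, start = pw$start + poff,
                     end = pw$start + poff + plen)
      }
      peaks <- bind_rows(
        tibble(chrom = se_chrom, start = m[, 1], end = m[, 2]),
        bg, pp)
      peaks <- arrange(peaks, .data$chrom, .data$start)
      paths[s] <- file.path(dir, paste0(sid, ".bed"))
      write_bed(peaks, paths[s])
    }
    paths
  }

  peak_paths <- write_peaks_for(frac_disc, disc$sample_id, file.path(out_dir, "peaks"))
  sheet <- mutate(disc, peaks_path = file.path("peaks", basename(peak_paths)))

  ## --- expression (discovery) -------------------------------------------
  expr <- expression_matrix_for(genes_truth, frac_disc, cfg, disc$sample_id)

  ## --- probes and validation cohort --------------------------------------
  probes <- bind_rows(lapply(seq_len(nrow(se)), function(j) {
    if (cfg$probes_per_se == 0) return(NULL)
    tibble(probe_id = sprintf("p_%s_%d", se$se_id[j], seq_len(cfg$probes_per_se)),
           chrom = se$chrom[j],
           pos = sort(round(runif(cfg$probes_per_se, se$start[j], se$end[j] - 1))),
           se_id = se$se_id[j])
  }))
  val <- tibble(
    sample_id = c(sprintf("vcase%02d", seq_len(cfg$n_case_val)),
                  sprintf("vctrl%02d", seq_len(cfg$n_control_val))),
    group = rep(c("case", "control"), c(cfg$n_case_val, cfg$n_control_val)))
  mean_val <- group_mean_matrix(se$class, val$group, cfg$f0, cfg$delta)
  dimnames(mean_val) <- list(se$se_id, val$sample_id)
  frac_val <- draw_fractions(mean_val, cfg$jitter_concentration)
  beta_vals <- frac_val[probes$se_id, , drop = FALSE] +
    matrix(rnorm(nrow(probes) * nrow(val), 0, cfg$probe_sd),
           nrow(probes), nrow(val))
  beta_vals <- pmin(pmax(beta_vals, 0), 1)
  betas <- bind_cols(tibble(probe_id = probes$probe_id),
                     setNames(as_tibble(as.data.frame(beta_vals)), val$sample_id))
  expr_val <- expression_matrix_for(genes_truth, frac_val, cfg, val$sample_id)

  ## --- truth --------------------------------------------------------------
  truth_se <- tibble(se_id = se$se_id, chrom = se$chrom, start = se$start,
                     end = se$end, class = se$class)
  truth_pairs <- mutate(
    select(genes_truth, "se_id", "gene_id", "role"),
    link_sign = dplyr::case_when(role == "target" ~ -1L,
                                 role == "artifact" ~ 1L,
                                 TRUE ~ 0L))

  ## --- write everything ----------------------------------------------------
  files <- list(
    chrom_sizes = file.path(out_dir, "chrom_sizes.tsv"),
    se_catalog = file.path(out_dir, "se_catalog.bed"),
    samples = file.path(out_dir, "samples.tsv"),
    genes = file.path(out_dir, "genes.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    probes = file.path(out_dir, "validation", "probes.tsv"),
    betas = file.path(out_dir, "validation", "betas.tsv"),
    expression_val = file.path(out_dir, "validation", "expression.tsv"),
    truth_se = file.path(out_dir, "truth", "se.tsv"),
    truth_pairs = file.path(out_dir, "truth", "pairs.tsv"))
  readr::write_tsv(sizes, files$chrom_sizes, col_names = FALSE, progress = FALSE)
  write_bed(mutate(se, name = .data$se_id)[, c("chrom", "start", "end", "name")],
            files$se_catalog)
  readr::write_tsv(sheet, files$samples, progress = FALSE)
  readr::write_tsv(genes, files$genes, progress = FALSE)
  readr::write_tsv(mutate(expr, across(dplyr::where(is.double), ~ signif(.x, 6))),
                   files$expression, progress = FALSE)
  readr::write_tsv(select(probes, -"se_id"), files$probes, progress = FALSE)
  readr::write_tsv(mutate(betas, across(dplyr::where(is.double), ~ signif(.x, 6))),
                   files$betas, progress = FALSE)
  readr::write_tsv(mutate(expr_val, across(dplyr::where(is.double), ~ signif(.x, 6))),
                   files$expression_val, progress = FALSE)
  readr::write_tsv(truth_se, files$truth_se, progress = FALSE)
  readr::write_tsv(truth_pairs, files$truth_pairs, progress = FALSE)

  invisible(list(dir = out_dir, files = files,
                 truth = list(se = truth_se, pairs = truth_pairs, config = cfg),
                 frac_discovery = frac_disc, frac_validation = frac_val))
}

#' Score pipeline calls against planted truth
#'
#' @param dm `se_dm` result on the simulated cohort.
#' @param pairs `se_pairs` result (with `passed`), or NULL.
#' @param truth Truth list from [simulate_cohort()] (or its `truth` element).
#' @param validated Optional pair table annotated by [validate_pairs()].
#' @return One-row tibble of recovery metrics: SE-level sensitivity,
#'   empirical FDR, specificity and direction accuracy; pair-level
#'   sensitivity (conditional on the SE being called, and overall),
#'   empirical FDR, artifact (positive-link) removal rate; and the
#'   validation rate when `validated` is given.
#' @export
truth_eval <- function(dm, pairs = NULL, truth, validated = NULL) {
  if (!is.null(truth$truth)) truth <- truth$truth
  tse <- truth$se
  d <- as_tibble(dm)
  if (!all(d$region_id %in% tse$se_id)) {
    abort("truth_eval: region ids do not match truth SE ids")
  }
  d <- left_join(d, select(tse, region_id = "se_id", "class"), by = "region_id")
  called <- d$direction != "none"
  planted <- d$class != "null"
  n_called <- sum(called)
  out <- tibble(
    n_se = nrow(d),
    n_dm_called = n_called,
    dm_sensitivity = if (sum(planted) > 0) mean(called[planted]) else NA_real_,
    dm_fdr = if (n_called > 0) mean(!planted[called]) else 0,
    dm_specificity = if (sum(!planted) > 0) mean(!called[!planted]) else NA_real_,
    dm_direction_accuracy = if (sum(called & planted) > 0) {
      mean((d$direction == d$class)[called & planted])
    } else NA_real_)
  if (!is.null(pairs)) {
    tp <- truth$pairs
    p <- left_join(as_tibble(pairs), tp, by = c("se_id", "gene_id"))
    known <- p$se_id %in% tse$se_id & p$gene_id %in% tp$gene_id
    if (!all(known)) abort("truth_eval: pair ids do not match truth")
    # a candidate pair joining a planted SE to another SE's gene is simply
    # not a planted link
    p$link_sign[is.na(p$link_sign)] <- 0L
    called_se <- d$region_id[called]
    planted_dm <- tse$se_id[tse$class != "null"]
    neg_all <- tp$link_sign == -1 & tp$se_id %in% planted_dm
    neg_called <- filter(p, .data$link_sign == -1,
                         .data$se_id %in% intersect(planted_dm, called_se))
    n_passed <- sum(p$passed)
    pos_cand <- filter(p, .data$link_sign == 1)
    out <- bind_cols(out, tibble(
      n_candidate_pairs = nrow(p),
      n_passed_pairs = n_passed,
      pair_sensitivity_called = if (nrow(neg_called) > 0) mean(neg_called$passed) else NA_real_,
      pair_sensitivity_overall = if (sum(neg_all) > 0) {
        sum(p$passed & p$link_sign == -1 & p$se_id %in% planted_dm) / sum(neg_all)
      } else NA_real_,
      pair_fdr = if (n_passed > 0) mean(p$link_sign[p$passed] != -1) else 0,
      artifact_removal = if (nrow(pos_cand) > 0) mean(!pos_cand$passed) else NA_real_))
  }
  if (!is.null(validated)) {
    v <- left_join(as_tibble(validated), truth$pairs, by = c("se_id", "gene_id"))
    v$link_sign[is.na(v$link_sign)] <- 0L
    assessable <- v$link_sign == -1 & v$passed & !is.na(v$validated)
    out$validation_rate <- if (sum(assessable) > 0) {
      mean(v$validated[assessable])
    } else NA_real_
    out$n_validated <- sum(v$validated, na.rm = TRUE)
  }
  out
}
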