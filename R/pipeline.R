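# End-to-end orchestration: catalog -> SE methylation -> differential SEs ->
# candidate in-cis targets -> correlation screen -> (optional) array
# validation, with the filtering funnel logged at every stage. Arguments may
# be file paths (read with the package readers) or in-memory tibbles.

load_or <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else x

#' Run the full SE differential-methylation and target-linkage pipeline
#'
#' @param se_bed SE catalog: BED path or interval tibble.
#' @param samples Sample sheet: TSV path or tibble (sample_id, group,
#'   peaks_path).
#' @param chrom_sizes Chromosome sizes: TSV path, tibble or named vector.
#' @param genes Gene annotation: TSV path or tibble.
#' @param expr Expression matrix: TSV path or tibble.
#' @param probes,betas,expr_validation Optional array-validation inputs
#'   (probe map, beta matrix, validation-cohort expression); when all three
#'   are given, passed pairs are validated.
#' @param out_dir Optional directory; when given, result tables are written
#'   there deterministically.
#' @param window TSS eligibility window in bp (default 1 Mbp).
#' @param promoter_up,promoter_down Promoter window around the TSS (defaults
#'   1500 / 500 bp).
#' @param dm_alpha,pair_alpha FDR thresholds for DM-SE calling and pair
#'   screening (defaults 0.05).
#' @param validation_p Unadjusted p cutoff for validation (default 0.05).
#' @param fdr_scope `"joint"` or `"per_se"` FDR scope for pair correlations.
#' @param run_tile_scan Also run the genome-wide 100 bp tile scan and the
#'   DM-tile/SE-catalog overlap statistic (default FALSE; intended for small
#'   genomes).
#' @param tile_width Tile width in bp for the tile scan (default 100).
#' @param quiet Suppress progress messages.
#' @return An `se_pipeline` list: `se_catalog`, `se_meth`, `dm`, `pairs`
#'   (all candidates, with promoter correlations), `passed`, `validated`
#'   (or NULL), `tiles`/`overlap` (or NULL), and `funnel` (stage counts).
#' @export
run_pipeline <- function(se_bed, samples, chrom_sizes, genes, expr,
                         probes = NULL, betas = NULL, expr_validation = NULL,
                         out_dir = NULL,
                         window = 1e6, promoter_up = 1500, promoter_down = 500,
                         dm_alpha = 0.05, pair_alpha = 0.05, validation_p = 0.05,
                         fdr_scope = c("joint", "per_se"),
                         run_tile_scan = FALSE, tile_width = 100,
                         quiet = FALSE) {
  fdr_scope <- match.arg(fdr_scope)
  run <- function(expr_) if (quiet) suppressMessages(expr_) else expr_

  se_catalog <- load_or(se_bed, read_bed)
  samples <- load_or(samples, read_sample_sheet)
  sizes <- if (is.character(chrom_sizes)) read_chrom_sizes(chrom_sizes) else as_chrom_sizes(chrom_sizes)
  genes <- load_or(genes, read_gene_annotation)
  expr <- load_or(expr, function(p) read_matrix_tsv(p, "expression"))

  run({
    se_meth <- region_methylation_matrix(se_catalog, samples, kind = "se")
    dm <- se_differential(se_meth, samples, alpha = dm_alpha)
    dm_set <- dm_regions(dm)
    cand <- find_targets(dm_set, genes, window = window)
    inform(sprintf("find_targets: %d candidate pairs over %d genes within %g bp of %d DM-SEs",
                   nrow(cand), length(unique(cand$gene_id)), window, nrow(dm_set)))
    pairs <- correlate_pairs(cand, se_meth, expr, alpha = pair_alpha,
                             fdr_scope = fdr_scope)
    cand_genes <- filter(genes, .data$gene_id %in% unique(pairs$gene_id))
    prom_meth <- region_methylation_matrix(
      promoter_intervals(cand_genes, sizes, promoter_up, promoter_down),
      samples, kind = "promoter")
    pairs <- new_se_pairs(correlate_promoters(pairs, prom_meth, expr),
                          alpha = pair_alpha, fdr_scope = fdr_scope,
                          n_samples = attr(pairs, "n_samples"))
    passed <- filter(as_tibble(pairs), .data$passed)

    validated <- NULL
    if (!is.null(probes) && !is.null(betas) && !is.null(expr_validation)) {
      probes <- load_or(probes, function(p) readr::read_tsv(
        p, col_types = readr::cols(probe_id = "c", chrom = "c", pos = "d"),
        progress = FALSE))
      betas <- load_or(betas, function(p) read_matrix_tsv(p, "beta"))
      expr_validation <- load_or(expr_validation,
                                 function(p) read_matrix_tsv(p, "expression"))
      validated <- validate_pairs(passed, probes, betas, expr_validation,
                                  p_cut = validation_p)
    }

    tiles_dm <- NULL
    overlap <- NULL
    if (run_tile_scan) {
      status <- tile_status_matrix(tile_genome(sizes, tile_width), samples)
      tiles_dm <- scan_tiles(status, samples, alpha = dm_alpha)
      overlap <- dm_tiles_vs_se_overlap(tiles_dm, se_catalog, sizes)
    }
  })

  funnel <- tibble(
    stage = c("input_SEs", "dm_SEs", "hyper_SEs", "hypo_SEs",
              "candidate_genes", "candidate_pairs", "passed_pairs",
              "validated_pairs"),
    n = c(nrow(se_catalog), nrow(dm_regions(dm)),
          sum(dm$direction == "hyper"), sum(dm$direction == "hypo"),
          length(unique(pairs$gene_id)), nrow(pairs), nrow(passed),
          if (is.null(validated)) NA_integer_ else sum(validated$validated, na.rm = TRUE)))

  res <- structure(
    list(se_catalog = se_catalog, se_meth = se_meth, dm = dm, pairs = pairs,
         passed = passed, validated = validated, tiles = tiles_dm,
         overlap = overlap, funnel = funnel,
         params = list(window = window, promoter_up = promoter_up,
                       promoter_down = promoter_down, dm_alpha = dm_alpha,
                       pair_alpha = pair_alpha, validation_p = validation_p,
                       fdr_scope = fdr_scope, tile_width = tile_width)),
    class = "se_pipeline")
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write pipeline result tables to a directory
#'
#' @param x An `se_pipeline` result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_pipeline_results <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dm = file.path(out_dir, "se_differential.tsv"),
    dm_bed = file.path(out_dir, "dm_se.bed"),
    pairs = file.path(out_dir, "pairs_all.tsv"),
    passed = file.path(out_dir, "pairs_passed.tsv"),
    funnel = file.path(out_dir, "funnel.tsv"))
  write_result_tsv(as_tibble(x$dm), paths[["dm"]])
  write_bed(dplyr::rename(dm_regions(x$dm), name = "region_id"), paths[["dm_bed"]])
  write_result_tsv(as_tibble(x$pairs), paths[["pairs"]])
  write_result_tsv(x$passed, paths[["passed"]])
  readr::write_tsv(x$funnel, paths[["funnel"]], progress = FALSE)
  if (!is.null(x$validated)) {
    paths[["validated"]] <- file.path(out_dir, "pairs_validated.tsv")
    write_result_tsv(x$validated, paths[["validated"]])
  }
  if (!is.null(x$tiles)) {
    paths[["tiles"]] <- file.path(out_dir, "tiles_differential.tsv")
    write_result_tsv(as_tibble(x$tiles), paths[["tiles"]])
  }
  if (!is.null(x$overlap)) {
    paths[["overlap"]] <- file.path(out_dir, "overlap_stats.tsv")
    readr::write_tsv(mutate(x$overlap, across(dplyr::where(is.double), ~ signif(.x, 6))),
                     paths[["overlap"]], progress = FALSE)
  }
  invisible(paths)
}

#' @export
print.se_pipeline <- function(x, ...) {
  cat("SE methylation pipeline result\n")
  cat(sprintf("  samples: %d case / %d control\n",
              attr(x$dm, "n_case"), attr(x$dm, "n_control")))
  f <- x$funnel
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-16s %s\n", f$stage[i],
                ifelse(is.na(f$n[i]), "-", format(f$n[i]))))
  }
  invisible(x)
}
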