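# Small simulated cohorts shared across test files, built once per run.

small_sim_config <- function(seed, ...) {
  defaults <- list(n_case = 10, n_control = 8, n_chrom = 2,
                   chrom_length = 3e7, n_se = 40,
                   frac_hyper = 0.2, frac_hypo = 0.1,
                   n_case_val = 10, n_control_val = 6)
  do.call(sim_config, c(list(seed = seed),
                        utils::modifyList(defaults, list(...))))
}

.cohort_cache <- new.env(parent = emptyenv())

# one small simulated cohort + full pipeline run, memoised for the session
shared_small_run <- function() {
  if (!is.null(.cohort_cache$small)) return(.cohort_cache$small)
  td <- file.path(tempdir(), "semeth-shared-small")
  sim <- simulate_cohort(small_sim_config(seed = 424242), td)
  res <- run_pipeline(sim$files$se_catalog, sim$files$samples,
                      sim$files$chrom_sizes, sim$files$genes,
                      sim$files$expression,
                      probes = sim$files$probes, betas = sim$files$betas,
                      expr_validation = sim$files$expression_val,
                      quiet = TRUE)
  .cohort_cache$small <- list(sim = sim, res = res)
  .cohort_cache$small
}

# tiny deterministic peak fixtures for quantification tests
write_tiny_cohort <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beds <- list(
    s1 = tibble::tibble(chrom = "chr1", start = c(99, 150), end = c(101, 250)),
    s2 = tibble::tibble(chrom = "chr1", start = 0, end = 100),
    s3 = tibble::tibble(chrom = "chr2", start = 10, end = 20))
  paths <- vapply(names(beds), function(s) {
    p <- file.path(dir, paste0(s, ".bed"))
    write_bed(beds[[s]], p)
    p
  }, "")
  tibble::tibble(sample_id = names(beds),
                 group = c("case", "case", "control"),
                 peaks_path = unname(paths))
}
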