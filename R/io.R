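# Readers and writers for the external tables: BED interval files, chromosome
# sizes, sample sheets, gene annotation, and gene/probe x sample matrices.
# Readers reject malformed records (with the offending line) rather than
# coercing; writers are deterministic so identical inputs give identical bytes.

#' Read a BED file as an interval tibble
#'
#' Accepts BED3+ (MACS narrowPeak included: only the first 3/6 columns are
#' used). Column 4 becomes `name` and column 6 `strand` when present.
#' `track`, `browser` and `#` lines are skipped.
#'
#' @param path Path to a BED file.
#' @return Interval tibble (chrom, start, end, and name/strand when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: line %d has fewer than 3 columns", path, lineno[which(nf < 3)[1]]))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-integer coordinates at line %d", path, lineno[bad[1]]))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at line %d", path, lineno[bad[1]]))
  }
  out <- tibble(chrom = col(1), start = start, end = end)
  if (any(nf >= 4)) out$name <- col(4)
  if (any(nf >= 6)) {
    strand <- col(6)
    ok <- is.na(strand) | strand %in% c("+", "-", ".")
    if (!all(ok)) {
      abort(sprintf("%s: unknown strand token at line %d", path, lineno[which(!ok)[1]]))
    }
    out$strand <- strand
  }
  out
}

#' Write an interval tibble as BED
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom,
               format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) cols <- c(cols, list(x$name))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome sizes table
#'
#' Two-column TSV (chromosome name, length in bp), no header.
#'
#' @param path Path to the TSV.
#' @return Chromosome sizes tibble (chrom, length).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = readr::cols(chrom = "c", length = "d"),
                       progress = FALSE)
  as_chrom_sizes(x)
}

#' Read a sample sheet
#'
#' TSV with header columns `sample_id`, `group` (`case`/`control`) and
#' `peaks_path`. Relative peak paths are resolved against the sheet's
#' directory.
#'
#' @param path Path to the sheet.
#' @return Tibble with columns sample_id, group, peaks_path.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("sample_id", "group", "peaks_path")
  if (!all(need %in% names(x))) {
    abort(paste0(path, ": sample sheet needs columns ", paste(need, collapse = ", ")))
  }
  x <- as_tibble(x[, need])
  validate_sample_sheet(x)
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", x$peaks_path)
  x$peaks_path[rel] <- file.path(base, x$peaks_path[rel])
  x
}

validate_sample_sheet <- function(x) {
  if (!is.data.frame(x) ||
      !all(c("sample_id", "group") %in% names(x))) {
    abort("sample sheet must have columns sample_id and group")
  }
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in sample sheet")
  if (!all(x$group %in% c("case", "control"))) {
    abort("sample sheet group must be 'case' or 'control'")
  }
  invisible(x)
}

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `chrom`, `strand` (`+`/`-`) and `tss`
#' (0-based transcription start site).
#'
#' @param path Path to the TSV.
#' @return Tibble with those four columns.
#' @export
read_gene_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(x))) {
    abort(paste0(path, ": gene annotation needs columns ", paste(need, collapse = ", ")))
  }
  x <- as_tibble(x[, need])
  x$tss <- suppressWarnings(as.numeric(x$tss))
  if (anyDuplicated(x$gene_id)) abort(paste0(path, ": duplicate gene_id"))
  if (!all(x$strand %in% c("+", "-"))) abort(paste0(path, ": strand must be + or -"))
  if (any(!is.finite(x$tss) | x$tss < 0 | x$tss != floor(x$tss))) {
    abort(paste0(path, ": tss must be a non-negative integer"))
  }
  x
}

#' Read a numeric matrix TSV (expression or probe beta values)
#'
#' First column holds row identifiers, header row holds sample identifiers.
#' Empty cells and `NA` are kept as missing (they are later excluded pairwise
#' from correlations).
#'
#' @param path Path to the TSV.
#' @param kind `"expression"` (non-negative values, id column `gene_id`) or
#'   `"beta"` (values in `[0, 1]`, id column `probe_id`).
#' @return Tibble with the id column followed by one numeric column per sample.
#' @export
read_matrix_tsv <- function(path, kind = c("expression", "beta")) {
  kind <- match.arg(kind)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = c("", "NA"), progress = FALSE)
  if (ncol(x) < 2) abort(paste0(path, ": matrix needs an id column plus samples"))
  id_col <- if (kind == "expression") "gene_id" else "probe_id"
  names(x)[1] <- id_col
  if (anyDuplicated(x[[1]])) abort(paste0(path, ": duplicate row ids"))
  vals <- x[, -1]
  num <- lapply(vals, function(v) suppressWarnings(as.numeric(v)))
  for (j in seq_along(num)) {
    bad <- !is.na(vals[[j]]) & is.na(num[[j]])
    if (any(bad)) {
      abort(sprintf("%s: non-numeric entry '%s' in column %s",
                    path, vals[[j]][which(bad)[1]], names(vals)[j]))
    }
  }
  m <- as_tibble(num)
  all_vals <- unlist(num)
  if (length(all_vals) > 0 && !all(is.na(all_vals))) {
    rng <- range(all_vals, na.rm = TRUE)
    if (kind == "beta" && (rng[1] < 0 || rng[2] > 1)) {
      abort(paste0(path, ": beta values must lie in [0, 1]"))
    }
    if (kind == "expression" && rng[1] < 0) {
      abort(paste0(path, ": expression values must be non-negative"))
    }
  }
  bind_cols(x[, 1], m)
}

matrix_samples <- function(x) setdiff(names(x), c(
  "gene_id", "probe_id", "region_id", "chrom", "start", "end", "kind", "source_id"))

#' Write a result table deterministically
#'
#' Rows are sorted by whichever of `chrom`, `start`, `gene_id`, `region_id`
#' are present; doubles are rounded to 6 significant digits, so identical
#' inputs produce byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  keys <- intersect(c("chrom", "start", "gene_id", "region_id"), names(x))
  if (length(keys) > 0) x <- arrange(x, across(dplyr::all_of(keys)))
  x <- mutate(x, across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
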