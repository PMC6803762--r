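# Genomic interval algebra on plain tibbles.
#
# Conventions: coordinates are 0-based, half-open ([start, end), BED-style)
# everywhere in this package. The heavy lifting (merging, overlap search)
# is delegated to IRanges; tibbles are converted to 1-based closed IRanges
# per chromosome at the boundary.

#' Construct a genomic interval tibble
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` and
#' optionally `name` and `strand`, using 0-based half-open (BED) coordinates.
#'
#' @param chrom Chromosome names (character).
#' @param start,end 0-based half-open coordinates; `0 <= start < end`.
#' @param name Optional interval labels.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."`.
#' @return A tibble with one row per interval.
#' @examples
#' intervals("chr1", c(0, 150), c(100, 300))
#' @export
intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  x <- tibble(chrom = as.character(chrom), start = as.numeric(start),
              end = as.numeric(end))
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(strand)) x$strand <- as.character(strand)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " must be a data frame with columns chrom, start, end"))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(paste0(what, ": start and end must be numeric"))
  }
  whole <- function(v) all(is.finite(v)) && all(v == floor(v))
  if (!whole(x$start) || !whole(x$end)) {
    abort(paste0(what, ": coordinates must be non-negative integers"))
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "%s: malformed interval at row %d (%s:%s-%s); need 0 <= start < end",
      what, i, x$chrom[i], format(x$start[i], scientific = FALSE),
      format(x$end[i], scientific = FALSE)))
  }
  invisible(x)
}

# tibble -> list of IRanges keyed by chromosome (1-based closed)
split_iranges <- function(x) {
  idx <- split(seq_len(nrow(x)), x$chrom)
  lapply(idx, function(i) IRanges::IRanges(start = x$start[i] + 1, end = x$end[i]))
}

iranges_to_tibble <- function(ir_list) {
  chroms <- sort(names(ir_list))
  rows <- lapply(chroms, function(ch) {
    ir <- ir_list[[ch]]
    tibble(chrom = rep(ch, length(ir)),
           start = IRanges::start(ir) - 1,
           end = as.numeric(IRanges::end(ir)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(chrom = character(), start = numeric(), end = numeric())
  arrange(out, .data$chrom, .data$start)
}

#' Normalize an interval set
#'
#' Sorts intervals and merges any that overlap or touch, so that within each
#' chromosome the result is ordered, pairwise disjoint and non-adjacent.
#' Total covered base pairs are unchanged.
#'
#' @param x Interval tibble (see [intervals()]).
#' @return A normalized interval tibble with columns chrom, start, end.
#' @examples
#' normalize_intervals(intervals("chr1", c(100, 150), c(160, 200)))
#' @export
normalize_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  iranges_to_tibble(lapply(split_iranges(x), IRanges::reduce))
}

total_length <- function(x) sum(x$end - x$start)

#' Net intersection length of regions with a peak set
#'
#' For each region, counts the base pairs covered by at least one peak —
#' the per-sample methylation metric for SEs and promoters: the net length
#' of the intersection of the region with a sample's methylation peaks.
#'
#' @param regions Interval tibble of regions (one result per row).
#' @param peaks Interval tibble of peaks; normalized internally.
#' @return Numeric vector of covered base pairs, one per region row, each in
#'   `[0, region length]`. Regions on chromosomes absent from `peaks` get 0.
#' @examples
#' net_intersection_length(intervals("chr1", 100, 200),
#'                         intervals("chr1", c(90, 180), c(120, 300)))
#' @export
net_intersection_length <- function(regions, peaks) {
  validate_intervals(regions, "regions")
  validate_intervals(peaks, "peaks")
  out <- numeric(nrow(regions))
  if (nrow(regions) == 0 || nrow(peaks) == 0) return(out)
  peak_ir <- lapply(split_iranges(peaks), IRanges::reduce)
  idx <- split(seq_len(nrow(regions)), regions$chrom)
  for (ch in names(idx)) {
    pk <- peak_ir[[ch]]
    if (is.null(pk) || length(pk) == 0) next
    i <- idx[[ch]]
    reg <- IRanges::IRanges(start = regions$start[i] + 1, end = regions$end[i])
    hits <- IRanges::findOverlaps(reg, pk)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    w <- pmin(IRanges::end(reg)[q], IRanges::end(pk)[s]) -
      pmax(IRanges::start(reg)[q], IRanges::start(pk)[s]) + 1
    cov <- tapply(w, q, sum)
    out[i[as.integer(names(cov))]] <- as.numeric(cov)
  }
  out
}

#' Chromosome sizes table
#'
#' @param x Either a two-column data frame (chrom, length) or a named numeric
#'   vector of chromosome lengths.
#' @return A tibble with columns `chrom` and `length`.
#' @export
as_chrom_sizes <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble(chrom = names(x), length = as.numeric(x))
  }
  if (!is.data.frame(x) || !all(c("chrom", "length") %in% names(x))) {
    abort("chromosome sizes must have columns chrom and length")
  }
  x <- as_tibble(x[, c("chrom", "length")])
  x$chrom <- as.character(x$chrom)
  x$length <- as.numeric(x$length)
  if (anyDuplicated(x$chrom)) abort("duplicate chromosome names in sizes table")
  if (any(!is.finite(x$length) | x$length <= 0 | x$length != floor(x$length))) {
    abort("chromosome lengths must be positive integers")
  }
  x
}

#' Tile a genome with fixed-width windows
#'
#' Produces non-overlapping tiles `[0,w), [w,2w), ...` per chromosome, the
#' final tile truncated at the chromosome end, so the tiles cover every base
#' exactly once.
#'
#' @param sizes Chromosome sizes (see [as_chrom_sizes()]).
#' @param width Tile width in bp (default 100).
#' @return Interval tibble with a `name` column (`chrom:start-end`).
#' @export
tile_genome <- function(sizes, width = 100) {
  sizes <- as_chrom_sizes(sizes)
  if (!is.numeric(width) || length(width) != 1 || width < 1) {
    abort("tile width must be a single integer >= 1")
  }
  rows <- lapply(seq_len(nrow(sizes)), function(i) {
    len <- sizes$length[i]
    start <- seq(0, len - 1, by = width)
    tibble(chrom = sizes$chrom[i], start = start, end = pmin(start + width, len))
  })
  out <- bind_rows(rows)
  out$name <- paste0(out$chrom, ":", format(out$start, scientific = FALSE, trim = TRUE),
                     "-", format(out$end, scientific = FALSE, trim = TRUE))
  out
}

#' Jaccard index of two interval sets
#'
#' Base-pair Jaccard index `|A intersect B| / |A union B|` after
#' normalization. Defined as 0 when both sets are empty.
#'
#' @param a,b Interval tibbles.
#' @return A number in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  a <- normalize_intervals(a)
  b <- normalize_intervals(b)
  la <- total_length(a)
  lb <- total_length(b)
  if (la + lb == 0) return(0)
  inter <- sum(net_intersection_length(a, b))
  inter / (la + lb - inter)
}

#' Distance from a position to an interval
#'
#' 0 if the position lies inside the (half-open) interval, otherwise the gap
#' in bp to the nearest covered base. Positions on a different chromosome get
#' `Inf` (such gene-SE combinations are simply skipped by pairing, never an
#' error).
#'
#' @param pos Base-pair positions (0-based).
#' @param region Interval tibble, recycled against `pos` (either one row or
#'   `length(pos)` rows).
#' @param pos_chrom Optional chromosome of each position; when supplied,
#'   mismatches with `region$chrom` yield `Inf`.
#' @return Numeric vector of distances in bp.
#' @export
distance_to_interval <- function(pos, region, pos_chrom = NULL) {
  validate_intervals(region, "region")
  n <- max(length(pos), nrow(region))
  start <- rep_len(region$start, n)
  end <- rep_len(region$end, n)
  chrom <- rep_len(region$chrom, n)
  pos <- rep_len(as.numeric(pos), n)
  d <- ifelse(pos >= start & pos < end, 0,
              pmin(abs(pos - start), abs(pos - (end - 1))))
  if (!is.null(pos_chrom)) d[rep_len(as.character(pos_chrom), n) != chrom] <- Inf
  d
}

interval_midpoint <- function(x) floor((x$start + x$end) / 2)

#' Midpoint-projection overlap statistics
#'
#' Counts query intervals whose midpoint falls inside the reference set and
#' compares the count with the binomial expectation under uniform placement
#' (reference coverage / genome length), in the spirit of genome-wide
#' interval-correlation tools. The p-value is the upper binomial tail at the
#' observed count.
#'
#' @param query,reference Interval tibbles.
#' @param sizes Chromosome sizes defining the genome.
#' @return One-row tibble: `n_query`, `observed`, `expected`, `ratio`,
#'   `p_value`. `ratio` is `NA` when the query is empty.
#' @export
projection_overlap_stats <- function(query, reference, sizes) {
  sizes <- as_chrom_sizes(sizes)
  validate_intervals(query, "query")
  reference <- normalize_intervals(reference)
  genome <- sum(sizes$length)
  if (genome <= 0) abort("genome length must be positive")
  covered <- total_length(reference)
  p0 <- covered / genome
  n <- nrow(query)
  if (n == 0) {
    return(tibble(n_query = 0L, observed = 0L, expected = 0,
                  ratio = NA_real_, p_value = NA_real_))
  }
  mid <- interval_midpoint(query)
  points <- tibble(chrom = query$chrom, start = mid, end = mid + 1)
  observed <- sum(net_intersection_length(points, reference) > 0)
  expected <- n * p0
  tibble(
    n_query = n,
    observed = as.integer(observed),
    expected = expected,
    ratio = if (expected > 0) observed / expected else NA_real_,
    p_value = pbinom(observed - 1, n, p0, lower.tail = FALSE)
  )
}
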