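# Region x sample methylation matrices. Entries are either the net bp of
# peak intersection (SEs, promoters) or a binary methylation status (tiles:
# any intersection at all). One column per sample-sheet sample, in sheet
# order; one row per catalog region, in catalog order (duplicate coordinates
# each keep their own row, as duplicated catalog entries are treated
# individually).

region_ids <- function(regions) {
  base <- if ("name" %in% names(regions) && !anyNA(regions$name)) {
    regions$name
  } else {
    paste0(regions$chrom, ":",
           format(regions$start, scientific = FALSE, trim = TRUE), "-",
           format(regions$end, scientific = FALSE, trim = TRUE))
  }
  make.unique(base, sep = "#")
}

read_sample_peaks <- function(samples) {
  validate_sample_sheet(samples)
  if (!"peaks_path" %in% names(samples)) {
    abort("sample sheet has no peaks_path column")
  }
  peaks <- vector("list", nrow(samples))
  names(peaks) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    p <- samples$peaks_path[i]
    if (!file.exists(p)) {
      abort(sprintf("peak file for sample %s not found: %s", samples$sample_id[i], p))
    }
    peaks[[i]] <- read_bed(p)
  }
  peaks
}

build_region_matrix <- function(regions, samples, kind, binary) {
  validate_intervals(regions, "regions")
  peaks <- read_sample_peaks(samples)
  out <- tibble(region_id = region_ids(regions),
                chrom = regions$chrom, start = regions$start, end = regions$end,
                kind = kind)
  for (sid in samples$sample_id) {
    v <- net_intersection_length(regions, peaks[[sid]])
    out[[sid]] <- if (binary) as.numeric(v > 0) else v
  }
  out
}

#' Binary methylation status matrix for genome tiles
#'
#' A tile is methylated in a sample iff it has any base in common with that
#' sample's methylation peaks.
#'
#' @param tiles Interval tibble of tiles (see [tile_genome()]).
#' @param samples Sample sheet with `sample_id`, `group`, `peaks_path`.
#' @return Tibble: region_id, chrom, start, end, kind, then one 0/1 column
#'   per sample.
#' @export
tile_status_matrix <- function(tiles, samples) {
  build_region_matrix(tiles, samples, kind = "tile", binary = TRUE)
}

#' Net-intersection methylation matrix for regions
#'
#' Entry = net bp of the region covered by the sample's methylation peaks,
#' the per-sample SE (or promoter) methylation metric.
#'
#' @inheritParams tile_status_matrix
#' @param regions Interval tibble (SE catalog or promoter windows).
#' @param kind Label stored in the `kind` column (default `"se"`).
#' @return Tibble: region_id, chrom, start, end, kind, then one bp column per
#'   sample.
#' @export
region_methylation_matrix <- function(regions, samples, kind = "se") {
  build_region_matrix(regions, samples, kind = kind, binary = FALSE)
}

#' Promoter windows around transcription start sites
#'
#' The promoter is the interval 1500 bp upstream to 500 bp downstream of the
#' TSS, taken strand-relatively: on `+` a TSS `t` gives `[t-1500, t+500)`, on
#' `-` it gives `[t-500, t+1500)`. Windows are clamped to chromosome bounds.
#'
#' @param genes Gene annotation tibble (gene_id, chrom, strand, tss).
#' @param sizes Chromosome sizes.
#' @param upstream,downstream Window extents in bp (defaults 1500 / 500).
#' @return Interval tibble with `name` = gene_id.
#' @export
promoter_intervals <- function(genes, sizes, upstream = 1500, downstream = 500) {
  sizes <- as_chrom_sizes(sizes)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("promoter_intervals: every gene needs strand + or -")
  }
  len <- setNames(sizes$length, sizes$chrom)[genes$chrom]
  if (anyNA(len)) {
    abort(paste0("promoter_intervals: chromosome missing from sizes: ",
                 genes$chrom[which(is.na(len))[1]]))
  }
  if (any(genes$tss >= len)) {
    i <- which(genes$tss >= len)[1]
    abort(sprintf("promoter_intervals: TSS beyond chromosome end for gene %s",
                  genes$gene_id[i]))
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  tibble(chrom = genes$chrom,
         start = pmax(0, start),
         end = pmin(unname(len), end),
         name = genes$gene_id,
         strand = genes$strand)
}
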