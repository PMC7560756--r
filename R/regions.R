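#' Detect high-depth (complex) regions from a coverage profile
#'
#' A window is flagged when at least `sample_threshold` samples show mean
#' depth `>= depth_threshold` in it — the signature of collapsed duplicated
#' sequence that attracts mismapped reads and generates unreliable SV calls.
#' Flagged windows on the same chromosome separated by at most `merge_gap`
#' bp are merged into single intervals.
#'
#' @param coverage A `coverage_profile` (see [simulate_coverage()]) or a list
#'   with `windows` (tibble `chrom`, `start`, `end`) and `depth` (windows x
#'   samples matrix).
#' @param depth_threshold Depth cutoff per sample (default 100x).
#' @param sample_threshold Minimum number of samples at or above the depth
#'   cutoff (default 100).
#' @param merge_gap Maximum gap (bp, inclusive) between flagged windows to
#'   merge (default 100).
#' @return A region tibble `chrom`, `start`, `end` (0-based half-open,
#'   sorted, non-overlapping).
#' @export
find_high_depth_regions <- function(coverage, depth_threshold = 100,
                                    sample_threshold = 100, merge_gap = 100) {
  stopifnot(depth_threshold > 0, sample_threshold > 0, merge_gap >= 0)
  n_samples <- ncol(coverage$depth)
  if (sample_threshold > n_samples) {
    abort(sprintf("sample_threshold (%d) exceeds the %d samples in the profile",
                  sample_threshold, n_samples),
          class = "svpop_value_error")
  }
  n_qual <- rowSums(coverage$depth >= depth_threshold)
  flagged <- coverage$windows[n_qual >= sample_threshold, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(as_granges0(flagged), min.gapwidth = merge_gap + 1L)
  granges_to_regions(gr)
}

granges_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Merge two region sets into a sorted, coalesced union
#'
#' Overlapping and abutting intervals (half-open: `[100,200)` and
#' `[200,300)` share a boundary but no base) are coalesced.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`; 0-based half-open).
#' @return A region tibble, sorted and non-overlapping.
#' @export
merge_regions <- function(a, b) {
  both <- dplyr::bind_rows(a, b)
  if (nrow(both) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  granges_to_regions(GenomicRanges::reduce(as_granges0(both)))
}

#' Partition an SV catalog by overlap with excluded regions
#'
#' An SV is excluded when it shares at least one base with any region
#' (half-open intervals: an SV ending where a region starts does not
#' overlap it). The partition is exhaustive and disjoint.
#'
#' @param catalog SV catalog tibble.
#' @param regions Region tibble; zero rows keeps everything.
#' @return A list with `kept` and `excluded` catalog tibbles.
#' @export
exclude_overlapping <- function(catalog, regions) {
  if (nrow(catalog) == 0L || nrow(regions) == 0L) {
    return(list(kept = catalog, excluded = catalog[0, ]))
  }
  hit <- IRanges::overlapsAny(as_granges0(catalog), as_granges0(regions))
  list(kept = catalog[!hit, , drop = FALSE],
       excluded = catalog[hit, , drop = FALSE])
}

#' Read a BED file as a region tibble
#'
#' @param path Path to a BED file (0-based half-open, as BED is defined).
#' @return A region tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    granges_to_regions(gr)
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    tibble(chrom = df[[1]], start = as.integer(df[[2]]), end = as.integer(df[[3]])) |>
      dplyr::arrange(.data$chrom, .data$start)
  }
}

#' Write a region tibble as 3-column BED
#'
#' @param regions Region tibble `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d", regions$chrom, regions$start, regions$end),
             path)
  invisible(path)
}
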