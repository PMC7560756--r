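#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer
NULL

# Derive a deterministic 31-bit substream seed from a global seed and a
# stream name, so adding one simulation stage never perturbs another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483629 + 1)
}

with_substream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

# genotype string <-> dosage codes; NA carried through
GT_LEVELS <- c("0/0", "0/1", "1/1")

gt_to_dosage <- function(gt) {
  d <- match(gt, GT_LEVELS) - 1L
  d[is.na(gt)] <- NA_integer_
  d
}

dosage_to_gt <- function(d) {
  GT_LEVELS[d + 1L]
}

# SV catalog / region tibble -> GRanges (internal 0-based half-open to
# 1-based closed; conversions happen only here and at the VCF/BED edges)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1]", name),
          class = "svpop_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) || any(x != floor(x))) {
    abort(sprintf("`%s` must be an integer count >= %d", name, min),
          class = "svpop_config_error")
  }
  invisible(x)
}

sv_types <- c("DEL", "DUP", "INV")
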