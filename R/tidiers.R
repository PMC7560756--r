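#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fst_outlier_scan `tidy()` returns the per-SV results tibble.
#' @param x An `fst_scan` object.
#' @param ... Unused.
#' @export
tidy.fst_scan <- function(x, ...) {
  x$results
}

#' @describeIn fst_outlier_scan `glance()` returns a one-row scan summary.
#' @export
glance.fst_scan <- function(x, ...) {
  out <- dplyr::filter(x$results, .data$outlier)
  tibble(
    n_sv = nrow(x$results),
    n_polymorphic = sum(!x$results$excluded_monomorphic),
    n_outliers = nrow(out),
    global_cutoff = x$global_cutoff,
    median_outlier_theta = if (nrow(out)) stats::median(out$theta) else NA_real_,
    n_perm = x$n_perm, q = x$q, alpha = x$alpha
  )
}

#' @describeIn ohnolog_enrichment `tidy()` returns a one-row tibble with the
#'   2x2 counts, odds ratio and P value.
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    test = x$test,
    n11 = x$table[1, 1], n12 = x$table[1, 2],
    n21 = x$table[2, 1], n22 = x$table[2, 2],
    odds_ratio = x$odds_ratio,
    p_value = x$p_value,
    or_defined = x$or_defined
  )
}

#' @describeIn expression_correlation_resample `tidy()` returns a one-row
#'   summary tibble.
#' @param x A `resample_test`.
#' @param ... Unused.
#' @export
tidy.resample_test <- function(x, ...) {
  tibble(
    observed_median = x$observed_median,
    null_median = stats::median(x$null_medians),
    p_value = x$p_value,
    n_selected = x$n_selected,
    n_pairs = x$n_pairs,
    n_resample = x$n_resample
  )
}

#' @describeIn pca_dosage `tidy()` returns the sample score tibble.
#' @param x A `dosage_pca`.
#' @param ... Unused.
#' @export
tidy.dosage_pca <- function(x, ...) {
  x$scores
}

#' @describeIn pca_dosage `glance()` returns per-component explained
#'   variance fractions.
#' @export
glance.dosage_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained)),
         explained_variance = x$explained)
}
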