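#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_point
#'   geom_vline geom_col facet_wrap labs theme_minimal scale_x_log10
#' @export
ggplot2::autoplot

#' Plot SV size distributions by type
#'
#' Histogram of SV sizes on a log10 axis, faceted by type; the narrow
#' deletion spike near 1.4 kb is visible as an isolated bar when present.
#'
#' @param catalog SV catalog tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_sv_sizes <- function(catalog, bins = 60) {
  ggplot(catalog, aes(x = .data$size)) +
    geom_histogram(bins = bins, fill = "grey30") +
    scale_x_log10() +
    facet_wrap(~svtype, scales = "free_y") +
    labs(x = "SV size (bp)", y = "count") +
    theme_minimal()
}

#' @describeIn fst_outlier_scan `autoplot()` draws the observed theta
#'   distribution against the permutation null with the global cutoff; with
#'   a `catalog` it draws a Manhattan-style plot instead.
#' @param object An `fst_scan` object.
#' @param catalog Optional SV catalog for genomic positions.
#' @export
autoplot.fst_scan <- function(object, catalog = NULL, ...) {
  res <- dplyr::filter(object$results, !.data$excluded_monomorphic)
  if (!is.null(catalog)) {
    df <- dplyr::inner_join(res, catalog, by = "sv_id")
    return(
      ggplot(df, aes(x = .data$start, y = .data$theta,
                     colour = .data$outlier)) +
        geom_point(size = 0.7) +
        geom_vline(xintercept = numeric(0)) +
        facet_wrap(~chrom, nrow = 1, scales = "free_x") +
        labs(x = "position (bp)", y = expression(theta),
             colour = "outlier") +
        theme_minimal()
    )
  }
  null_df <- tibble(theta = object$null_theta, which = "permuted")
  obs_df <- tibble(theta = res$theta, which = "observed")
  ggplot(dplyr::bind_rows(obs_df, null_df), aes(x = .data$theta)) +
    geom_histogram(bins = 80, fill = "grey30") +
    geom_vline(xintercept = object$global_cutoff, linetype = 2) +
    facet_wrap(~which, ncol = 1, scales = "free_y") +
    labs(x = expression(theta), y = "count") +
    theme_minimal()
}

#' @describeIn pca_dosage `autoplot()` draws PC1 vs PC2 sample scores,
#'   optionally coloured by a sample-table column.
#' @param object A `dosage_pca`.
#' @param samples Optional sample tibble joined on `sample_id`.
#' @param colour Column of `samples` to colour by (default `origin`).
#' @param ... Unused.
#' @export
autoplot.dosage_pca <- function(object, samples = NULL, colour = "origin", ...) {
  df <- object$scores
  p <- if (!is.null(samples)) {
    df <- dplyr::left_join(df, samples, by = "sample_id")
    ggplot(df, aes(x = .data$PC1, y = .data$PC2,
                   colour = .data[[colour]]))
  } else {
    ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  }
  p + geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    theme_minimal()
}

#' Plot validation concordance rates per SV type
#'
#' @param report Tibble from [concordance_report()].
#' @return A ggplot object.
#' @export
plot_concordance <- function(report) {
  df <- report |>
    tidyr::pivot_longer(c("presence_rate", "genotype_rate"),
                        names_to = "metric", values_to = "rate")
  ggplot(df, aes(x = .data$svtype, y = .data$rate, fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "concordance rate", fill = NULL) +
    theme_minimal()
}
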