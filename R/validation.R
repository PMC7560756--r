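#' Classify amplicon pileups into SV genotypes
#'
#' Applies the long-read validation rule set: a pileup with fewer than
#' `min_cov` total reads is a failed PCR (`FAIL`); otherwise, with allele
#' fractions computed over allele-assignable reads only (`f_alt =
#' n_alt/(n_alt+n_ref)`), a locus is `1/1` when `f_alt > hom_frac`, `0/0`
#' when the reference fraction exceeds `hom_frac`, and `0/1` when both
#' fractions are at least `het_frac`. The checks apply in that order
#' (coverage gate, homozygote rules with strict `>`, heterozygote rule with
#' `>=`), so a pileup with `f_alt` exactly 0.9 is heterozygous. A covered
#' pileup with no assignable reads fails with its own reason code.
#'
#' @param pileups Tibble with `n_total`, `n_alt`, `n_ref` columns (e.g. from
#'   [simulate_amplicon_pileups()]).
#' @param min_cov Coverage gate (default 50 reads).
#' @param hom_frac Homozygote fraction threshold (default 0.9, strict).
#' @param het_frac Heterozygote minimum fraction (default 0.1, inclusive).
#' @return The input tibble with `class_gt` (`0/0`, `0/1`, `1/1`, `FAIL`)
#'   and `fail_reason` (`NA`, `low_coverage` or `no_assignable_reads`).
#' @examples
#' p <- tibble::tibble(n_total = c(40, 100, 100, 100),
#'                     n_alt   = c(30,  95,  60,   2),
#'                     n_ref   = c(10,   5,  40,  98))
#' classify_amplicon(p)$class_gt  # FAIL, 1/1, 0/1, 0/0
#' @export
classify_amplicon <- function(pileups, min_cov = 50, hom_frac = 0.9,
                              het_frac = 0.1) {
  stopifnot(all(c("n_total", "n_alt", "n_ref") %in% names(pileups)))
  if (any(pileups$n_alt + pileups$n_ref > pileups$n_total, na.rm = TRUE)) {
    abort("n_alt + n_ref exceeds n_total in some pileups",
          class = "svpop_value_error")
  }
  assignable <- pileups$n_alt + pileups$n_ref
  f_alt <- ifelse(assignable > 0, pileups$n_alt / assignable, NA_real_)
  f_ref <- ifelse(assignable > 0, pileups$n_ref / assignable, NA_real_)
  class_gt <- rep(NA_character_, nrow(pileups))
  fail_reason <- rep(NA_character_, nrow(pileups))

  low <- pileups$n_total < min_cov
  class_gt[low] <- "FAIL"; fail_reason[low] <- "low_coverage"
  none <- !low & assignable == 0
  class_gt[none] <- "FAIL"; fail_reason[none] <- "no_assignable_reads"

  open <- is.na(class_gt)
  class_gt[open & f_alt > hom_frac] <- "1/1"
  open <- is.na(class_gt)
  class_gt[open & f_ref > hom_frac] <- "0/0"
  open <- is.na(class_gt)
  class_gt[open & f_alt >= het_frac & f_ref >= het_frac] <- "0/1"
  open <- is.na(class_gt)
  class_gt[open] <- "FAIL"; fail_reason[open] <- "unclassifiable"

  dplyr::mutate(pileups, class_gt = class_gt, fail_reason = fail_reason)
}

#' Presence/absence and genotype concordance of validated SV calls
#'
#' Compares pipeline genotype calls against amplicon-derived
#' classifications. Failed pileups are excluded from all denominators. A
#' call is presence-concordant when both sides agree on whether the SV
#' allele is present at all (at least one alternative allele), and
#' genotype-concordant on an exact diploid genotype match. Rates are
#' reported per SV type and pooled.
#'
#' @param classified Tibble with `called_gt`, `class_gt` and (optionally)
#'   `svtype` columns, e.g. [classify_amplicon()] output joined to a catalog.
#' @param catalog Optional SV catalog used to attach `svtype` via `sv_id`.
#' @return A tibble with one row per SV type plus an `overall` row:
#'   `svtype`, `n_calls`, `n_presence_concordant`, `n_genotype_concordant`,
#'   `presence_rate`, `genotype_rate`. With no usable calls the counts are
#'   zero and the rates `NA`.
#' @export
concordance_report <- function(classified, catalog = NULL) {
  if (!("svtype" %in% names(classified))) {
    if (is.null(catalog)) {
      abort("provide a `svtype` column or a `catalog` to join it from",
            class = "svpop_value_error")
    }
    classified <- dplyr::left_join(
      classified, dplyr::select(catalog, "sv_id", "svtype"), by = "sv_id")
  }
  usable <- dplyr::filter(classified, .data$class_gt != "FAIL",
                          !is.na(.data$called_gt))
  has_alt <- function(gt) gt %in% c("0/1", "1/1")
  usable <- dplyr::mutate(
    usable,
    presence_ok = has_alt(.data$called_gt) == has_alt(.data$class_gt),
    genotype_ok = .data$called_gt == .data$class_gt
  )
  summarise_rates <- function(df, label) {
    tibble(
      svtype = label,
      n_calls = nrow(df),
      n_presence_concordant = sum(df$presence_ok),
      n_genotype_concordant = sum(df$genotype_ok),
      presence_rate = if (nrow(df) > 0) sum(df$presence_ok) / nrow(df) else NA_real_,
      genotype_rate = if (nrow(df) > 0) sum(df$genotype_ok) / nrow(df) else NA_real_
    )
  }
  per_type <- usable |>
    dplyr::group_by(.data$svtype) |>
    dplyr::group_map(~ summarise_rates(.x, .y$svtype)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_type, summarise_rates(usable, "overall"))
}
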