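#' Flag genes overlapped by structural variants
#'
#' A gene is flagged when at least one SV (optionally restricted to one
#' type) shares at least one base with its interval; intervals are 0-based
#' half-open, so an SV ending where a gene starts does not overlap it.
#'
#' @param catalog SV catalog tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param svtype Optional single SV type (`"DEL"`, `"DUP"`, `"INV"`) filter.
#' @return A tibble `gene_id`, `sv_overlap` (logical).
#' @export
gene_overlap_flags <- function(catalog, genes, svtype = NULL) {
  if (!is.null(svtype)) {
    catalog <- dplyr::filter(catalog, .data$svtype == !!svtype)
  }
  hit <- if (nrow(catalog) == 0L || nrow(genes) == 0L) {
    rep(FALSE, nrow(genes))
  } else {
    IRanges::overlapsAny(as_granges0(genes), as_granges0(catalog))
  }
  tibble(gene_id = genes$gene_id, sv_overlap = hit)
}

#' Test SV-overlap enrichment in WGD-retained ohnologs
#'
#' Builds the 2x2 contingency table {ohnolog, singleton} x {SV-overlapped,
#' not} at the gene level and applies Fisher's exact test (two-sided,
#' conditional odds ratio). An odds ratio above 1 means duplicated genes
#' tolerate — and therefore accumulate — more structural variation than
#' singletons, the mutational-buffering signature expected after a
#' whole-genome duplication.
#'
#' @param flags Per-gene overlap flags from [gene_overlap_flags()] or
#'   [simulate_gene_overlap()] (`gene_id`, `sv_overlap`).
#' @param ohnologs Gene table with `gene_id` and `status`
#'   (`ohnolog`/`singleton`).
#' @return An object of class `enrichment_result`: list with `table` (2x2
#'   matrix), `odds_ratio`, `p_value`, `or_defined` (FALSE when a margin is
#'   zero) and `test` label. Supports [generics::tidy()].
#' @export
ohnolog_enrichment <- function(flags, ohnologs) {
  df <- dplyr::inner_join(dplyr::select(flags, "gene_id", "sv_overlap"),
                          dplyr::select(ohnologs, "gene_id", "status"),
                          by = "gene_id")
  if (nrow(df) < nrow(flags)) {
    abort("some flagged genes are absent from the ohnolog table",
          class = "svpop_value_error")
  }
  tab <- matrix(
    c(sum(df$status == "ohnolog" & df$sv_overlap),
      sum(df$status == "ohnolog" & !df$sv_overlap),
      sum(df$status == "singleton" & df$sv_overlap),
      sum(df$status == "singleton" & !df$sv_overlap)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("ohnolog", "singleton"), c("overlapped", "not_overlapped"))
  )
  enrichment_from_table(tab, "ohnolog SV-overlap enrichment (Fisher exact)")
}

enrichment_from_table <- function(tab, label) {
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  ft <- stats::fisher.test(tab)
  structure(
    list(table = tab,
         odds_ratio = if (zero_margin) NA_real_ else unname(ft$estimate),
         p_value = ft$p.value,
         or_defined = !zero_margin,
         test = label),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s\n", x$test))
  print(x$table)
  cat(sprintf("  odds ratio = %s, two-sided P = %.3g\n",
              if (x$or_defined) format(x$odds_ratio, digits = 4) else "undefined (zero margin)",
              x$p_value))
  invisible(x)
}

# per-row Spearman correlation between two gene x tissue matrices
row_spearman <- function(a, b) {
  ra <- t(apply(a, 1L, rank))
  rb <- t(apply(b, 1L, rank))
  ra <- ra - rowMeans(ra); rb <- rb - rowMeans(rb)
  num <- rowSums(ra * rb)
  den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Resampling test for ohnolog expression correlation
#'
#' Computes per-pair Spearman correlation of the two copies' expression
#' across tissues, takes the median over the pairs with an SV-overlapped
#' member, and compares it with medians of `n_resample` randomly sampled
#' ohnolog pair sets of the same size. The empirical P is the proportion of
#' resampled medians strictly lower than the observed one, so a small P
#' means SV-overlapped pairs are unusually weakly correlated.
#'
#' @param ohnologs Gene table from [simulate_ohnolog_table()] (or the same
#'   columns: `gene_id`, `partner_id`).
#' @param expr Expression tibble (`gene_id` + >= 3 tissue columns).
#' @param sv_genes Character vector of SV-overlapped gene ids; a pair is
#'   selected when at least one member is in this set.
#' @param n_resample Number of random same-size pair sets (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @return An object of class `resample_test`: `observed_median`,
#'   `null_medians`, `p_value`, `n_selected`, `n_pairs`, `n_resample`.
#' @export
expression_correlation_resample <- function(ohnologs, expr, sv_genes,
                                            n_resample = 1000, seed = 1L) {
  tissues <- setdiff(names(expr), "gene_id")
  if (length(tissues) < 3L) {
    abort("need >= 3 tissues for correlation", class = "svpop_value_error")
  }
  pairs <- ohnologs |>
    dplyr::filter(!is.na(.data$partner_id), .data$gene_id < .data$partner_id)
  em <- as.matrix(expr[, tissues, drop = FALSE])
  rownames(em) <- expr$gene_id
  a <- em[pairs$gene_id, , drop = FALSE]
  b <- em[pairs$partner_id, , drop = FALSE]
  rho <- row_spearman(a, b)
  if (anyNA(rho)) {
    warn(sprintf("dropped %d pair(s) with constant expression in a member",
                 sum(is.na(rho))))
    pairs <- pairs[!is.na(rho), , drop = FALSE]
    rho <- rho[!is.na(rho)]
  }
  selected <- pairs$gene_id %in% sv_genes | pairs$partner_id %in% sv_genes
  if (sum(selected) < 2L) {
    abort("need >= 2 selected pairs", class = "svpop_value_error")
  }
  observed <- stats::median(rho[selected])
  k <- sum(selected)
  null_medians <- with_substream(seed, "expr_resample", {
    vapply(seq_len(n_resample),
           function(i) stats::median(rho[sample(length(rho), k)]),
           numeric(1))
  })
  structure(
    list(observed_median = observed, null_medians = null_medians,
         p_value = sum(null_medians < observed) / n_resample,
         n_selected = k, n_pairs = length(rho), n_resample = n_resample),
    class = "resample_test"
  )
}

#' @export
print.resample_test <- function(x, ...) {
  cat(sprintf(
    "<resample_test> observed median Spearman = %.3f over %d pairs\n",
    x$observed_median, x$n_selected))
  cat(sprintf("  empirical P (null medians < observed) = %.4g (%d resamples of %d pairs)\n",
              x$p_value, x$n_resample, x$n_pairs))
  invisible(x)
}

#' Wilcoxon tests of expression level by SV-overlap status
#'
#' Works on each gene's summed log10 abundance across tissues (a
#' `pseudocount` is added before the log so all-zero tissues are defined).
#' Two rank-sum comparisons are run: (i) within ohnolog pairs discordant
#' for SV overlap, the overlapped copies against their non-overlapped
#' partners; (ii) genes in pairs with at least one overlapped member
#' against genes in pairs with none. P values are exact (enumeration) when
#' both groups have at most 10 untied observations, otherwise the normal
#' approximation is used.
#'
#' @param ohnologs Gene table (`gene_id`, `partner_id`).
#' @param expr Expression tibble (`gene_id` + tissue columns).
#' @param flags Per-gene overlap flags (`gene_id`, `sv_overlap`).
#' @param pseudocount Added to abundance before log10 (default 1e-3).
#' @return A tibble with one row per test: `test`, `n_x`, `n_y`,
#'   `statistic`, `p_value`, `note` (reason when a test is skipped).
#' @export
expression_level_tests <- function(ohnologs, expr, flags, pseudocount = 1e-3) {
  tissues <- setdiff(names(expr), "gene_id")
  sumlog <- rowSums(log10(as.matrix(expr[, tissues, drop = FALSE]) + pseudocount))
  names(sumlog) <- expr$gene_id
  ov <- stats::setNames(flags$sv_overlap, flags$gene_id)

  pairs <- ohnologs |>
    dplyr::filter(!is.na(.data$partner_id), .data$gene_id < .data$partner_id) |>
    dplyr::mutate(ov_a = unname(ov[.data$gene_id]) %in% TRUE,
                  ov_b = unname(ov[.data$partner_id]) %in% TRUE)

  # (i) discordant pairs: overlapped copy vs its partner
  disc <- dplyr::filter(pairs, xor(.data$ov_a, .data$ov_b))
  x1 <- sumlog[ifelse(disc$ov_a, disc$gene_id, disc$partner_id)]
  y1 <- sumlog[ifelse(disc$ov_a, disc$partner_id, disc$gene_id)]
  t1 <- run_wilcox(x1, y1, "overlapped_copy_vs_partner")

  # (ii) genes in overlapped pairs vs genes in untouched pairs
  hit_pairs <- pairs$ov_a | pairs$ov_b
  genes_hit <- c(pairs$gene_id[hit_pairs], pairs$partner_id[hit_pairs])
  genes_clean <- c(pairs$gene_id[!hit_pairs], pairs$partner_id[!hit_pairs])
  t2 <- run_wilcox(sumlog[genes_hit], sumlog[genes_clean],
                   "overlapped_pairs_vs_clean_pairs")
  dplyr::bind_rows(t1, t2)
}

run_wilcox <- function(x, y, label) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    return(tibble(test = label, n_x = length(x), n_y = length(y),
                  statistic = NA_real_, p_value = NA_real_,
                  note = "skipped: empty group"))
  }
  no_ties <- !any(duplicated(c(x, y)))
  use_exact <- length(x) <= 10L && length(y) <= 10L && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  tibble(test = label, n_x = length(x), n_y = length(y),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         note = if (use_exact) "exact" else "normal approximation")
}
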