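#' Tissue-specificity index from an expression matrix
#'
#' For each gene, the specificity index of a tissue is that tissue's share
#' of the gene's total across-tissue abundance, `CPM(g,t) / sum_t CPM(g,t)`,
#' bounded in `[0, 1]` and summing to 1 across tissues. Genes whose total
#' abundance is below `min_total` (default 1 CPM) are flagged filtered and
#' carry no indices; an all-zero gene never divides by zero.
#'
#' @param expr Expression tibble (`gene_id` + one abundance column per
#'   tissue, all values >= 0).
#' @param min_total Total-abundance filter threshold (default 1.0).
#' @return A tibble `gene_id`, `total`, `filtered`, plus one specificity
#'   column per tissue (`NA` for filtered genes).
#' @export
tissue_specificity <- function(expr, min_total = 1.0) {
  tissues <- setdiff(names(expr), "gene_id")
  m <- as.matrix(expr[, tissues, drop = FALSE])
  if (any(m < 0)) abort("expression must be non-negative",
                        class = "svpop_value_error")
  total <- rowSums(m)
  filtered <- total < min_total
  spec <- m / ifelse(total > 0, total, NA_real_)
  spec[filtered, ] <- NA_real_
  dplyr::bind_cols(
    tibble(gene_id = expr$gene_id, total = total, filtered = filtered),
    as_tibble(spec)
  )
}

#' Tissue-specificity and expression-level enrichment of a gene subset
#'
#' Asks whether a gene subset (e.g. genes linked to F(ST) outlier SVs) is
#' enriched for genes specific to one tissue, and whether its expression
#' level in that tissue differs from the transcriptome-wide expectation.
#' The enrichment is an upper-tail hypergeometric test: with `K` of `N`
#' retained genes having specificity `>= threshold` in `tissue` and `k` of
#' the `n`-gene subset, `P = P(X >= k)`. The level comparison is a Welch
#' two-sample t-test of the subset's tissue abundance against all retained
#' genes.
#'
#' @param subset_genes Character vector of gene ids (a subset of the
#'   retained transcriptome).
#' @param spec Specificity table from [tissue_specificity()].
#' @param expr Expression tibble used for the level test.
#' @param tissue Tissue column name (default `"brain"`).
#' @param threshold Specificity cutoff (default 0.5).
#' @return A list with `hypergeometric` (tibble `N`, `K`, `n`, `k`,
#'   `p_value`) and `t_test` (tibble `mean_subset`, `mean_population`,
#'   `statistic`, `p_value`), or a `skipped` reason when the subset is
#'   empty after filtering.
#' @export
brain_enrichment_tests <- function(subset_genes, spec, expr,
                                   tissue = "brain", threshold = 0.5) {
  retained <- dplyr::filter(spec, !.data$filtered)
  subset <- intersect(subset_genes, retained$gene_id)
  if (length(subset) == 0L) {
    return(list(skipped = "subset empty after abundance filtering"))
  }
  specific <- retained$gene_id[retained[[tissue]] >= threshold]
  N <- nrow(retained)
  K <- length(specific)
  n <- length(subset)
  k <- sum(subset %in% specific)
  p_hyper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)

  tissues_cpm <- stats::setNames(expr[[tissue]], expr$gene_id)
  x <- tissues_cpm[subset]
  y <- tissues_cpm[retained$gene_id]
  tt <- stats::t.test(x, y)
  list(
    hypergeometric = tibble(N = N, K = K, n = n, k = k, p_value = p_hyper),
    t_test = tibble(mean_subset = unname(tt$estimate[1]),
                    mean_population = unname(tt$estimate[2]),
                    statistic = unname(tt$statistic),
                    p_value = tt$p.value)
  )
}

#' Test whether outlier SVs preferentially overlap open-chromatin peaks
#'
#' Peaks are first assigned to genes: a peak is kept when it lies within
#' `flank` bp of a gene span (overlapping the span extended by `flank` on
#' both sides). Each SV is then flagged for >= 1 bp overlap with any
#' gene-assigned peak, and the {outlier, non-outlier} x {peak-overlapping,
#' not} table is tested with Fisher's exact test.
#'
#' @param outliers,non_outliers SV catalog tibbles for the two classes.
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param flank Gene-assignment window in bp (default 3000).
#' @return An `enrichment_result` with an extra `proportions` element
#'   (per-class fraction of peak-overlapping SVs), or a list with a
#'   `skipped` reason when no peak is gene-assigned.
#' @export
atac_overlap_test <- function(outliers, non_outliers, peaks, genes,
                              flank = 3000) {
  assigned <- assign_peaks_to_genes(peaks, genes, flank)
  if (nrow(assigned) == 0L) {
    return(list(skipped = "no gene-assigned peaks"))
  }
  pk <- as_granges0(assigned)
  hit_out <- IRanges::overlapsAny(as_granges0(outliers), pk)
  hit_non <- IRanges::overlapsAny(as_granges0(non_outliers), pk)
  tab <- matrix(
    c(sum(hit_out), sum(!hit_out), sum(hit_non), sum(!hit_non)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("outlier", "non_outlier"), c("peak", "no_peak"))
  )
  res <- enrichment_from_table(tab, "outlier SV x ATAC-peak overlap (Fisher exact)")
  res$proportions <- c(outlier = mean(hit_out), non_outlier = mean(hit_non))
  res
}

assign_peaks_to_genes <- function(peaks, genes, flank) {
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(peaks[0, ])
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start + 1L - flank), genes$end + flank)
  )
  hit <- IRanges::overlapsAny(as_granges0(peaks), gene_gr)
  peaks[hit, , drop = FALSE]
}

#' Link SVs to nearby genes
#'
#' Links every SV to each gene whose span, extended by `flank` bp on both
#' sides, intersects it. Links record the gap distance: 0 for any body
#' overlap (or direct adjacency), otherwise the number of bases between SV
#' and gene.
#'
#' @param catalog SV catalog tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param flank Linking window in bp (default 5000).
#' @return A tibble `sv_id`, `gene_id`, `distance`.
#' @export
link_svs_to_genes <- function(catalog, genes, flank = 5000) {
  if (nrow(catalog) == 0L || nrow(genes) == 0L) {
    return(tibble(sv_id = character(), gene_id = character(),
                  distance = integer()))
  }
  sv_gr <- as_granges0(catalog)
  gene_gr <- as_granges0(genes)
  hits <- GenomicRanges::findOverlaps(sv_gr, gene_gr, maxgap = flank - 1L)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(sv_gr[q], gene_gr[s])
  tibble(sv_id = catalog$sv_id[q], gene_id = genes$gene_id[s],
         distance = as.integer(dist))
}
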