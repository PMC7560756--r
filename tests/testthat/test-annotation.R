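expr_tbl <- function(m, genes = sprintf("g%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% c("brain", "liver", "muscle")[seq_len(ncol(m))]
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

test_that("tissue specificity normalizes, filters, and never divides by zero", {
  ex <- expr_tbl(rbind(c(9, 1, 0),
                       c(2, 2, 2),
                       c(0.2, 0.2, 0.1),
                       c(0, 0, 0)))
  spec <- tissue_specificity(ex)
  expect_equal(spec$brain[1], 0.9)
  expect_equal(spec$liver[1], 0.1)
  expect_equal(unlist(spec[2, c("brain", "liver", "muscle")]),
               rep(1 / 3, 3), ignore_attr = TRUE)
  expect_true(spec$filtered[3])   # total 0.5 < 1
  expect_true(spec$filtered[4])   # all-zero
  expect_true(all(is.na(spec$brain[3:4])))
  # retained rows sum to 1
  retained <- spec[!spec$filtered, c("brain", "liver", "muscle")]
  expect_equal(rowSums(as.matrix(retained)), rep(1, nrow(retained)),
               tolerance = 1e-9)
  expect_error(tissue_specificity(expr_tbl(matrix(-1, 1, 3))),
               class = "svpop_value_error")
})

test_that("hypergeometric enrichment matches exhaustive subset enumeration", {
  # N = 10, K = 4, n = 5, k = 4 -> P(X >= 4) = 6/252
  m <- matrix(1, 10, 3)
  m[1:4, 1] <- 10   # 4 genes brain-specific (index 0.833)
  spec <- tissue_specificity(expr_tbl(m))
  res <- brain_enrichment_tests(sprintf("g%02d", c(1:4, 10)), spec,
                                expr_tbl(m))
  expect_equal(res$hypergeometric$k, 4)
  expect_equal(res$hypergeometric$p_value, 6 / 252, tolerance = 1e-12)
  expect_equal(res$hypergeometric$p_value,
               oracle_hyper_upper(10, 4, 5, 4), tolerance = 1e-12)

  # subset = population -> k = K, P = 1
  res_all <- brain_enrichment_tests(sprintf("g%02d", 1:10), spec, expr_tbl(m))
  expect_equal(res_all$hypergeometric$p_value, 1)

  # empty subset skipped with reason
  skip_res <- brain_enrichment_tests(character(), spec, expr_tbl(m))
  expect_match(skip_res$skipped, "empty")

  # upper-tail P agrees with enumeration across all N <= 12 configurations
  for (N in 3:12) {
    for (K in 1:(N - 1)) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       oracle_hyper_upper(N, K, n, k), tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("planted brain-specific outlier genes are detected", {
  withr::with_seed(79, {
    n_genes <- 3000
    m <- matrix(stats::rgamma(n_genes * 10, 2, 1), n_genes, 10)
    colnames(m) <- c("brain", paste0("t", 2:10))
    outlier_genes <- sprintf("g%04d", 1:300)
    planted <- sample(300, 120)
    m[planted, "brain"] <- m[planted, "brain"] * 30
    ex <- dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes))),
      tibble::as_tibble(m))
    spec <- tissue_specificity(ex)
    res <- brain_enrichment_tests(outlier_genes, spec, ex)
    expect_lt(res$hypergeometric$p_value, 0.01)
    expect_lt(res$t_test$p_value, 0.01)
    expect_gt(res$t_test$mean_subset, res$t_test$mean_population)
  })
})

test_that("peak assignment and ATAC overlap test follow the interval rules", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 5100L, end = 9000L)
  peaks <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5200L)
  far_peaks <- tibble::tibble(chrom = "chr1", start = 20000L, end = 20200L)
  outliers <- make_catalog(5150, 5400)
  non_out <- make_catalog(c(8000, 12000), c(8100, 12100))

  res <- atac_overlap_test(outliers, non_out, peaks, genes, flank = 3000)
  expect_equal(unname(res$proportions["outlier"]), 1)
  expect_equal(unname(res$proportions["non_outlier"]), 0)

  # a peak outside gene +/- flank is not assigned -> test skipped
  skip_res <- atac_overlap_test(outliers, non_out, far_peaks, genes, flank = 3000)
  expect_match(skip_res$skipped, "no gene-assigned")

  # identical proportions: OR = 1, P = 1
  res_null <- atac_overlap_test(
    make_catalog(c(5150, 12000), c(5400, 12100)),
    make_catalog(c(5160, 13000), c(5410, 13100)),
    peaks, genes, flank = 3000)
  expect_equal(res_null$p_value, 1)
  expect_equal(res_null$odds_ratio, 1, tolerance = 1e-6)

  # label-swap symmetry: P unchanged, OR inverted
  a <- make_catalog(c(5150, 12000, 13000), c(5400, 12100, 13100))
  b <- make_catalog(c(5160, 14000), c(5410, 14100))
  r1 <- atac_overlap_test(a, b, peaks, genes, 3000)
  r2 <- atac_overlap_test(b, a, peaks, genes, 3000)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-6)
})

test_that("planted peak enrichment among outliers is recovered", {
  cfg <- sim_config(n_ohnolog_pairs = 400, n_singletons = 200, seed = 83)
  oh <- simulate_ohnolog_table(cfg)
  withr::with_seed(87, {
    # outlier SVs sit on genes with enriched peak probability
    outlier_genes <- sample(oh$gene_id, 150)
    peaks <- simulate_atac_peaks(oh, cfg, p_peak = 0.1,
                                 enriched_genes = outlier_genes,
                                 p_enriched = 0.7)
    g <- oh[match(outlier_genes, oh$gene_id), ]
    outliers <- tibble::tibble(
      sv_id = sprintf("out%03d", seq_along(outlier_genes)),
      chrom = g$chrom, start = g$start, end = g$start + 200L,
      svtype = "DEL", size = 200L)
    other <- oh[!(oh$gene_id %in% outlier_genes), ]
    non_idx <- sample(nrow(other), 300)
    non_out <- tibble::tibble(
      sv_id = sprintf("non%03d", seq_len(300)),
      chrom = other$chrom[non_idx],
      start = pmax(0L, other$start[non_idx] - 10000L),
      end = pmax(0L, other$start[non_idx] - 10000L) + 200L,
      svtype = "DEL", size = 200L)
    res <- atac_overlap_test(outliers, non_out, peaks, oh, flank = 3000)
    expect_gt(res$odds_ratio, 1)
    expect_lt(res$p_value, 0.05)
  })
})

test_that("SV-gene linkage respects the flank window and gap distance", {
  genes <- tibble::tibble(gene_id = c("near", "far", "spanned"),
                          chrom = "chr1",
                          start = c(300L, 100000L, 120L),
                          end = c(800L, 101000L, 180L))
  cat <- make_catalog(100, 200)
  links <- link_svs_to_genes(cat, genes, flank = 5000)
  expect_setequal(links$gene_id, c("near", "spanned"))
  expect_equal(links$distance[links$gene_id == "near"], 100L)
  expect_equal(links$distance[links$gene_id == "spanned"], 0L)

  # flank boundary: gap of exactly `flank` is out of range (half-open spans)
  edge_genes <- tibble::tibble(gene_id = c("at", "in"), chrom = "chr1",
                               start = c(5200L, 5199L), end = c(6000L, 6000L))
  edge <- link_svs_to_genes(cat, edge_genes, flank = 5000)
  expect_equal(edge$gene_id, "in")
})
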