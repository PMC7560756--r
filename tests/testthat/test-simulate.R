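test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(spike_fraction = 1.5), "spike_fraction",
               class = "svpop_config_error")
  expect_error(sim_config(n_wild = -1), "n_wild", class = "svpop_config_error")
  expect_error(sim_config(latitudes = c(1, 2)), "latitudes",
               class = "svpop_config_error")
  expect_error(sim_config(n_tissues = 2), "n_tissues",
               class = "svpop_config_error")
  expect_error(sim_config(genome = c(10, 20)), "genome",
               class = "svpop_config_error")
})

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_wild = 30, n_farmed = 10, n_populations = 2,
         n_sv = c(DEL = 80, DUP = 10, INV = 5),
         n_ohnolog_pairs = 60, n_singletons = 50,
         n_amplicons = 100, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("identical config and seed give bit-identical outputs", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_coverage(small_cfg(), n_samples = 20)$depth,
                   simulate_coverage(small_cfg(), n_samples = 20)$depth)
})

test_that("degenerate and count-conservation contracts hold", {
  empty <- simulate_cohort(small_cfg(n_sv = c(DEL = 0, DUP = 0, INV = 0)))
  expect_equal(nrow(empty$genotypes), 0)
  expect_equal(nrow(empty$truth$sv), 0)

  co <- simulate_cohort(small_cfg())
  expect_equal(nrow(co$genotypes), nrow(co$catalog))
  expect_equal(ncol(co$genotypes) - 1L, 40)
  expect_setequal(co$genotypes$sv_id, co$catalog$sv_id)
  expect_equal(sum(co$catalog$svtype == "INV"), 5)
  # planted outliers are a subset of the simulated (true) SVs
  expect_true(all(co$truth$sv$planted_outlier <= co$truth$sv$true_call))
})

test_that("deletion size spike obeys the boundary configs", {
  all_spike <- simulate_sv_catalog(small_cfg(spike_fraction = 1))
  dels <- dplyr::filter(all_spike, svtype == "DEL")
  expect_true(all(dels$size >= 1432 & dels$size <= 1436))

  no_spike <- simulate_sv_catalog(
    sim_config(n_sv = c(DEL = 10000, DUP = 0, INV = 0), spike_fraction = 0,
               genome = c(chr1 = 5e7), seed = 3))
  # chi-square on binned sizes: spike bin vs flanking bins of equal width
  spike <- sum(no_spike$size >= 1432 & no_spike$size <= 1436)
  left <- sum(no_spike$size >= 1427 & no_spike$size <= 1431)
  right <- sum(no_spike$size >= 1437 & no_spike$size <= 1441)
  p <- stats::chisq.test(c(left, spike, right))$p.value
  expect_gt(p, 0.01)

  with_spike <- simulate_sv_catalog(
    sim_config(n_sv = c(DEL = 10000, DUP = 0, INV = 0), spike_fraction = 0.05,
               genome = c(chr1 = 5e7), seed = 3))
  expect_gt(mean(with_spike$size >= 1432 & with_spike$size <= 1436), 0.04)
})

test_that("SVs always lie within chromosome bounds", {
  cfg <- small_cfg(genome = c(tiny = 2e4, chrA = 3e6))
  cat <- suppressWarnings(simulate_sv_catalog(cfg))
  lens <- cfg$genome[cat$chrom]
  expect_true(all(cat$start >= 0))
  expect_true(all(cat$end <= lens))
})

test_that("coverage simulation plants detectable high-depth regions", {
  cfg <- small_cfg(genome = c(chr1 = 1e5), window = 1000,
                   depth_mean = 8, depth_high = 150,
                   n_complex_regions = 2, n_high_samples = 15)
  cov <- simulate_coverage(cfg, n_samples = 20)
  regions <- find_high_depth_regions(cov, depth_threshold = 100,
                                     sample_threshold = 10)
  # every planted region is recovered
  expect_true(all(vapply(seq_len(nrow(cov$truth_regions)), function(i) {
    any(regions$chrom == cov$truth_regions$chrom[i] &
          regions$start <= cov$truth_regions$start[i] &
          regions$end >= cov$truth_regions$end[i])
  }, logical(1))))

  # background-only profile: P(depth >= 100 | Poisson mean 8) ~ 0, so empty
  cfg0 <- small_cfg(genome = c(chr1 = 1e5), n_complex_regions = 0,
                    depth_mean = 8)
  cov0 <- simulate_coverage(cfg0, n_samples = 20)
  expect_equal(nrow(find_high_depth_regions(cov0, 100, 10)), 0)
  expect_error(simulate_coverage(small_cfg(genome = c(chr1 = 500), window = 1000)),
               "window", class = "svpop_config_error")
})

test_that("curation labels follow region-dependent false-call rates", {
  cat <- make_catalog(seq(0, 99990, by = 10000),
                      seq(100, 100090, by = 10000))
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 50000L)
  cfg <- small_cfg(fdr_complex = 1, fdr_normal = 0)
  labs <- simulate_curation_labels(cat, regions, cfg)
  expect_true(all(labs$label[labs$region_class == "complex"] %in% c("no", "maybe")))
  expect_true(all(labs$label[labs$region_class == "normal"] == "yes"))

  # empty regions: only fdr_normal applies
  none <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  labs0 <- simulate_curation_labels(cat, none, small_cfg(fdr_normal = 0))
  expect_true(all(labs0$label == "yes"))

  # binomial recovery of fdr_normal over 10,000 calls
  big <- make_catalog(seq_len(10000) * 300L, seq_len(10000) * 300L + 100L)
  labs1 <- simulate_curation_labels(big, none, sim_config(fdr_normal = 0.85, seed = 5))
  est <- estimate_fdr(labs1)$fdr[estimate_fdr(labs1)$stratum == "overall"]
  expect_lt(abs(est - 0.85), 0.011)
})

test_that("amplicon pileups reflect genotype and error model", {
  dos <- matrix(rep(c(0L, 1L, 2L), each = 20), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  geno <- geno_from_dosage(dos)
  cfg <- small_cfg(amplicon_error = 0, amplicon_dropout = 0,
                   amplicon_unassigned = 0, n_amplicons = 60)
  p <- simulate_amplicon_pileups(geno, cfg)
  hom_alt <- dplyr::filter(p, true_gt == "1/1")
  expect_true(all(hom_alt$n_alt == hom_alt$n_total))
  hom_ref <- dplyr::filter(p, true_gt == "0/0")
  expect_true(all(hom_ref$n_alt == 0))
  het <- dplyr::filter(p, true_gt == "0/1")
  f <- sum(het$n_alt) / sum(het$n_alt + het$n_ref)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / sum(het$n_total)) + 0.02)

  # dropout plants sub-threshold pileups that will FAIL the coverage gate
  pd <- simulate_amplicon_pileups(geno, small_cfg(amplicon_dropout = 0.5,
                                                  n_amplicons = 60))
  expect_gt(sum(pd$n_total < 50), 0)
})

test_that("expression generator hits correlation and effect targets", {
  cfg <- small_cfg()
  oh <- simulate_ohnolog_table(cfg)
  no_overlap <- tibble::tibble(gene_id = oh$gene_id, sv_overlap = FALSE)

  # expr_rho = 1, no SV noise: pair members identical up to the copula scale
  ex1 <- simulate_expression(oh, no_overlap, small_cfg(expr_rho = 1))
  pairs <- dplyr::filter(oh, !is.na(partner_id), gene_id < partner_id)
  tis <- setdiff(names(ex1), "gene_id")
  em <- as.matrix(ex1[, tis]); rownames(em) <- ex1$gene_id
  rho <- suppressWarnings(
    vapply(seq_len(nrow(pairs)), function(i) {
      stats::cor(em[pairs$gene_id[i], ], em[pairs$partner_id[i], ],
                 method = "spearman")
    }, numeric(1)))
  expect_equal(rho, rep(1, length(rho)), tolerance = 1e-12)

  expect_error(simulate_expression(oh, no_overlap, small_cfg(n_tissues = 2)),
               class = "svpop_config_error")

  # expr_sv_effect = 0.5: overlapped copies average half their partners
  cfg2 <- sim_config(n_ohnolog_pairs = 2000, n_singletons = 100, seed = 8,
                     expr_sv_effect = 0.5)
  oh2 <- simulate_ohnolog_table(cfg2)
  ovl2 <- simulate_gene_overlap(oh2, cfg2)
  ex2 <- simulate_expression(oh2, ovl2, cfg2)
  em2 <- as.matrix(ex2[, setdiff(names(ex2), "gene_id")])
  rownames(em2) <- ex2$gene_id
  pr2 <- dplyr::filter(oh2, !is.na(partner_id), gene_id < partner_id)
  ov <- stats::setNames(ovl2$sv_overlap, ovl2$gene_id)
  disc <- dplyr::filter(pr2, xor(ov[gene_id], ov[partner_id]))
  hit <- ifelse(ov[disc$gene_id], disc$gene_id, disc$partner_id)
  part <- ifelse(ov[disc$gene_id], disc$partner_id, disc$gene_id)
  ratio <- mean(rowSums(em2[hit, ])) / mean(rowSums(em2[part, ]))
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("ohnolog table respects pair/singleton structure", {
  oh <- simulate_ohnolog_table(small_cfg())
  expect_equal(sum(oh$status == "ohnolog"), 120)
  expect_equal(sum(oh$status == "singleton"), 50)
  pairs <- dplyr::filter(oh, status == "ohnolog")
  expect_identical(oh$gene_id[match(pairs$partner_id, oh$gene_id)],
                   pairs$partner_id)
  # partnership is symmetric
  back <- oh$partner_id[match(pairs$partner_id, oh$gene_id)]
  expect_identical(back, pairs$gene_id)
  expect_true(all(oh$start < oh$end))
})
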