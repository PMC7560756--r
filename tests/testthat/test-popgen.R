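test_that("theta hits the analytic limits and exclusion rules", {
  grp <- rep(c("farmed", "wild"), each = 20)
  fixed <- c(rep("1/1", 20), rep("0/0", 20))
  expect_equal(wc_fst(fixed, grp)$theta, 1)

  mono <- rep("0/0", 40)
  res <- wc_fst(mono, grp)
  expect_true(res$excluded_monomorphic)
  expect_true(is.na(res$theta))

  # one group empty after missing-data removal: flagged, not an abort
  gt <- c(rep(NA_character_, 20), rep("0/1", 20))
  res2 <- wc_fst(gt, grp)
  expect_true(res2$empty_group)
  expect_true(is.na(res2$theta))

  expect_error(wc_fst(fixed, rep("one", 40)), class = "svpop_value_error")
})

test_that("theta agrees with the hand variance-component oracle to 1e-10", {
  withr::with_seed(31, {
    for (i in 1:60) {
      n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
      gt <- sample(c("0/0", "0/1", "1/1"), n1 + n2, replace = TRUE,
                   prob = stats::runif(3))
      if (i %% 4 == 0) gt[sample(length(gt), 3)] <- NA
      grp <- rep(c("g1", "g2"), c(n1, n2))
      expected <- oracle_wc_theta(gt, grp)
      got <- wc_fst(gt, grp)
      if (is.na(expected)) {
        expect_true(got$excluded_monomorphic)
      } else {
        expect_equal(got$theta, expected, tolerance = 1e-10)
      }
      # vectorised path used by the permutation scan must agree too
      dos <- matrix(svpop:::gt_to_dosage(gt), nrow = 1)
      vec <- svpop:::wc_theta_rows(dos, grp == "g1")$theta
      if (!is.na(expected)) expect_equal(vec, expected, tolerance = 1e-10)
    }
  })
})

test_that("worked genotype-count example matches the oracle exactly", {
  # group1 (0/0:4, 0/1:4, 1/1:2), group2 (0/0:8, 0/1:2, 1/1:0)
  gt <- c(rep("0/0", 4), rep("0/1", 4), rep("1/1", 2),
          rep("0/0", 8), rep("0/1", 2))
  grp <- rep(c("g1", "g2"), each = 10)
  expect_equal(wc_fst(gt, grp)$theta, oracle_wc_theta(gt, grp),
               tolerance = 1e-10)
})

test_that("permutation P values live on the exceedance grid", {
  expect_equal(perm_pvalue(10, 200), 0.05)
  expect_equal(perm_pvalue(0, 200), 0)

  cfg <- sim_config(n_wild = 40, n_farmed = 12, n_populations = 2,
                    n_sv = c(DEL = 120, DUP = 0, INV = 0), seed = 17)
  co <- simulate_cohort(cfg)
  labs <- stats::setNames(co$samples$origin, co$samples$sample_id)
  scan <- fst_outlier_scan(co$genotypes, labs, n_perm = 50, seed = 23)
  res <- dplyr::filter(tidy(scan), !excluded_monomorphic)
  expect_identical(res$p_perm, res$n_exceed / 50)
  expect_true(all(res$n_exceed >= 0 & res$n_exceed <= 50))
  # observed theta above every permuted value -> P = 0 for at least the
  # most differentiated SVs in this strongly split design
  expect_gt(sum(res$p_perm == 0), 0)

  # determinism under a fixed seed
  scan2 <- fst_outlier_scan(co$genotypes, labs, n_perm = 50, seed = 23)
  expect_identical(tidy(scan), tidy(scan2))

  expect_error(fst_outlier_scan(co$genotypes, labs, n_perm = 0),
               class = "svpop_value_error")
})

test_that("exchangeable labels give approximately uniform permutation P", {
  cfg <- sim_config(n_wild = 80, n_farmed = 20, n_populations = 1,
                    divergence_F = c(lineage = 0, population = 0, farm = 0),
                    cline_slope = 0, n_planted_outliers = 0,
                    n_sv = c(DEL = 500, DUP = 0, INV = 0), seed = 19)
  co <- simulate_cohort(cfg)
  labs <- stats::setNames(co$samples$origin, co$samples$sample_id)
  scan <- fst_outlier_scan(co$genotypes, labs, n_perm = 100, seed = 29)
  res <- dplyr::filter(tidy(scan), !excluded_monomorphic)
  expect_lt(abs(mean(res$p_perm) - 0.5), 0.05)
  expect_lt(abs(mean(res$p_perm < 0.25) - 0.25), 0.06)
})

test_that("planted outliers are recovered and separate from the null", {
  cfg <- sim_config(n_wild = 150, n_farmed = 30, n_populations = 1,
                    divergence_F = c(lineage = 0, population = 0, farm = 0),
                    cline_slope = 0, n_planted_outliers = 25,
                    outlier_freq_shift = 0.35,
                    n_sv = c(DEL = 500, DUP = 0, INV = 0), seed = 37)
  co <- simulate_cohort(cfg)
  labs <- stats::setNames(co$samples$origin, co$samples$sample_id)
  scan <- fst_outlier_scan(co$genotypes, labs, n_perm = 100, seed = 41)
  res <- dplyr::inner_join(tidy(scan), co$truth$sv, by = "sv_id")
  planted <- dplyr::filter(res, planted_outlier)
  null <- dplyr::filter(res, !planted_outlier, !excluded_monomorphic)
  expect_gt(mean(planted$outlier), 0.8)
  expect_lt(mean(null$outlier), 0.02)
  expect_gt(median(planted$theta), median(null$theta, na.rm = TRUE))
})

test_that("dosage PCA separates planted lineages and obeys spectra", {
  cfg <- sim_config(n_wild = 60, n_farmed = 0, n_populations = 2,
                    divergence_F = c(lineage = 0.5, population = 0, farm = 0),
                    cline_slope = 0, missing_rate = 0,
                    n_sv = c(DEL = 300, DUP = 0, INV = 0), seed = 43)
  co <- simulate_cohort(cfg)
  dos <- recode_dosage(co$genotypes)
  pca <- suppressWarnings(pca_dosage(dos, n_components = 4))
  scores <- dplyr::inner_join(tidy(pca), co$samples, by = "sample_id")
  g1 <- scores$PC1[scores$lineage == "L1"]
  g2 <- scores$PC1[scores$lineage == "L2"]
  expect_true(max(min(g1), min(g2)) > min(max(g1), max(g2)) ||
                max(g1) < min(g2) || max(g2) < min(g1))

  # duplicated sample gets identical scores
  dup <- dos
  dup$dup_sample <- dup[[2]]
  pca2 <- suppressWarnings(pca_dosage(dup, n_components = 3))
  s <- tidy(pca2)
  expect_equal(unlist(s[s$sample_id == "dup_sample", -1]),
               unlist(s[s$sample_id == names(dos)[2], -1]),
               ignore_attr = TRUE)

  ev <- pca$explained
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-8)

  # constant columns dropped with warning
  dos_const <- dos
  dos_const[1, -1] <- 1
  expect_warning(pca_dosage(dos_const, 2), "constant")
})

test_that("multi-locus theta recovers Balding-Nichols divergence", {
  cfg <- sim_config(n_wild = 120, n_farmed = 0, n_populations = 2,
                    divergence_F = c(lineage = 0.15, population = 0, farm = 0),
                    cline_slope = 0, missing_rate = 0,
                    n_sv = c(DEL = 800, DUP = 0, INV = 0), seed = 47)
  co <- simulate_cohort(cfg)
  labs <- stats::setNames(co$samples$population, co$samples$sample_id)
  est <- wc_fst_global(co$genotypes, labs)
  expect_lt(abs(est - 0.15), 0.03)
})
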