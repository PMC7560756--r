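#' Weir-Cockerham F(ST) for a single bi-allelic site
#'
#' Computes the variance-component estimator theta for two groups from
#' diploid genotypes. With group sizes `n_i`, alternative-allele frequencies
#' `p_i` and heterozygote proportions `h_i`, the among-group (`a`),
#' between-individual (`b`) and within-individual (`c`) components are
#' combined as `theta = a / (a + b + c)`. Sites monomorphic across both
#' groups have a zero denominator and are flagged excluded rather than
#' returned as a number; theta may be negative (sampling noise around zero
#' differentiation) and is at most 1.
#'
#' @param gt Genotype vector: strings (`0/0`, `0/1`, `1/1`, `NA`) or integer
#'   dosages (0, 1, 2, `NA`). Missing genotypes are dropped pairwise.
#' @param labels Two-level grouping vector aligned with `gt`.
#' @return A list: `theta`, components `a`, `b`, `c`, per-group sizes `n`,
#'   and logical `excluded_monomorphic`.
#' @examples
#' gt <- c(rep("1/1", 20), rep("0/0", 20))
#' grp <- rep(c("farmed", "wild"), each = 20)
#' wc_fst(gt, grp)$theta  # fixed difference: theta = 1
#' @export
wc_fst <- function(gt, labels) {
  d <- if (is.character(gt)) gt_to_dosage(gt) else as.integer(gt)
  labels <- as.character(labels)
  stopifnot(length(d) == length(labels))
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) != 2L) {
    abort("`labels` must contain exactly two groups", class = "svpop_value_error")
  }
  keep <- !is.na(d) & !is.na(labels)
  d <- d[keep]; labels <- labels[keep]
  n <- vapply(groups, function(g) sum(labels == g), numeric(1))
  if (any(n == 0)) {
    return(list(theta = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
                n = n, excluded_monomorphic = FALSE, empty_group = TRUE))
  }
  p <- vapply(groups, function(g) mean(d[labels == g]) / 2, numeric(1))
  h <- vapply(groups, function(g) mean(d[labels == g] == 1L), numeric(1))
  comp <- wc_components(n, p, h)
  denom <- comp$a + comp$b + comp$c
  mono <- !is.finite(denom) || abs(denom) < 1e-12
  list(
    theta = if (mono) NA_real_ else comp$a / denom,
    a = comp$a, b = comp$b, c = comp$c, n = n,
    excluded_monomorphic = mono, empty_group = FALSE
  )
}

#' Permutation P value from exceedance counts
#'
#' The per-SV permutation P is the proportion of permuted values exceeding
#' the observed one: `n_exceed / n_perm`, so 10 exceedances in 200
#' permutations give P = 0.05. P values therefore live on the grid
#' `{0, 1/n_perm, ..., 1}`; zero means no permuted value exceeded the
#' observation.
#'
#' @param n_exceed Number of permuted statistics exceeding the observed one.
#' @param n_perm Number of permutations.
#' @return `n_exceed / n_perm`.
#' @examples
#' perm_pvalue(10, 200)
#' @export
perm_pvalue <- function(n_exceed, n_perm) {
  stopifnot(n_perm >= 1, all(n_exceed >= 0 | is.na(n_exceed)),
            all(n_exceed <= n_perm | is.na(n_exceed)))
  n_exceed / n_perm
}

# scalar variance components, r groups
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  list(a = a, b = b, c = hbar / 2)
}

# Vectorised theta over all rows of a dosage matrix (SVs x samples) for a
# logical group-1 indicator; missing genotypes excluded pairwise per SV.
# Returns list of numeric vectors theta and denom (a+b+c).
wc_theta_rows <- function(dos, in_g1, obs = NULL, het = NULL, dz = NULL) {
  obs <- obs %||% (!is.na(dos)) * 1
  het <- het %||% {
    hh <- (dos == 1L) * 1; hh[is.na(hh)] <- 0; hh
  }
  dz <- dz %||% {
    zz <- dos; zz[is.na(zz)] <- 0; zz
  }
  v1 <- as.numeric(in_g1); v2 <- 1 - v1
  n1 <- drop(obs %*% v1); n2 <- drop(obs %*% v2)
  p1 <- drop(dz %*% v1) / (2 * n1); p2 <- drop(dz %*% v2) / (2 * n2)
  h1 <- drop(het %*% v1) / n1;      h2 <- drop(het %*% v2) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- a / denom
  theta[!is.finite(denom) | abs(denom) < 1e-12] <- NA_real_
  list(theta = theta, denom = denom, empty = n1 == 0 | n2 == 0)
}

#' Multi-locus Weir-Cockerham F(ST)
#'
#' Combines loci the way the variance-component framework prescribes: the
#' among-group, between-individual and within-individual components are
#' summed over loci before the ratio is taken,
#' `theta = sum(a) / sum(a + b + c)`. Unlike the mean of per-locus ratios
#' (which is biased low by the ratio's nonlinearity), this form is
#' approximately unbiased, so under a Balding-Nichols model with
#' differentiation `F` it recovers `F`.
#'
#' @param genotypes Genotype tibble (`sv_id` + one column per sample).
#' @param labels Two-level grouping vector (sample-column order, or named by
#'   sample id).
#' @return A single numeric theta estimate.
#' @export
wc_fst_global <- function(genotypes, labels) {
  samples <- setdiff(names(genotypes), "sv_id")
  if (!is.null(names(labels))) labels <- labels[samples]
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) {
    abort("`labels` must contain exactly two groups", class = "svpop_value_error")
  }
  dos <- matrix(gt_to_dosage(as.matrix(genotypes[, samples, drop = FALSE])),
                nrow = nrow(genotypes))
  comp <- wc_theta_rows(dos, labels == groups[1L])
  keep <- is.finite(comp$theta)
  sum(comp$theta[keep] * comp$denom[keep]) / sum(comp$denom[keep])
}

#' Permutation F(ST) outlier scan between two groups
#'
#' Computes per-SV Weir-Cockerham theta for the observed grouping, then
#' randomly re-splits individuals into two sets of the original sizes
#' `n_perm` times, recomputing theta for every SV in every permutation. The
#' per-SV permutation P value is the fraction of permuted theta values
#' strictly greater than the observed one (so 10 exceedances in 200
#' permutations gives P = 0.05); with `exceed = "geq"` ties count as
#' exceedances instead. A single global cutoff is the `q` quantile of the
#' pooled permuted theta values, and an SV is called an outlier when
#' `p_perm < alpha` and its observed theta exceeds that cutoff. SVs
#' monomorphic across the two groups are excluded up front.
#'
#' @param genotypes Genotype tibble (`sv_id` + one column per sample).
#' @param labels Two-level grouping vector, either in sample-column order or
#'   named by sample id.
#' @param n_perm Number of random label permutations (default 200).
#' @param q Quantile of the pooled null used as the global theta cutoff
#'   (default 0.997).
#' @param alpha Per-SV permutation P threshold (default 0.01).
#' @param seed Integer seed; the permutation stream is independent of any
#'   simulation stream derived from the same seed.
#' @param exceed `"greater"` (strict, default) or `"geq"` for the tie rule.
#' @return An object of class `fst_scan`: list with `results` (tibble
#'   `sv_id`, `theta`, `n_exceed`, `p_perm`, `passes_cutoff`, `outlier`,
#'   `excluded_monomorphic`), `null_theta` (pooled permuted values),
#'   `global_cutoff`, and the scan parameters. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fst_outlier_scan <- function(genotypes, labels, n_perm = 200, q = 0.997,
                             alpha = 0.01, seed = 1L,
                             exceed = c("greater", "geq")) {
  exceed <- match.arg(exceed)
  if (n_perm < 1) abort("`n_perm` must be >= 1", class = "svpop_value_error")
  samples <- setdiff(names(genotypes), "sv_id")
  if (!is.null(names(labels))) labels <- labels[samples]
  labels <- as.character(labels)
  stopifnot(length(labels) == length(samples))
  groups <- sort(unique(labels))
  if (length(groups) != 2L) {
    abort("`labels` must contain exactly two groups", class = "svpop_value_error")
  }
  dos <- matrix(gt_to_dosage(as.matrix(genotypes[, samples, drop = FALSE])),
                nrow = nrow(genotypes),
                dimnames = list(genotypes$sv_id, samples))
  in_g1 <- labels == groups[1L]
  n1 <- sum(in_g1)

  obs_mask <- (!is.na(dos)) * 1
  het <- (dos == 1L) * 1; het[is.na(het)] <- 0
  dz <- dos; dz[is.na(dz)] <- 0

  alt_count <- rowSums(dz)
  total_alleles <- 2 * rowSums(obs_mask)
  monomorphic <- alt_count == 0 | alt_count == total_alleles
  obs <- wc_theta_rows(dos, in_g1, obs_mask, het, dz)
  excluded <- monomorphic | is.na(obs$theta)

  poly <- which(!excluded)
  theta_obs <- obs$theta
  n_exceed <- rep(NA_integer_, nrow(dos))
  null_theta <- numeric(0)
  if (length(poly) > 0L) {
    dos_p <- dos[poly, , drop = FALSE]
    obs_p <- obs_mask[poly, , drop = FALSE]
    het_p <- het[poly, , drop = FALSE]
    dz_p <- dz[poly, , drop = FALSE]
    exceed_cnt <- integer(length(poly))
    null_mat <- matrix(NA_real_, length(poly), n_perm)
    with_substream(seed, "fst_perm", {
      for (k in seq_len(n_perm)) {
        perm_g1 <- logical(length(labels))
        perm_g1[sample(length(labels), n1)] <- TRUE
        th <- wc_theta_rows(dos_p, perm_g1, obs_p, het_p, dz_p)$theta
        null_mat[, k] <- th
        hit <- if (exceed == "greater") th > theta_obs[poly] else th >= theta_obs[poly]
        exceed_cnt <- exceed_cnt + as.integer(!is.na(hit) & hit)
      }
    })
    n_exceed[poly] <- exceed_cnt
    null_theta <- as.numeric(null_mat[!is.na(null_mat)])
  }
  global_cutoff <- if (length(null_theta) > 0L) {
    as.numeric(stats::quantile(null_theta, q, names = FALSE))
  } else {
    NA_real_
  }
  p_perm <- perm_pvalue(n_exceed, n_perm)
  results <- tibble(
    sv_id = genotypes$sv_id,
    theta = ifelse(excluded, NA_real_, theta_obs),
    n_exceed = n_exceed,
    p_perm = p_perm,
    passes_cutoff = !excluded & !is.na(theta_obs) & theta_obs > global_cutoff,
    outlier = !excluded & !is.na(p_perm) & p_perm < alpha &
      !is.na(theta_obs) & theta_obs > global_cutoff,
    excluded_monomorphic = excluded
  )
  structure(
    list(results = results, null_theta = null_theta,
         global_cutoff = global_cutoff, n_perm = n_perm, q = q,
         alpha = alpha, seed = seed, exceed = exceed,
         groups = groups, group_sizes = c(n1, length(labels) - n1)),
    class = "fst_scan"
  )
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf(
    "<fst_scan> %d SVs (%d polymorphic), groups %s (n=%d) vs %s (n=%d)\n",
    nrow(x$results), sum(!x$results$excluded_monomorphic),
    x$groups[1], x$group_sizes[1], x$groups[2], x$group_sizes[2]))
  cat(sprintf("  %d permutations; global cutoff (q=%.3f): theta > %.4f\n",
              x$n_perm, x$q, x$global_cutoff))
  cat(sprintf("  outliers (p_perm < %.3g AND theta > cutoff): %d\n",
              x$alpha, sum(x$results$outlier, na.rm = TRUE)))
  invisible(x)
}

#' Principal component analysis of SV dosages
#'
#' Centres the samples-by-SV dosage matrix and runs [stats::prcomp()].
#' Constant (uninformative) SVs are dropped with a warning. Scores are
#' deterministic given the input up to the usual sign ambiguity.
#'
#' @param dosage Dosage tibble from [recode_dosage()] (`sv_id` + one numeric
#'   column per sample; missing values already imputed).
#' @param n_components Number of components to retain.
#' @return An object of class `dosage_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...) and `explained` (per-component fraction of
#'   variance, non-increasing, summing to at most 1).
#' @export
pca_dosage <- function(dosage, n_components = 10) {
  samples <- setdiff(names(dosage), "sv_id")
  if (length(samples) < 2L || nrow(dosage) < 2L) {
    abort("need >= 2 samples and >= 2 SVs", class = "svpop_value_error")
  }
  m <- t(as.matrix(dosage[, samples, drop = FALSE]))  # samples x SVs
  colnames(m) <- dosage$sv_id
  if (anyNA(m)) abort("dosage contains missing values; impute first",
                      class = "svpop_value_error")
  constant <- apply(m, 2L, function(x) max(x) == min(x))
  if (any(constant)) {
    warn(sprintf("dropped %d constant dosage column(s)", sum(constant)))
    m <- m[, !constant, drop = FALSE]
  }
  n_components <- min(n_components, nrow(m) - 1L, ncol(m))
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(m)), scores)
  structure(list(scores = scores, explained = explained[seq_len(n_components)]),
            class = "dosage_pca")
}

#' @export
print.dosage_pca <- function(x, ...) {
  cat(sprintf("<dosage_pca> %d samples, %d components (PC1 %.1f%% variance)\n",
              nrow(x$scores), length(x$explained), 100 * x$explained[1]))
  invisible(x)
}
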