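# Independent brute-force oracles. These re-derive expected results from
# first principles (per-base membership, exhaustive enumeration, direct
# transcription of the variance-component definitions) and deliberately
# share no code with the implementation paths they check.

# -- Weir-Cockerham theta, written as plain two-group sums ---------------
oracle_wc_theta <- function(gt, labels) {
  d <- ifelse(gt == "0/0", 0, ifelse(gt == "0/1", 1, ifelse(gt == "1/1", 2, NA)))
  ok <- !is.na(d)
  d <- d[ok]; labels <- labels[ok]
  gs <- sort(unique(labels))
  n1 <- sum(labels == gs[1]); n2 <- sum(labels == gs[2])
  p1 <- sum(d[labels == gs[1]]) / (2 * n1)
  p2 <- sum(d[labels == gs[2]]) / (2 * n2)
  h1 <- sum(d[labels == gs[1]] == 1) / n1
  h2 <- sum(d[labels == gs[2]] == 1) / n2
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
  if (abs(a + b + cc) < 1e-12) return(NA_real_)
  a / (a + b + cc)
}

# -- interval oracles (small coordinates only) ---------------------------
oracle_exclude <- function(catalog, regions) {
  hit <- vapply(seq_len(nrow(catalog)), function(i) {
    bases <- seq(catalog$start[i], catalog$end[i] - 1L)
    any(vapply(seq_len(nrow(regions)), function(j) {
      regions$chrom[j] == catalog$chrom[i] &&
        any(bases >= regions$start[j] & bases < regions$end[j])
    }, logical(1)))
  }, logical(1))
  hit
}

oracle_merge <- function(regions) {
  out <- list()
  for (ch in sort(unique(regions$chrom))) {
    sub <- regions[regions$chrom == ch, ]
    covered <- rep(FALSE, max(sub$end))
    for (j in seq_len(nrow(sub))) {
      covered[seq(sub$start[j] + 1L, sub$end[j])] <- TRUE  # 1-indexed base b+1
    }
    r <- rle(covered)
    pos <- cumsum(c(0L, r$lengths))
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = pos[k], end = pos[k + 1L])
    }
  }
  df <- do.call(rbind, out)
  tibble::as_tibble(df[order(df$chrom, df$start), ])
}

oracle_collapse_kept <- function(catalog, r) {
  n <- nrow(catalog)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (catalog$svtype[i] != catalog$svtype[j]) next
      if (catalog$chrom[i] != catalog$chrom[j]) next
      ov <- min(catalog$end[i], catalog$end[j]) -
        max(catalog$start[i], catalog$start[j])
      li <- catalog$end[i] - catalog$start[i]
      lj <- catalog$end[j] - catalog$start[j]
      if (ov >= r * li && ov >= r * lj) adj[i, j] <- TRUE
    }
  }
  # transitive closure by repeated expansion
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in which(adj[i, ])) {
        g <- min(group[i], group[j])
        if (group[i] != g || group[j] != g) {
          group[group == group[i] | group == group[j]] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  kept <- character()
  for (g in unique(group)) {
    idx <- which(group == g)
    o <- idx[order(catalog$start[idx], catalog$end[idx], catalog$sv_id[idx])][1]
    kept <- c(kept, catalog$sv_id[o])
  }
  sort(kept)
}

# -- exact-test oracles ---------------------------------------------------
oracle_hyper_upper <- function(N, K, n, k) {
  idx <- utils::combn(N, n)
  specific <- seq_len(K)   # label the first K items "specific"
  hits <- apply(idx, 2, function(s) sum(s %in% specific))
  mean(hits >= k)
}

oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, N - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_wilcox_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U
  idx <- utils::combn(nx + ny, nx)
  all_r <- rank(c(x, y))
  us <- apply(idx, 2, function(s) sum(all_r[s]) - nx * (nx + 1) / 2)
  pl <- mean(us <= w_obs); pu <- mean(us >= w_obs)
  min(1, 2 * min(pl, pu))
}

# -- fixture builders -----------------------------------------------------
make_catalog <- function(start, end, svtype = "DEL", chrom = "chr1") {
  tibble::tibble(
    sv_id = sprintf("sv%03d", seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    svtype = svtype, size = as.integer(end - start)
  )
}

random_catalog <- function(n, seed, max_pos = 5000L, max_size = 400L) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE)
    size <- sample.int(max_size, n, replace = TRUE)
    tibble::tibble(
      sv_id = sprintf("sv%03d", seq_len(n)),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = start, end = start + size,
      svtype = sample(c("DEL", "DUP", "INV"), n, replace = TRUE),
      size = size
    ) |> dplyr::arrange(chrom, start, end)
  })
}

# genotype tibble from a dosage matrix (SVs x samples)
geno_from_dosage <- function(dos) {
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- NA_character_
  colnames(gt) <- colnames(dos) %||% sprintf("s%03d", seq_len(ncol(dos)))
  dplyr::bind_cols(
    tibble::tibble(sv_id = rownames(dos) %||% sprintf("sv%03d", seq_len(nrow(dos)))),
    tibble::as_tibble(gt)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
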