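#' Simulate an SV catalog with type-specific size distributions
#'
#' Draws `sum(config$n_sv)` structural variants on the configured genome.
#' Deletion, duplication and inversion sizes follow log-normal bodies whose
#' means mirror a curated short-read SV catalog (deletions ~1.5 kb,
#' duplications ~8 kb, inversions ~120 kb, all >= 100 bp), and a
#' `spike_fraction` of deletions is drawn uniformly in 1432-1436 bp,
#' reproducing the narrow excision-footprint peak such catalogs show.
#' SVs longer than their chromosome are rejected and resampled.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sv_id`, `chrom`, `start`, `end`, `svtype`,
#'   `size`; coordinates are 0-based half-open.
#' @export
simulate_sv_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "catalog", {
    pieces <- lapply(sv_types, function(type) {
      n <- as.integer(config$n_sv[[type]])
      if (n == 0L) return(NULL)
      sizes <- draw_sv_sizes(type, n, config$spike_fraction)
      place_svs(sizes, type, config$genome)
    })
    out <- dplyr::bind_rows(pieces)
    if (is.null(out) || nrow(out) == 0L) {
      return(tibble(sv_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    svtype = character(), size = integer()))
    }
    out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
    out$sv_id <- sprintf("sv%05d", seq_len(nrow(out)))
    dplyr::select(out, "sv_id", "chrom", "start", "end", "svtype", "size")
  })
}

# log-normal size bodies chosen to match reported per-type means
SV_SIZE_PARAMS <- list(
  DEL = c(meanlog = log(1532) - 0.72,   sdlog = 1.2),
  DUP = c(meanlog = log(8183) - 1.125,  sdlog = 1.5),
  INV = c(meanlog = log(121935) - 2.0,  sdlog = 2.0)
)

draw_sv_sizes <- function(type, n, spike_fraction) {
  par <- SV_SIZE_PARAMS[[type]]
  sizes <- pmax(100, round(stats::rlnorm(n, par[["meanlog"]], par[["sdlog"]])))
  if (type == "DEL" && spike_fraction > 0 && n > 0) {
    in_spike <- stats::runif(n) < spike_fraction
    sizes[in_spike] <- sample(1432:1436, sum(in_spike), replace = TRUE)
  }
  sizes
}

place_svs <- function(sizes, type, genome) {
  max_len <- max(genome)
  too_long <- sizes >= max_len
  if (any(too_long)) {
    warn(sprintf("%d %s size draw(s) exceeded the longest chromosome; resampled",
                 sum(too_long), type))
    while (any(too_long)) {
      sizes[too_long] <- draw_sv_sizes(type, sum(too_long), 0)
      too_long <- sizes >= max_len
    }
  }
  # place on chromosomes long enough for each SV, uniform over valid starts
  chrom <- character(length(sizes))
  start <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    ok <- names(genome)[genome > sizes[i]]
    chrom[i] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    start[i] <- as.integer(floor(stats::runif(1, 0, genome[[chrom[i]]] - sizes[i])))
  }
  tibble(chrom = chrom, start = start, end = start + as.integer(sizes),
         svtype = type, size = as.integer(sizes))
}

#' Simulate a genotyped cohort under a hierarchical Balding-Nichols model
#'
#' Generates the SV catalog (via [simulate_sv_catalog()], so identifiers
#' match), a sample table and a per-sample genotype matrix. Ancestral allele
#' frequencies are uniform on (0.05, 0.95); lineage and population
#' frequencies are successive Balding-Nichols draws with parameters
#' `divergence_F["lineage"]` and `divergence_F["population"]`; a logit-scale
#' latitudinal cline (`cline_slope` per degree) is added on top. The farmed
#' group drifts from the southernmost wild population
#' (`divergence_F["farm"]`) and receives a directional allele-frequency
#' shift of `outlier_freq_shift` at `n_planted_outliers` randomly chosen
#' segregating SVs. Genotypes are Hardy-Weinberg draws from the population
#' frequencies, with genotypes set missing at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `catalog` (tibble), `genotypes` (tibble:
#'   `sv_id` plus one `0/0`/`0/1`/`1/1`/`NA` column per sample), `samples`
#'   (tibble: `sample_id`, `origin`, `population`, `lineage`, `latitude`)
#'   and `truth` (list: `sv` tibble with `planted_outlier`, `freqs` tibble of
#'   true per-population allele frequencies).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  catalog <- simulate_sv_catalog(config)
  n_sv <- nrow(catalog)
  samples <- build_sample_table(config)
  with_substream(config$seed, "cohort", {
    if (n_sv == 0L) {
      geno <- tibble(sv_id = character())
      for (s in samples$sample_id) geno[[s]] <- character()
      truth <- list(
        sv = tibble(sv_id = character(), true_call = logical(),
                    planted_outlier = logical()),
        freqs = tibble(sv_id = character(), population = character(),
                       freq = double())
      )
      return(list(catalog = catalog, genotypes = geno, samples = samples,
                  truth = truth))
    }
    Fl <- config$divergence_F[["lineage"]]
    Fp <- config$divergence_F[["population"]]
    Ff <- config$divergence_F[["farm"]]

    p_anc <- stats::runif(n_sv, 0.05, 0.95)
    lineages <- unique(samples$lineage[samples$origin == "wild"])
    p_lin <- vapply(lineages, function(l) bn_draw(p_anc, Fl), numeric(n_sv))
    colnames(p_lin) <- lineages

    pops <- samples |>
      dplyr::filter(.data$origin == "wild") |>
      dplyr::distinct(.data$population, .data$lineage, .data$latitude)
    lat_bar <- mean(pops$latitude)
    p_pop <- matrix(NA_real_, n_sv, nrow(pops),
                    dimnames = list(NULL, pops$population))
    for (j in seq_len(nrow(pops))) {
      p <- bn_draw(p_lin[, pops$lineage[j]], Fp)
      p <- clamp01(p)
      p_pop[, j] <- stats::plogis(stats::qlogis(p) +
                                    config$cline_slope * (pops$latitude[j] - lat_bar))
    }

    planted <- rep(FALSE, n_sv)
    has_farm <- config$n_farmed > 0L
    if (has_farm) {
      source_pop <- pops$population[which.min(pops$latitude)]
      p_src <- p_pop[, source_pop]
      p_farm <- clamp01(bn_draw(p_src, Ff))
      if (config$n_planted_outliers > 0L && config$outlier_freq_shift > 0) {
        eligible <- which(p_src >= 0.15 & p_src <= 0.6)
        k <- min(config$n_planted_outliers, length(eligible))
        idx <- sample(eligible, k)
        planted[idx] <- TRUE
        shift <- config$outlier_freq_shift
        up <- p_src[idx] + shift <= 0.98
        p_farm[idx] <- ifelse(up, p_src[idx] + shift, pmax(0.02, p_src[idx] - shift))
      }
      p_pop <- cbind(p_pop, farmed = p_farm)
    }

    # Hardy-Weinberg genotypes: dosage ~ Binomial(2, p_pop[sample's population])
    pop_of <- samples$population
    dos <- matrix(NA_integer_, n_sv, nrow(samples),
                  dimnames = list(catalog$sv_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      dos[, j] <- stats::rbinom(n_sv, 2L, p_pop[, pop_of[j]])
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow(dos), ncol(dos))
      dos[miss] <- NA_integer_
    }
    geno <- as_tibble(matrix(dosage_to_gt(dos), nrow(dos), ncol(dos),
                             dimnames = dimnames(dos)))
    geno <- dplyr::bind_cols(tibble(sv_id = catalog$sv_id), geno)

    truth <- list(
      sv = tibble(sv_id = catalog$sv_id, true_call = TRUE,
                  planted_outlier = planted),
      freqs = as_tibble(p_pop) |>
        dplyr::mutate(sv_id = catalog$sv_id, .before = 1) |>
        pivot_longer(-"sv_id", names_to = "population", values_to = "freq")
    )
    list(catalog = catalog, genotypes = geno, samples = samples, truth = truth)
  })
}

build_sample_table <- function(config) {
  n_pop <- config$n_populations
  pops <- sprintf("pop%02d", seq_len(n_pop))
  lineage <- ifelse(seq_len(n_pop) <= ceiling(n_pop / 2), "L1", "L2")
  pop_assign <- rep(pops, length.out = config$n_wild)
  wild <- tibble(
    sample_id = sprintf("wild%03d", seq_len(config$n_wild)),
    origin = "wild",
    population = sort(pop_assign),
    lineage = lineage[match(sort(pop_assign), pops)],
    latitude = config$latitudes[match(sort(pop_assign), pops)]
  )
  if (config$n_farmed > 0L) {
    src <- which.min(config$latitudes)
    farmed <- tibble(
      sample_id = sprintf("farm%03d", seq_len(config$n_farmed)),
      origin = "farmed",
      population = "farmed",
      lineage = lineage[src],
      latitude = config$latitudes[src]
    )
    dplyr::bind_rows(wild, farmed)
  } else {
    wild
  }
}

# Balding-Nichols draw around p with differentiation F
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  if (F >= 1) return(as.numeric(stats::rbinom(length(p), 1L, p)))
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

clamp01 <- function(p, eps = 1e-6) pmin(1 - eps, pmax(eps, p))

#' Simulate per-sample per-window sequencing coverage
#'
#' Background depths are Poisson around `depth_mean`. `n_complex_regions`
#' regions of `complex_region_width` bp are planted: inside them,
#' `n_high_samples` samples have Poisson depth around `depth_high`,
#' emulating collapsed duplications that attract excess coverage. The
#' planted intervals are recorded as truth.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples to simulate coverage for; defaults to
#'   the cohort size.
#' @return A list of class `coverage_profile`: `windows` (tibble `chrom`,
#'   `start`, `end`), `depth` (windows x samples matrix) and `truth_regions`
#'   (tibble of planted high-depth intervals).
#' @export
simulate_coverage <- function(config, n_samples = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_samples <- n_samples %||% (config$n_wild + config$n_farmed)
  if (config$window > min(config$genome)) {
    abort("coverage window is larger than the smallest chromosome",
          class = "svpop_config_error")
  }
  with_substream(config$seed, "coverage", {
    windows <- dplyr::bind_rows(lapply(names(config$genome), function(ch) {
      starts <- seq(0L, config$genome[[ch]] - 1L, by = config$window)
      tibble(chrom = ch, start = as.integer(starts),
             end = as.integer(pmin(starts + config$window, config$genome[[ch]])))
    }))
    n_win <- nrow(windows)
    depth <- matrix(stats::rpois(n_win * n_samples, config$depth_mean),
                    n_win, n_samples,
                    dimnames = list(NULL, sprintf("s%03d", seq_len(n_samples))))
    truth <- tibble(chrom = character(), start = integer(), end = integer())
    if (config$n_complex_regions > 0L) {
      region_idx <- sample(n_win, config$n_complex_regions)
      hi_samples <- seq_len(min(config$n_high_samples, n_samples))
      regions <- list()
      for (i in region_idx) {
        ch <- windows$chrom[i]
        span <- which(windows$chrom == ch &
                        windows$start >= windows$start[i] &
                        windows$start < windows$start[i] + config$complex_region_width)
        depth[span, hi_samples] <- stats::rpois(length(span) * length(hi_samples),
                                                config$depth_high)
        regions[[length(regions) + 1L]] <-
          tibble(chrom = ch, start = windows$start[min(span)],
                 end = windows$end[max(span)])
      }
      truth <- dplyr::bind_rows(regions) |>
        dplyr::arrange(.data$chrom, .data$start)
    }
    structure(list(windows = windows, depth = depth, truth_regions = truth),
              class = "coverage_profile")
  })
}

#' Simulate visual-curation labels with region-dependent false-call rates
#'
#' Each SV call is a false call with probability `fdr_complex` when it
#' overlaps a complex region and `fdr_normal` otherwise. False calls are
#' labelled `"no"` or `"maybe"` (equally likely), true calls `"yes"`,
#' mirroring the three-way question curators answer; the truth is recorded.
#'
#' @param catalog SV catalog tibble.
#' @param regions Region tibble (`chrom`, `start`, `end`) of complex regions;
#'   may have zero rows.
#' @param config A [sim_config()].
#' @return A tibble `sv_id`, `region_class` (`complex`/`normal`), `label`
#'   (`yes`/`no`/`maybe`), `true_call`.
#' @export
simulate_curation_labels <- function(catalog, regions, config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "curation", {
    in_region <- if (nrow(regions) == 0L) {
      rep(FALSE, nrow(catalog))
    } else {
      IRanges::overlapsAny(as_granges0(catalog), as_granges0(regions))
    }
    p_false <- ifelse(in_region, config$fdr_complex, config$fdr_normal)
    false_call <- stats::runif(nrow(catalog)) < p_false
    label <- ifelse(false_call,
                    ifelse(stats::runif(nrow(catalog)) < 0.5, "no", "maybe"),
                    "yes")
    tibble(
      sv_id = catalog$sv_id,
      region_class = ifelse(in_region, "complex", "normal"),
      label = label,
      true_call = !false_call
    )
  })
}

#' Simulate long-read amplicon pileups over SV breakpoints
#'
#' For each selected (SV, sample) pair the true genotype from the genotype
#' matrix drives read counts: total coverage is Poisson around
#' `amplicon_mean_cov` (failed PCRs, probability `amplicon_dropout`, draw
#' from a low-coverage Poisson instead), a fraction `amplicon_unassigned`
#' of reads supports neither allele, and assignable reads support the SV
#' allele with probability `g/2` perturbed by the per-read error rate.
#'
#' @param genotypes Genotype tibble from [simulate_cohort()].
#' @param config A [sim_config()].
#' @param pairs Optional tibble (`sv_id`, `sample_id`) selecting pileups;
#'   defaults to `n_amplicons` random pairs with non-missing genotypes.
#' @return A tibble `sv_id`, `sample_id`, `n_total`, `n_alt`, `n_ref`,
#'   `true_gt`, `called_gt`.
#' @export
simulate_amplicon_pileups <- function(genotypes, config, pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "amplicon", {
    long <- genotypes |>
      pivot_longer(-"sv_id", names_to = "sample_id", values_to = "gt") |>
      dplyr::filter(!is.na(.data$gt))
    if (is.null(pairs)) {
      n <- min(config$n_amplicons, nrow(long))
      long <- long[sample(nrow(long), n), ]
    } else {
      long <- dplyr::inner_join(pairs, long, by = c("sv_id", "sample_id"))
    }
    g <- gt_to_dosage(long$gt)
    n <- nrow(long)
    dropout <- stats::runif(n) < config$amplicon_dropout
    n_total <- ifelse(dropout,
                      stats::rpois(n, 20),
                      stats::rpois(n, config$amplicon_mean_cov))
    unassigned <- stats::rbinom(n, n_total, config$amplicon_unassigned)
    assignable <- n_total - unassigned
    e <- config$amplicon_error
    f_alt <- (g / 2) * (1 - e) + (1 - g / 2) * e
    n_alt <- stats::rbinom(n, assignable, f_alt)
    tibble(
      sv_id = long$sv_id, sample_id = long$sample_id,
      n_total = as.integer(n_total), n_alt = as.integer(n_alt),
      n_ref = as.integer(assignable - n_alt),
      true_gt = long$gt, called_gt = long$gt
    )
  })
}

#' Simulate an ohnolog/singleton gene table
#'
#' Places `2 * n_ohnolog_pairs + n_singletons` genes on the configured
#' genome (lengths log-normal around ~5 kb) and pairs the first
#' `2 * n_ohnolog_pairs` of them as whole-genome-duplication ohnolog pairs,
#' members on different chromosomes where possible.
#'
#' @param config A [sim_config()].
#' @return A tibble `gene_id`, `partner_id` (`NA` for singletons), `status`
#'   (`ohnolog`/`singleton`), `chrom`, `start`, `end`.
#' @export
simulate_ohnolog_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "ohnolog", {
    n_genes <- 2L * config$n_ohnolog_pairs + config$n_singletons
    len <- pmax(500, round(stats::rlnorm(n_genes, log(5000), 0.6)))
    chrom <- sample(names(config$genome), n_genes, replace = TRUE,
                    prob = config$genome / sum(config$genome))
    start <- vapply(seq_len(n_genes), function(i) {
      as.integer(floor(stats::runif(1, 0, config$genome[[chrom[i]]] - len[i])))
    }, integer(1))
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    partner <- rep(NA_character_, n_genes)
    if (config$n_ohnolog_pairs > 0L) {
      a <- seq_len(config$n_ohnolog_pairs)
      b <- a + config$n_ohnolog_pairs
      partner[a] <- gene_id[b]
      partner[b] <- gene_id[a]
    }
    tibble(
      gene_id = gene_id, partner_id = partner,
      status = ifelse(is.na(partner), "singleton", "ohnolog"),
      chrom = chrom, start = start, end = start + as.integer(len)
    )
  })
}

#' Plant per-gene SV-overlap truth with duplicate-status bias
#'
#' Flags each gene as SV-overlapped with probability `overlap_p_ohnolog`
#' (ohnologs) or `overlap_p_singleton` (singletons), giving a known
#' enrichment odds ratio for the downstream Fisher test to recover.
#'
#' @param ohnologs Gene table from [simulate_ohnolog_table()].
#' @param config A [sim_config()].
#' @return A tibble `gene_id`, `status`, `sv_overlap`.
#' @export
simulate_gene_overlap <- function(ohnologs, config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "gene_overlap", {
    p <- ifelse(ohnologs$status == "ohnolog",
                config$overlap_p_ohnolog, config$overlap_p_singleton)
    tibble(gene_id = ohnologs$gene_id, status = ohnologs$status,
           sv_overlap = stats::runif(nrow(ohnologs)) < p)
  })
}

#' Simulate a gene-by-tissue expression matrix with correlated ohnolog pairs
#'
#' Log2 abundance for each ohnolog pair is a Gaussian copula: per tissue the
#' pair's deviations are bivariate normal with Pearson correlation
#' `2*sin(pi*expr_rho/6)`, so the population Spearman correlation across
#' tissues equals `expr_rho` exactly. Singletons are independent draws. Gene
#' copies flagged as SV-overlapped get (i) their abundance multiplied by
#' `expr_sv_effect` and (ii) an independent per-tissue log2 perturbation of
#' standard deviation `expr_sv_noise`, mean-corrected so the expected
#' abundance ratio to the partner stays `expr_sv_effect` while the
#' within-pair correlation is attenuated — a disrupted copy is both lower
#' and less coordinated.
#'
#' @param ohnologs Gene table from [simulate_ohnolog_table()].
#' @param overlap_truth Tibble with `gene_id` and logical `sv_overlap`
#'   (e.g. from [simulate_gene_overlap()] or computed flags).
#' @param config A [sim_config()].
#' @return A tibble: `gene_id` plus one non-negative abundance column per
#'   tissue.
#' @export
simulate_expression <- function(ohnologs, overlap_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 3) {
    abort("at least 3 tissues are required for expression simulation",
          class = "svpop_config_error")
  }
  with_substream(config$seed, "expression", {
    tis <- tissue_names(config$n_tissues)
    n_t <- length(tis)
    rho_pearson <- if (config$expr_rho >= 1) 1 else 2 * sin(pi * config$expr_rho / 6)
    expr <- matrix(NA_real_, nrow(ohnologs), n_t,
                   dimnames = list(ohnologs$gene_id, tis))
    is_a <- !is.na(ohnologs$partner_id) &
      ohnologs$gene_id < ohnologs$partner_id
    a_idx <- which(is_a)
    b_idx <- match(ohnologs$partner_id[a_idx], ohnologs$gene_id)
    mu <- stats::rnorm(nrow(ohnologs), 4, 1.5)
    mu[b_idx] <- mu[a_idx]                       # pair members share a baseline
    if (length(a_idx) > 0L) {
      z_a <- matrix(stats::rnorm(length(a_idx) * n_t), length(a_idx), n_t)
      z_i <- matrix(stats::rnorm(length(a_idx) * n_t), length(a_idx), n_t)
      z_b <- rho_pearson * z_a + sqrt(1 - rho_pearson^2) * z_i
      expr[a_idx, ] <- mu[a_idx] + z_a
      expr[b_idx, ] <- mu[b_idx] + z_b
    }
    singles <- which(is.na(ohnologs$partner_id))
    if (length(singles) > 0L) {
      expr[singles, ] <- mu[singles] +
        matrix(stats::rnorm(length(singles) * n_t), length(singles), n_t)
    }
    hit <- ohnolog_overlap_lookup(ohnologs$gene_id, overlap_truth)
    if (any(hit) && config$expr_sv_noise > 0) {
      s <- config$expr_sv_noise
      # lognormal mean correction keeps E[2^noise] = 1
      expr[hit, ] <- expr[hit, , drop = FALSE] +
        matrix(stats::rnorm(sum(hit) * n_t, 0, s), sum(hit), n_t) -
        s^2 * log(2) / 2
    }
    tpm <- 2^expr
    tpm[hit, ] <- tpm[hit, , drop = FALSE] * config$expr_sv_effect
    dplyr::bind_cols(tibble(gene_id = ohnologs$gene_id), as_tibble(tpm))
  })
}

ohnolog_overlap_lookup <- function(gene_ids, overlap_truth) {
  m <- match(gene_ids, overlap_truth$gene_id)
  hit <- overlap_truth$sv_overlap[m]
  hit[is.na(hit)] <- FALSE
  hit
}

#' Simulate open-chromatin (ATAC) peaks near genes
#'
#' Places one peak within the gene span or its 3 kb flanks for a fraction of
#' genes, optionally enriching peak presence among a designated gene subset.
#'
#' @param genes Gene table (needs `gene_id`, `chrom`, `start`, `end`).
#' @param config A [sim_config()].
#' @param p_peak Baseline probability a gene carries a peak.
#' @param enriched_genes Optional character vector of gene ids whose peak
#'   probability is `p_enriched`.
#' @param p_enriched Peak probability for `enriched_genes`.
#' @return A tibble `peak_id`, `chrom`, `start`, `end`, `gene_id`.
#' @export
simulate_atac_peaks <- function(genes, config, p_peak = 0.2,
                                enriched_genes = character(), p_enriched = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "atac", {
    p <- ifelse(genes$gene_id %in% enriched_genes, p_enriched, p_peak)
    has_peak <- stats::runif(nrow(genes)) < p
    idx <- which(has_peak)
    if (length(idx) == 0L) {
      return(tibble(peak_id = character(), chrom = character(),
                    start = integer(), end = integer(), gene_id = character()))
    }
    width <- pmax(100L, as.integer(round(stats::rlnorm(length(idx), log(400), 0.4))))
    offset <- as.integer(round(stats::runif(length(idx), -2000, 2000)))
    start <- pmax(0L, genes$start[idx] + offset)
    tibble(
      peak_id = sprintf("peak%05d", seq_along(idx)),
      chrom = genes$chrom[idx],
      start = start,
      end = start + width,
      gene_id = genes$gene_id[idx]
    )
  })
}
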