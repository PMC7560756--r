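#' Simulation configuration for the synthetic SV cohort
#'
#' Builds the single configuration object consumed by every `simulate_*()`
#' generator. Defaults emulate the design of a large farmed-vs-wild salmonid
#' resequencing cohort at desk scale: 257 wild fish in six populations along
#' a latitudinal cline split over two diverged lineages, 34 farmed fish
#' derived from the southernmost population, roughly 90/8/2 percent
#' DEL/DUP/INV structural variants with a narrow deletion-size spike at
#' 1432-1436 bp (a transposon-excision signature), region-dependent
#' false-call rates matching visual-curation estimates (0.992 in complex
#' regions, 0.85 elsewhere), and a 15-tissue expression atlas with tunable
#' within-ohnolog-pair correlation.
#'
#' Allele frequencies follow a hierarchical Balding-Nichols model: each
#' population frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around its lineage
#' frequency, which is itself a Balding-Nichols draw around the ancestral
#' frequency. `divergence_F` carries the three differentiation parameters
#' (`lineage`, `population`, `farm`); the closed-form link E(theta) = F makes
#' the generator's parameters recoverable by the Weir-Cockerham estimator.
#'
#' @param n_wild,n_farmed Number of wild and farmed individuals.
#' @param n_populations Number of wild populations (split over two lineages).
#' @param latitudes Per-population latitude (degrees); length `n_populations`.
#' @param n_sv Named integer vector of SV counts per type (`DEL`, `DUP`, `INV`).
#' @param spike_fraction Fraction of deletions drawn uniformly in 1432-1436 bp.
#' @param divergence_F Named Balding-Nichols parameters
#'   `c(lineage=, population=, farm=)`, each in `[0, 1]`.
#' @param cline_slope Logit-scale allele-frequency shift per degree latitude.
#' @param n_planted_outliers Number of SVs given a directional farmed shift.
#' @param outlier_freq_shift Allele-frequency delta applied to the farmed
#'   group at planted outlier SVs.
#' @param missing_rate Per-genotype missingness probability.
#' @param fdr_complex,fdr_normal False-call probability for SV calls inside /
#'   outside complex regions.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param window Coverage window size (bp).
#' @param depth_mean,depth_high Mean per-window depth for background and for
#'   planted high-depth (collapsed-duplication) regions.
#' @param n_complex_regions,complex_region_width Number and width (bp) of
#'   planted high-depth regions.
#' @param n_high_samples Number of samples carrying `depth_high` in planted
#'   regions.
#' @param n_tissues Number of expression tissues (must be >= 3; the first is
#'   named `brain`).
#' @param expr_rho Target within-ohnolog-pair Spearman expression correlation.
#' @param expr_sv_effect Multiplicative abundance factor (< 1 reduces) applied
#'   to gene copies overlapped by an SV.
#' @param expr_sv_noise Log2-scale standard deviation of the per-tissue
#'   regulatory perturbation added to SV-overlapped copies; attenuates their
#'   within-pair correlation without changing the mean abundance ratio.
#' @param n_ohnolog_pairs,n_singletons Gene counts for the duplicate table.
#' @param overlap_p_ohnolog,overlap_p_singleton Per-gene SV-overlap
#'   probability by duplicate status, used when planting overlap truth.
#' @param n_amplicons Number of (SV, sample) amplicon pileups to simulate.
#' @param amplicon_mean_cov Mean pileup coverage for successful PCRs.
#' @param amplicon_dropout Probability a pileup is a failed PCR (low coverage).
#' @param amplicon_error Per-read allele misassignment rate.
#' @param amplicon_unassigned Fraction of reads assignable to neither allele.
#' @param seed Integer master seed, expanded into independent named
#'   substreams so each generator has its own reproducible stream.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_wild = 20, n_farmed = 6, n_sv = c(DEL = 50, DUP = 5, INV = 2))
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$genotypes)
#' @export
sim_config <- function(n_wild = 257L,
                       n_farmed = 34L,
                       n_populations = 6L,
                       latitudes = seq(58, 70, length.out = n_populations),
                       n_sv = c(DEL = 1800L, DUP = 160L, INV = 40L),
                       spike_fraction = 0.0075,
                       divergence_F = c(lineage = 0.10, population = 0.02, farm = 0.02),
                       cline_slope = 0.03,
                       n_planted_outliers = 50L,
                       outlier_freq_shift = 0.3,
                       missing_rate = 0.01,
                       fdr_complex = 0.992,
                       fdr_normal = 0.85,
                       genome = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6, chr4 = 5e6),
                       window = 1000L,
                       depth_mean = 8,
                       depth_high = 150,
                       n_complex_regions = 5L,
                       complex_region_width = 5000L,
                       n_high_samples = 120L,
                       n_tissues = 15L,
                       expr_rho = 0.6,
                       expr_sv_effect = 0.5,
                       expr_sv_noise = 0.5,
                       n_ohnolog_pairs = 2000L,
                       n_singletons = 1650L,
                       overlap_p_ohnolog = 0.30,
                       overlap_p_singleton = 0.20,
                       n_amplicons = 876L,
                       amplicon_mean_cov = 120,
                       amplicon_dropout = 0.05,
                       amplicon_error = 0.02,
                       amplicon_unassigned = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_wild = n_wild, n_farmed = n_farmed, n_populations = n_populations,
    latitudes = latitudes, n_sv = n_sv, spike_fraction = spike_fraction,
    divergence_F = divergence_F, cline_slope = cline_slope,
    n_planted_outliers = n_planted_outliers,
    outlier_freq_shift = outlier_freq_shift, missing_rate = missing_rate,
    fdr_complex = fdr_complex, fdr_normal = fdr_normal, genome = genome,
    window = window, depth_mean = depth_mean, depth_high = depth_high,
    n_complex_regions = n_complex_regions,
    complex_region_width = complex_region_width,
    n_high_samples = n_high_samples, n_tissues = n_tissues,
    expr_rho = expr_rho, expr_sv_effect = expr_sv_effect,
    expr_sv_noise = expr_sv_noise,
    n_ohnolog_pairs = n_ohnolog_pairs, n_singletons = n_singletons,
    overlap_p_ohnolog = overlap_p_ohnolog,
    overlap_p_singleton = overlap_p_singleton,
    n_amplicons = n_amplicons, amplicon_mean_cov = amplicon_mean_cov,
    amplicon_dropout = amplicon_dropout, amplicon_error = amplicon_error,
    amplicon_unassigned = amplicon_unassigned, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_count(cfg$n_wild, "n_wild")
  check_count(cfg$n_farmed, "n_farmed")
  check_count(cfg$n_populations, "n_populations", min = 1L)
  if (length(cfg$latitudes) != cfg$n_populations ||
      any(!is.finite(cfg$latitudes))) {
    abort("`latitudes` must be finite and of length `n_populations`",
          class = "svpop_config_error")
  }
  if (is.null(names(cfg$n_sv)) || !all(sv_types %in% names(cfg$n_sv))) {
    abort("`n_sv` must be named with DEL, DUP and INV counts",
          class = "svpop_config_error")
  }
  check_count(cfg$n_sv, "n_sv")
  for (f in c("spike_fraction", "missing_rate", "fdr_complex", "fdr_normal",
              "outlier_freq_shift", "expr_sv_effect", "amplicon_dropout",
              "amplicon_error", "amplicon_unassigned", "overlap_p_ohnolog",
              "overlap_p_singleton")) {
    check_fraction(cfg[[f]], f)
  }
  check_fraction(cfg$divergence_F, "divergence_F")
  if (is.null(names(cfg$genome)) || any(cfg$genome <= 0)) {
    abort("`genome` must be a named vector of positive chromosome lengths",
          class = "svpop_config_error")
  }
  if (cfg$n_tissues < 3) {
    abort("`n_tissues` must be >= 3 (correlation undefined otherwise)",
          class = "svpop_config_error")
  }
  check_count(cfg$seed, "seed")
  cfg
}

# canonical tissue names; first is brain so specificity examples are natural
tissue_names <- function(n) {
  base <- c("brain", "liver", "muscle", "spleen", "pancreas", "heart",
            "pyloric", "gill", "skin", "foregut", "kidney", "gonad",
            "eye", "gut", "nose")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("tissue", seq_len(n - length(base))))
}
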