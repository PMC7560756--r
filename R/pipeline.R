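#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent R list) with three blocks:
#' `seed` (integer, mandatory for any stochastic stage), `out_dir`,
#' `stages` (subset of `simulate`, `filter_regions`, `collapse`, `fdr`,
#' `validate`, `fst_scan`, `ohnolog_test`, `annotate`), `sim` (overrides
#' passed to [sim_config()]) and `parameters` (stage thresholds:
#' `depth_threshold`, `sample_threshold`, `merge_gap`, `reciprocal`,
#' `min_cov`, `hom_frac`, `het_frac`, `n_perm`, `alpha`, `quantile`,
#' `n_resample`, `flank`, `peak_flank`, `specificity_threshold`).
#' Unknown stages or missing seeds fail before any stage runs.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  all_stages <- c("simulate", "filter_regions", "collapse", "fdr",
                  "validate", "fst_scan", "ohnolog_test", "annotate")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
          class = "svpop_config_error")
  }
  if (is.null(config$seed)) {
    abort("`seed` is required", class = "svpop_config_error")
  }
  check_count(config$seed, "seed")
  if (is.null(config$out_dir)) {
    abort("`out_dir` is required", class = "svpop_config_error")
  }
  defaults <- list(depth_threshold = 100, sample_threshold = 100,
                   merge_gap = 100, reciprocal = 0.9, min_cov = 50,
                   hom_frac = 0.9, het_frac = 0.1, n_perm = 200,
                   alpha = 0.01, quantile = 0.997, n_resample = 1000,
                   flank = 5000, peak_flank = 3000,
                   specificity_threshold = 0.5)
  config$parameters <- utils::modifyList(defaults, config$parameters %||% list())
  # YAML maps come back as named lists; sim_config expects named vectors
  config$sim <- lapply(config$sim %||% list(),
                       function(x) if (is.list(x)) unlist(x) else x)
  structure(config, class = "pipeline_config")
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the SV analysis pipeline end-to-end
#'
#' Executes the configured stages in dependency order on fully synthetic
#' inputs: simulate the cohort and auxiliary tables, detect and exclude
#' complex regions, collapse redundant calls, estimate curation FDR,
#' validate amplicon pileups, run the permutation F(ST) outlier scan,
#' test ohnolog enrichment and expression effects, and annotate outliers.
#' Every output file is listed in a JSON manifest with its md5 digest, the
#' stage parameters and the seed; rerunning with an identical
#' configuration reproduces byte-identical outputs.
#'
#' @param config A [read_pipeline_config()] input (path or list).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  par <- cfg$parameters
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "svpop",
                   version = as.character(utils::packageVersion("svpop")),
                   seed = cfg$seed, parameters = par, stages = list())
  outputs <- character()
  add_output <- function(stage, path) {
    outputs <<- c(outputs, path)
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], path)
  }
  path_of <- function(f) file.path(cfg$out_dir, f)

  sim <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  cohort <- simulate_cohort(sim)
  state <- list(catalog = cohort$catalog, genotypes = cohort$genotypes)

  if ("simulate" %in% cfg$stages) {
    write_sv_vcf(cohort$catalog, cohort$genotypes, path_of("svs.vcf"))
    write_tsv_file(cohort$samples, path_of("samples.tsv"))
    write_tsv_file(cohort$truth$sv, path_of("truth_sv.tsv"))
    write_tsv_file(cohort$truth$freqs, path_of("truth_freqs.tsv"))
    for (f in c("svs.vcf", "samples.tsv", "truth_sv.tsv", "truth_freqs.tsv")) {
      add_output("simulate", path_of(f))
    }
  }

  if ("filter_regions" %in% cfg$stages) {
    coverage <- simulate_coverage(sim)
    high_depth <- find_high_depth_regions(
      coverage, par$depth_threshold,
      min(par$sample_threshold, ncol(coverage$depth)), par$merge_gap)
    gaps <- with_substream(cfg$seed, "gaps", {
      ch <- sample(names(sim$genome), 10, replace = TRUE)
      st <- vapply(ch, function(c) as.integer(stats::runif(1, 0, sim$genome[[c]] - 1e4)),
                   integer(1))
      dplyr::arrange(tibble(chrom = ch, start = st, end = st + 10000L),
                     .data$chrom, .data$start)
    })
    excl_regions <- merge_regions(high_depth, gaps)
    part <- exclude_overlapping(state$catalog, excl_regions)
    state$catalog <- part$kept
    state$genotypes <- dplyr::filter(state$genotypes,
                                     .data$sv_id %in% part$kept$sv_id)
    write_bed(high_depth, path_of("high_depth.bed"))
    write_bed(gaps, path_of("gaps.bed"))
    write_bed(excl_regions, path_of("exclusion.bed"))
    write_tsv_file(part$excluded, path_of("excluded_svs.tsv"))
    for (f in c("high_depth.bed", "gaps.bed", "exclusion.bed", "excluded_svs.tsv")) {
      add_output("filter_regions", path_of(f))
    }
  }

  if ("collapse" %in% cfg$stages) {
    coll <- collapse_redundant(state$catalog, par$reciprocal)
    state$catalog <- coll$kept
    state$genotypes <- dplyr::filter(state$genotypes,
                                     .data$sv_id %in% coll$kept$sv_id)
    write_tsv_file(coll$kept, path_of("catalog_collapsed.tsv"))
    write_tsv_file(coll$removed, path_of("collapsed_removed.tsv"))
    add_output("collapse", path_of("catalog_collapsed.tsv"))
    add_output("collapse", path_of("collapsed_removed.tsv"))
  }

  if ("fdr" %in% cfg$stages) {
    complex_regions <- if (file.exists(path_of("high_depth.bed"))) {
      read_bed(path_of("high_depth.bed"))
    } else {
      tibble(chrom = character(), start = integer(), end = integer())
    }
    labels <- simulate_curation_labels(cohort$catalog, complex_regions, sim)
    fdr <- estimate_fdr(labels, strata = "region_class")
    write_tsv_file(labels, path_of("curation_labels.tsv"))
    write_tsv_file(fdr, path_of("fdr_report.tsv"))
    add_output("fdr", path_of("curation_labels.tsv"))
    add_output("fdr", path_of("fdr_report.tsv"))
  }

  if ("validate" %in% cfg$stages) {
    pile <- simulate_amplicon_pileups(state$genotypes, sim)
    classified <- classify_amplicon(pile, par$min_cov, par$hom_frac, par$het_frac)
    report <- concordance_report(classified, catalog = state$catalog)
    write_tsv_file(classified, path_of("pileups_classified.tsv"))
    write_tsv_file(report, path_of("concordance_report.tsv"))
    add_output("validate", path_of("pileups_classified.tsv"))
    add_output("validate", path_of("concordance_report.tsv"))
  }

  scan <- NULL
  if ("fst_scan" %in% cfg$stages) {
    farm_lineage <- unique(cohort$samples$lineage[cohort$samples$origin == "farmed"])
    keep_samples <- cohort$samples$sample_id[
      cohort$samples$origin == "farmed" |
        (cohort$samples$origin == "wild" & cohort$samples$lineage %in% farm_lineage)]
    geno <- state$genotypes[, c("sv_id", keep_samples)]
    labels <- stats::setNames(
      cohort$samples$origin[match(keep_samples, cohort$samples$sample_id)],
      keep_samples)
    scan <- fst_outlier_scan(geno, labels, n_perm = par$n_perm,
                             q = par$quantile, alpha = par$alpha,
                             seed = cfg$seed)
    write_tsv_file(tidy(scan), path_of("fst_results.tsv"))
    write_tsv_file(tibble(theta = scan$null_theta), path_of("fst_null.tsv"))
    write_tsv_file(glance(scan), path_of("fst_summary.tsv"))
    for (f in c("fst_results.tsv", "fst_null.tsv", "fst_summary.tsv")) {
      add_output("fst_scan", path_of(f))
    }
  }

  ohno <- NULL
  if ("ohnolog_test" %in% cfg$stages || "annotate" %in% cfg$stages) {
    ohno <- simulate_ohnolog_table(sim)
  }
  if ("ohnolog_test" %in% cfg$stages) {
    flags <- gene_overlap_flags(state$catalog, ohno)
    enr <- ohnolog_enrichment(flags, ohno)
    expr <- simulate_expression(ohno, flags, sim)
    sv_genes <- flags$gene_id[flags$sv_overlap]
    res <- tryCatch(
      expression_correlation_resample(ohno, expr, sv_genes,
                                      n_resample = par$n_resample,
                                      seed = cfg$seed),
      error = function(e) NULL)
    lvl <- expression_level_tests(ohno, expr, flags)
    write_tsv_file(ohno, path_of("ohnologs.tsv"))
    write_tsv_file(expr, path_of("expression.tsv"))
    write_tsv_file(tidy(enr), path_of("ohnolog_enrichment.tsv"))
    if (!is.null(res)) write_tsv_file(tidy(res), path_of("expression_resample.tsv"))
    write_tsv_file(lvl, path_of("expression_level_tests.tsv"))
    for (f in c("ohnologs.tsv", "expression.tsv", "ohnolog_enrichment.tsv",
                "expression_level_tests.tsv")) {
      add_output("ohnolog_test", path_of(f))
    }
    if (!is.null(res)) add_output("ohnolog_test", path_of("expression_resample.tsv"))
  }

  if ("annotate" %in% cfg$stages) {
    flags <- gene_overlap_flags(state$catalog, ohno)
    expr <- simulate_expression(ohno, flags, sim)
    spec <- tissue_specificity(expr)
    links <- link_svs_to_genes(state$catalog, ohno, par$flank)
    write_tsv_file(spec, path_of("tissue_specificity.tsv"))
    write_tsv_file(links, path_of("sv_gene_links.tsv"))
    add_output("annotate", path_of("tissue_specificity.tsv"))
    add_output("annotate", path_of("sv_gene_links.tsv"))
    if (!is.null(scan)) {
      out_ids <- scan$results$sv_id[scan$results$outlier]
      outlier_genes <- unique(links$gene_id[links$sv_id %in% out_ids])
      if (length(outlier_genes) > 0L) {
        enr <- brain_enrichment_tests(outlier_genes, spec, expr)
        if (is.null(enr$skipped)) {
          write_tsv_file(dplyr::bind_cols(enr$hypergeometric,
                                          dplyr::rename_with(enr$t_test,
                                                             ~ paste0("t_", .x))),
                         path_of("brain_enrichment.tsv"))
          add_output("annotate", path_of("brain_enrichment.tsv"))
        }
      }
      peaks <- simulate_atac_peaks(ohno, sim)
      out_cat <- dplyr::filter(state$catalog, .data$sv_id %in% out_ids)
      non_cat <- dplyr::filter(state$catalog, !(.data$sv_id %in% out_ids))
      if (nrow(out_cat) > 0L && nrow(non_cat) > 0L) {
        atac <- atac_overlap_test(out_cat, non_cat, peaks, ohno, par$peak_flank)
        if (is.null(atac$skipped)) {
          write_tsv_file(tidy(atac), path_of("atac_overlap_test.tsv"))
          add_output("annotate", path_of("atac_overlap_test.tsv"))
        }
      }
    }
  }

  manifest$files <- lapply(outputs, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
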