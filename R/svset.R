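#' Read an SV VCF into a catalog and genotype tibble
#'
#' Parses a VCF 4.2 file (via vcfR) whose records carry `SVTYPE` and `END`
#' INFO keys and per-sample `GT` fields. 1-based `POS`/`END` are converted
#' to the package's internal 0-based half-open coordinates: a record with
#' `POS=101, END=200` becomes `start=100, end=200` (size 100). Records with
#' an `SVTYPE` outside DEL/DUP/INV are skipped with a warning; records
#' missing `SVTYPE` or `END` raise an error naming the offending file line.
#'
#' @param path Path to a VCF file.
#' @return A list with `catalog` (tibble `sv_id`, `chrom`, `start`, `end`,
#'   `svtype`, `size`) and `genotypes` (tibble `sv_id` plus one genotype
#'   column per sample, values in `0/0`, `0/1`, `1/1`, `NA`).
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_meta <- length(vcf@meta)
  line_of <- function(i) n_meta + 1L + i   # meta lines + #CHROM header + record
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  end1 <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))
  bad <- which(is.na(svtype) | is.na(end1))
  if (length(bad) > 0L) {
    abort(sprintf("VCF record at line %d lacks SVTYPE or END",
                  line_of(bad[1])),
          class = "svpop_vcf_error")
  }
  unknown <- !(svtype %in% sv_types)
  if (any(unknown)) {
    warn(sprintf("skipped %d record(s) with unknown SVTYPE", sum(unknown)))
  }
  keep <- which(!unknown)
  catalog <- tibble(
    sv_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                   sprintf("sv%05d", seq_along(keep)), fix$ID[keep]),
    chrom = fix$CHROM[keep],
    start = as.integer(as.numeric(fix$POS[keep]) - 1),
    end = as.integer(end1[keep]),
    svtype = svtype[keep]
  )
  catalog$size <- catalog$end - catalog$start
  genotypes <- tibble(sv_id = catalog$sv_id)
  if (ncol(vcf@gt) > 1L) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    gt[gt %in% c("./.", ".")] <- NA_character_
    gt[gt == "1/0"] <- "0/1"
    gt <- gt[keep, , drop = FALSE]
    genotypes <- dplyr::bind_cols(genotypes, as_tibble(gt))
  }
  list(catalog = catalog, genotypes = genotypes)
}

#' Write an SV catalog and genotypes as VCF 4.2
#'
#' Emits one record per SV with `SVTYPE`, `END` and `SVLEN` INFO keys and a
#' `GT` FORMAT column per sample; internal 0-based half-open coordinates are
#' converted to 1-based `POS`. [read_sv_vcf()] of the written file
#' round-trips the catalog and genotypes exactly.
#'
#' @param catalog SV catalog tibble.
#' @param genotypes Genotype tibble (`sv_id` + sample columns); may be `NULL`
#'   for a site-only VCF.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(catalog, genotypes = NULL, path) {
  stopifnot(all(catalog$start < catalog$end))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svpop",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("##contig=<ID=", ">"), collapse = "")
  )
  header <- header[header != "##contig=<ID=,>"]
  contigs <- unique(catalog$chrom)
  header <- c(header[1:6], sprintf("##contig=<ID=%s>", contigs))
  samples <- character()
  if (!is.null(genotypes)) {
    samples <- setdiff(names(genotypes), "sv_id")
    genotypes <- genotypes[match(catalog$sv_id, genotypes$sv_id), , drop = FALSE]
  }
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", if (length(samples)) c("FORMAT", samples)),
                      collapse = "\t")
  svlen <- ifelse(catalog$svtype == "DEL", -catalog$size, catalog$size)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                  catalog$svtype, catalog$end, svlen)
  fixed <- paste(catalog$chrom, catalog$start + 1L, catalog$sv_id, "N",
                 sprintf("<%s>", catalog$svtype), ".", "PASS", info,
                 sep = "\t")
  if (length(samples)) {
    gt <- as.matrix(genotypes[, samples, drop = FALSE])
    gt[is.na(gt)] <- "./."
    fixed <- paste(fixed, "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, chrom_line, fixed), path)
  invisible(path)
}

#' Collapse redundant SV calls by reciprocal overlap
#'
#' Two SVs of the same type are redundant when their overlap covers at least
#' `reciprocal` of *each* SV's length (the bedtools `-f -r` convention).
#' Redundant calls are grouped by transitive closure and each group is
#' represented by its record with the smallest `(start, end, sv_id)`, so
#' the operation is deterministic and idempotent.
#'
#' @param catalog SV catalog tibble.
#' @param reciprocal Required reciprocal overlap fraction, in `(0, 1]`.
#' @return A list with `kept` (tibble, sorted by chrom/start/end) and
#'   `removed` (tibble of discarded records with a `kept_as` column naming
#'   their group representative).
#' @export
collapse_redundant <- function(catalog, reciprocal = 0.9) {
  if (!is.numeric(reciprocal) || reciprocal <= 0 || reciprocal > 1) {
    abort("`reciprocal` must be in (0, 1]", class = "svpop_value_error")
  }
  catalog <- dplyr::arrange(catalog, .data$chrom, .data$start, .data$end)
  n <- nrow(catalog)
  if (n == 0L) {
    return(list(kept = catalog, removed = catalog[0, ]))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  for (type in unique(catalog$svtype)) {
    idx <- which(catalog$svtype == type)
    gr <- as_granges0(catalog[idx, ])
    hits <- GenomicRanges::findOverlaps(gr, gr)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    sel <- q < s
    q <- q[sel]; s <- s[sel]
    if (length(q) == 0L) next
    ov <- pmin(GenomicRanges::end(gr)[q], GenomicRanges::end(gr)[s]) -
      pmax(GenomicRanges::start(gr)[q], GenomicRanges::start(gr)[s]) + 1L
    wq <- GenomicRanges::width(gr)[q]
    ws <- GenomicRanges::width(gr)[s]
    red <- ov >= reciprocal * wq & ov >= reciprocal * ws
    for (k in which(red)) union2(idx[q[k]], idx[s[k]])
  }
  root <- vapply(seq_len(n), find, integer(1))
  # representative: smallest (start, end, sv_id) within each group
  ord <- order(catalog$start, catalog$end, catalog$sv_id)
  rep_of <- integer(n)
  seen <- logical(n)
  for (i in ord) {
    r <- root[i]
    if (!seen[r]) { rep_of[r] <- i; seen[r] <- TRUE }
  }
  keep_idx <- rep_of[root]
  kept <- catalog[sort(unique(keep_idx)), , drop = FALSE]
  removed_rows <- which(seq_len(n) != keep_idx)
  removed <- catalog[removed_rows, , drop = FALSE]
  if (nrow(removed) > 0L) {
    removed$kept_as <- catalog$sv_id[keep_idx[removed_rows]]
  } else {
    removed$kept_as <- character(0)
  }
  list(kept = kept, removed = removed)
}

#' Recode genotypes to bi-allelic dosage
#'
#' Maps `0/0`, `0/1`, `1/1` to dosages 0, 1, 2. Missing genotypes are either
#' imputed with the per-SV mean of observed dosages (`"mean"`, the default,
#' as required by PCA) or left as `NA` for pairwise-complete downstream use
#' (`"drop"`). SVs with no observed genotype at all are excluded with a
#' warning.
#'
#' @param genotypes Genotype tibble (`sv_id` + sample columns).
#' @param missing_policy `"mean"` or `"drop"`.
#' @return A tibble `sv_id` plus one numeric dosage column per sample.
#' @export
recode_dosage <- function(genotypes, missing_policy = c("mean", "drop")) {
  missing_policy <- match.arg(missing_policy)
  samples <- setdiff(names(genotypes), "sv_id")
  dos <- matrix(gt_to_dosage(as.matrix(genotypes[, samples, drop = FALSE])),
                nrow = nrow(genotypes),
                dimnames = list(genotypes$sv_id, samples))
  storage.mode(dos) <- "double"
  n_obs <- rowSums(!is.na(dos))
  if (any(n_obs == 0L)) {
    warn(sprintf("excluded %d SV(s) with all genotypes missing", sum(n_obs == 0L)))
    dos <- dos[n_obs > 0L, , drop = FALSE]
  }
  if (missing_policy == "mean") {
    mu <- rowMeans(dos, na.rm = TRUE)
    na_idx <- which(is.na(dos), arr.ind = TRUE)
    if (nrow(na_idx) > 0L) dos[na_idx] <- mu[na_idx[, 1L]]
  }
  dplyr::bind_cols(tibble(sv_id = rownames(dos)), as_tibble(dos))
}

#' Estimate the curation false discovery rate by stratum
#'
#' In visual curation, every call answered `"no"` or `"maybe"` is a
#' low-confidence call (only `"yes"` calls are kept downstream), so the
#' empirical FDR of a stratum is `n_low_confidence / n_total`. Reports one
#' row per stratum plus a pooled `overall` row; an empty stratum yields
#' `fdr = NA` rather than 0.
#'
#' @param labels Tibble with a `label` column (`yes`/`no`/`maybe`) and any
#'   stratification columns (e.g. `region_class`).
#' @param strata Character vector of column names to stratify by; `NULL` for
#'   the overall estimate only.
#' @return A tibble `stratum`, `n_total`, `n_low_confidence`, `fdr`.
#' @examples
#' labs <- tibble::tibble(
#'   label = rep(c("no", "yes"), c(9, 1)),
#'   region_class = "complex"
#' )
#' estimate_fdr(labs, strata = "region_class")
#' @export
estimate_fdr <- function(labels, strata = "region_class") {
  if (nrow(labels) == 0L) {
    abort("`labels` is empty", class = "svpop_value_error")
  }
  bad <- setdiff(unique(labels$label), c("yes", "no", "maybe"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown curation label(s): %s", paste(bad, collapse = ", ")),
          class = "svpop_value_error")
  }
  low <- labels$label %in% c("no", "maybe")
  overall <- tibble(
    stratum = "overall",
    n_total = nrow(labels),
    n_low_confidence = sum(low),
    fdr = sum(low) / nrow(labels)
  )
  if (is.null(strata)) return(overall)
  per <- labels |>
    dplyr::mutate(.low = low) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_low_confidence = sum(.data$.low), .groups = "drop") |>
    dplyr::mutate(fdr = ifelse(.data$n_total > 0,
                               .data$n_low_confidence / .data$n_total, NA_real_)) |>
    tidyr::unite("stratum", dplyr::all_of(strata), sep = "/")
  dplyr::bind_rows(per, overall)
}
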