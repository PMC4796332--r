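#' Remove samples with discordant reported and genotype sex
#'
#' A sample is discordant when both sexes are known ("male"/"female") and
#' differ; "unknown" on either side is treated as non-discordant.
#'
#' @param panel a `genotype_panel`.
#' @return list: `panel` (filtered), `removed` (character sample ids).
#' @export
filter_sex_discordant <- function(panel) {
  s <- panel$samples
  known <- s$reported_sex %in% c("male", "female") &
    s$genotype_sex %in% c("male", "female")
  disc <- known & s$reported_sex != s$genotype_sex
  subset_result(panel, keep_samples = !disc, removed = s$sample_id[disc])
}

#' Remove samples exceeding a missing-call fraction
#'
#' A sample is removed when strictly more than `max_missing` of its calls
#' are missing (the study's threshold was "more than 20 %").
#'
#' @param panel a `genotype_panel`.
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return list: `panel`, `removed` (sample ids).
#' @export
filter_sample_missingness <- function(panel, max_missing = 0.20) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(panel$dosages))
  drop <- frac > max_missing
  subset_result(panel, keep_samples = !drop,
                removed = panel$samples$sample_id[drop])
}

#' Remove loci exceeding a missing-call fraction
#'
#' @param panel a `genotype_panel`.
#' @param max_missing maximum tolerated per-locus missing fraction.
#' @return list: `panel`, `removed` (locus ids), `missing_fraction` (named
#'   vector over the input loci).
#' @export
filter_snp_missingness <- function(panel, max_missing = 0.30) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(panel$dosages))
  names(frac) <- panel$loci$id
  drop <- frac > max_missing
  if (all(drop)) stop("SNP missingness filter would remove every locus")
  res <- subset_result(panel, keep_loci = !drop,
                       removed = panel$loci$id[drop])
  res$missing_fraction <- frac
  res
}

#' @noRd
subset_result <- function(panel, keep_samples = NULL, keep_loci = NULL, removed) {
  loci <- panel$loci
  samples <- panel$samples
  dosages <- panel$dosages
  if (!is.null(keep_samples)) {
    samples <- samples[keep_samples, , drop = FALSE]
    dosages <- dosages[keep_samples, , drop = FALSE]
    rownames(samples) <- NULL
  }
  if (!is.null(keep_loci)) {
    loci <- loci[keep_loci, , drop = FALSE]
    class(loci) <- c("hh_loci", "data.frame")
    rownames(loci) <- NULL
    dosages <- dosages[, keep_loci, drop = FALSE]
  }
  list(panel = genotype_panel(loci, samples, dosages, panel$populations),
       removed = removed)
}

#' Genotype concordance between two call sets
#'
#' The fraction of jointly non-missing calls that agree. Calls missing on
#' either side are excluded from the denominator, so the statistic is
#' independent of the missingness rate. Returns `NA` (the undefined marker)
#' when no call is jointly non-missing.
#'
#' @param calls_a,calls_b dosage matrices or vectors of identical shape.
#' @return scalar fraction in `[0, 1]`, or `NA`.
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  if (!identical(dim(calls_a) %||% length(calls_a),
                 dim(calls_b) %||% length(calls_b))) {
    stop("call sets have mismatched shapes")
  }
  joint <- !is.na(calls_a) & !is.na(calls_b)
  n <- sum(joint)
  if (n == 0L) return(NA_real_)
  sum(calls_a[joint] == calls_b[joint]) / n
}

#' Run the full genotype QC pipeline
#'
#' Filters are applied in a fixed, documented order: sex-discordance, then
#' sample missingness, then SNP missingness. Duplicate concordance is
#' computed over pairs flagged by `duplicate_of` before any filtering.
#' Re-running QC on its own output removes nothing (idempotence).
#'
#' @param panel a `genotype_panel`.
#' @param max_sample_missing sample-level missingness threshold (strict).
#' @param max_snp_missing SNP-level missingness threshold (strict).
#' @param reference optional dosage matrix (samples x loci, matching a
#'   subset of the panel's sample ids and locus ids) of externally validated
#'   calls for concordance checking.
#' @return a `qc_report` list: the filtered `panel` plus counts, per-SNP
#'   missing fractions and concordance statistics.
#' @export
run_qc <- function(panel, max_sample_missing = 0.20, max_snp_missing = 0.30,
                   reference = NULL) {
  n_input <- nrow(panel$samples)

  dup_conc <- NA_real_
  dups <- panel$samples$duplicate_of
  if (any(!is.na(dups))) {
    di <- which(!is.na(dups))
    si <- match(dups[di], panel$samples$sample_id)
    ok <- !is.na(si)
    if (any(ok)) {
      dup_conc <- genotype_concordance(panel$dosages[di[ok], , drop = FALSE],
                                       panel$dosages[si[ok], , drop = FALSE])
    }
  }

  ref_conc <- NA_real_
  if (!is.null(reference)) {
    rs <- intersect(rownames(reference), panel$samples$sample_id)
    rl <- intersect(colnames(reference), panel$loci$id)
    if (length(rs) && length(rl)) {
      ref_conc <- genotype_concordance(
        panel$dosages[match(rs, panel$samples$sample_id), rl, drop = FALSE],
        reference[rs, rl, drop = FALSE])
    }
  }

  step1 <- filter_sex_discordant(panel)
  step2 <- filter_sample_missingness(step1$panel, max_sample_missing)
  step3 <- filter_snp_missingness(step2$panel, max_snp_missing)

  structure(list(
    panel = step3$panel,
    n_input_samples = n_input,
    n_removed_sex_discordant = length(step1$removed),
    n_removed_missingness = length(step2$removed),
    n_removed_snps = length(step3$removed),
    removed_sex_discordant = step1$removed,
    removed_missingness = step2$removed,
    removed_snps = step3$removed,
    per_snp_missing_fraction = step3$missing_fraction,
    duplicate_concordance = dup_conc,
    reference_concordance = ref_conc
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input samples:          %d\n", x$n_input_samples))
  cat(sprintf("  sex-discordant removed: %d\n", x$n_removed_sex_discordant))
  cat(sprintf("  missingness removed:    %d\n", x$n_removed_missingness))
  cat(sprintf("  SNPs removed:           %d\n", x$n_removed_snps))
  cat(sprintf("  retained:               %d samples x %d loci\n",
              nrow(x$panel$samples), nrow(x$panel$loci)))
  if (!is.na(x$duplicate_concordance))
    cat(sprintf("  duplicate concordance:  %.3f\n", x$duplicate_concordance))
  if (!is.na(x$reference_concordance))
    cat(sprintf("  reference concordance:  %.3f\n", x$reference_concordance))
  invisible(x)
}

#' Serialize a QC report
#'
#' Writes both a human-readable text file and a structured key/value TSV.
#'
#' @param report a `qc_report`.
#' @param path base output path; `.txt` and `.tsv` suffixes are appended.
#' @export
write_qc_report <- function(report, path) {
  txt <- paste0(path, ".txt")
  con <- file(txt, "w"); sink(con); print(report); sink(); close(con)
  kv <- data.frame(
    key = c("n_input_samples", "n_removed_sex_discordant",
            "n_removed_missingness", "n_removed_snps",
            "duplicate_concordance", "reference_concordance",
            paste0("missing_fraction.", names(report$per_snp_missing_fraction))),
    value = c(report$n_input_samples, report$n_removed_sex_discordant,
              report$n_removed_missingness, report$n_removed_snps,
              report$duplicate_concordance, report$reference_concordance,
              unname(report$per_snp_missing_fraction)))
  utils::write.table(kv, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
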