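#' Construct a locus table for a genotyping panel
#'
#' A locus table records, for each SNP in the panel, its identifier, the
#' ancestral and derived alleles (polarity assigned from a primate alignment,
#' supplied as configuration), an optional 1-based reference coordinate, and
#' whether the locus belongs to the five-SNP core motif that defines the
#' archaic (Denisovan-derived) haplotype.
#'
#' @param id character vector of unique SNP identifiers.
#' @param ancestral single-base ancestral allele per locus.
#' @param derived single-base derived allele per locus.
#' @param chrom_pos optional integer reference coordinates (NA allowed).
#' @param core logical: is the locus part of the core motif?
#' @return a `data.frame` with class `hh_loci`.
#' @export
locus_table <- function(id, ancestral, derived, chrom_pos = NA_integer_, core = FALSE) {
  n <- length(id)
  stopifnot(length(ancestral) == n, length(derived) == n)
  chrom_pos <- rep_len(as.integer(chrom_pos), n)
  core <- rep_len(as.logical(core), n)
  if (anyDuplicated(id)) {
    stop("locus ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- ancestral == derived
  if (any(bad)) {
    stop("ancestral and derived alleles identical at: ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = as.character(id), ancestral = toupper(ancestral),
                    derived = toupper(derived), chrom_pos = chrom_pos,
                    core = core, stringsAsFactors = FALSE)
  class(out) <- c("hh_loci", "data.frame")
  out
}

#' Default 19-SNP intronic EPAS1 panel
#'
#' The panel used throughout the package: 19 intronic EPAS1 SNPs of which
#' five (rs115321619, rs73926263, rs73926264, rs73926265, rs55981512) form
#' the core Denisovan motif, whose derived-allele configuration spells
#' "AGGAA". Only nine locus identifiers of the full assay are public;
#' the remaining ten ids and all ancestral bases are synthetic placeholders
#' (prefixed `syn_`) so that the panel has a complete, self-consistent
#' configuration. Loci are ordered along the gene; the three-region
#' structure used by [region_summary()] corresponds to indices 1-8
#' (region 1, containing the core motif and ending at rs149306391),
#' 9-14 (region 2, rs4953354 to rs7586141) and 15-19 (region 3, ending
#' at rs150877473).
#'
#' @return an `hh_loci` locus table with 19 rows.
#' @export
default_panel <- function() {
  ids <- c("rs115321619", "rs73926263", "rs73926264", "rs73926265",
           "rs55981512", "syn_snp06", "syn_snp07", "rs149306391",
           "rs4953354", "syn_snp10", "syn_snp11", "syn_snp12",
           "syn_snp13", "rs7586141", "syn_snp15", "syn_snp16",
           "syn_snp17", "syn_snp18", "rs150877473")
  # derived bases for the core motif spell AGGAA; everything else synthetic
  derived <- c("A", "G", "G", "A", "A", "T", "C", "A",
               "G", "T", "A", "C", "G", "T", "A", "C",
               "G", "T", "G")
  ancestral <- c("G", "A", "A", "G", "G", "C", "T", "G",
                 "A", "C", "G", "T", "A", "C", "G", "T",
                 "A", "C", "C")
  core <- ids %in% c("rs115321619", "rs73926263", "rs73926264",
                     "rs73926265", "rs55981512")
  locus_table(ids, ancestral, derived, chrom_pos = seq(46571000, by = 1800,
                                                       length.out = 19),
              core = core)
}

#' Default three-region partition of the panel
#'
#' @param loci an `hh_loci` table (default [default_panel()]).
#' @return named list of integer locus-index vectors.
#' @export
default_regions <- function(loci = default_panel()) {
  n <- nrow(loci)
  stopifnot(n >= 15L)
  list(region1 = 1:8, region2 = 9:14, region3 = 15:n)
}

#' Population metadata table
#'
#' @param code 3-letter population codes (unique).
#' @param country country name.
#' @param altitude_m residence altitude in metres above sea level (>= 0).
#' @return data.frame with class `hh_populations`.
#' @export
population_table <- function(code, country, altitude_m) {
  if (anyDuplicated(code)) {
    stop("population codes must be unique; duplicated: ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  if (any(!is.finite(altitude_m)) || any(altitude_m < 0)) {
    stop("altitude_m must be finite and non-negative")
  }
  out <- data.frame(code = as.character(code), country = as.character(country),
                    altitude_m = as.numeric(altitude_m),
                    stringsAsFactors = FALSE)
  class(out) <- c("hh_populations", "data.frame")
  out
}

#' Classify a residence altitude
#'
#' Altitude categories follow the study's stratification: high above 3000 m,
#' medium from 2000 m to 3000 m (closed interval, so the three classes
#' partition the non-negative line), low below 2000 m.
#'
#' @param altitude_m numeric vector of altitudes in metres, >= 0.
#' @return character vector in `c("high", "medium", "low")`.
#' @export
#' @examples
#' altitude_class(c(86, 2500, 4115))
altitude_class <- function(altitude_m) {
  if (any(!is.finite(altitude_m)) || any(altitude_m < 0)) {
    stop("altitude_m must be finite and non-negative")
  }
  ifelse(altitude_m > 3000, "high",
         ifelse(altitude_m >= 2000, "medium", "low"))
}

#' Assemble a genotype panel object
#'
#' The central container: an ordered locus table, per-sample metadata, and a
#' samples x loci matrix of derived-allele dosages (0, 1, 2 or NA for a
#' missing call).
#'
#' @param loci an `hh_loci` table.
#' @param samples data.frame with columns `sample_id`, `population`,
#'   `reported_sex`, `genotype_sex` (values "male"/"female"/"unknown"),
#'   optionally `amplified` (logical) and `duplicate_of` (sample id or NA).
#' @param dosages integer matrix, rows = samples, columns = loci.
#' @param populations an `hh_populations` table covering every population
#'   code appearing in `samples`.
#' @return list with class `genotype_panel`.
#' @export
genotype_panel <- function(loci, samples, dosages, populations) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "reported_sex", "genotype_sex")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(samples$amplified)) samples$amplified <- FALSE
  if (is.null(samples$duplicate_of)) samples$duplicate_of <- NA_character_
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(samples)) stop("dosage rows != number of samples")
  if (ncol(dosages) != nrow(loci)) stop("dosage columns != number of loci")
  bad <- dosages[!is.na(dosages)]
  if (any(!(bad %in% 0:2))) stop("dosages must be 0, 1, 2 or NA")
  unknown <- setdiff(unique(samples$population), populations$code)
  if (length(unknown)) {
    stop("unknown population codes: ", paste(unknown, collapse = ", "))
  }
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- loci$id
  structure(list(loci = loci, samples = samples, dosages = dosages,
                 populations = populations),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_panel: %d samples x %d loci (%d core), %d populations, %.1f%% missing\n",
              nrow(x$samples), nrow(x$loci), sum(x$loci$core),
              nrow(x$populations), 100 * miss))
  invisible(x)
}

#' Number of samples and loci in a panel
#' @param panel a `genotype_panel`.
#' @return named integer vector `c(samples =, loci =)`.
#' @export
panel_dim <- function(panel) {
  c(samples = nrow(panel$samples), loci = nrow(panel$loci))
}
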