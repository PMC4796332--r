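#' Read a population metadata TSV
#'
#' Expected columns: `code`, `country`, `altitude_m` (tab-separated, header).
#'
#' @param path file path.
#' @return an `hh_populations` table.
#' @export
read_populations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("code", "country", "altitude_m")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("population table missing columns: ", paste(miss, collapse = ", "))
  population_table(df$code, df$country, df$altitude_m)
}

#' @rdname read_populations
#' @param populations an `hh_populations` table.
#' @export
write_populations <- function(populations, path) {
  utils::write.table(as.data.frame(populations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

META_COLS <- c("sample_id", "population_code", "reported_sex",
               "genotype_sex", "amplified", "duplicate_of")

#' Read a genotype table
#'
#' Two dialects are supported. `"tabular"` is the package's native format:
#' tab-separated with a header row; the first columns are `sample_id`,
#' `population_code`, `reported_sex` (optionally followed by `genotype_sex`,
#' `amplified`, `duplicate_of`), then one column per locus named by its id,
#' holding derived-allele dosages `0`, `1`, `2` or `.` for a missing call.
#' `"vcf"` accepts a VCF v4.2 subset with GT fields; genotypes are converted
#' to derived-allele dosages using the panel's derived allele (not the ALT
#' allele), so records where REF is the derived allele are flipped.
#'
#' @param path file path.
#' @param format `"tabular"` or `"vcf"`.
#' @param loci panel locus table; defaults to [default_panel()].
#' @param populations `hh_populations` table (or path to one). Every sample's
#'   population code must appear here.
#' @param sample_info for `format = "vcf"` only: data.frame keyed by
#'   `sample_id` supplying `population`, `reported_sex`, `genotype_sex`.
#' @return a validated [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("tabular", "vcf"),
                           loci = default_panel(), populations,
                           sample_info = NULL) {
  format <- match.arg(format)
  if (is.character(populations)) populations <- read_populations(populations)
  if (format == "tabular") {
    read_genotypes_tabular(path, loci, populations)
  } else {
    read_genotypes_vcf(path, loci, populations, sample_info)
  }
}

#' @noRd
read_genotypes_tabular <- function(path, loci, populations) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty genotype file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  meta_cols <- header[header %in% META_COLS]
  if (!all(c("sample_id", "population_code", "reported_sex") %in% meta_cols)) {
    stop("tabular genotype file must begin with sample_id, population_code, reported_sex columns")
  }
  locus_cols <- setdiff(header, META_COLS)
  missing_loci <- setdiff(locus_cols, loci$id)
  if (length(missing_loci)) {
    stop("columns not in the panel: ", paste(missing_loci, collapse = ", "))
  }
  n_meta <- length(meta_cols)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- length(header)
  badlen <- which(vapply(rows, length, 0L) != nc)
  if (length(badlen)) {
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 badlen[1L] + 1L, nc, length(rows[[badlen[1L]]])))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  meta <- as.data.frame(mat[, meta_cols, drop = FALSE], stringsAsFactors = FALSE)
  dos_chr <- mat[, locus_cols, drop = FALSE]
  bad_sym <- matrix(!(dos_chr %in% c("0", "1", "2", ".")),
                    nrow(dos_chr), ncol(dos_chr))
  if (any(bad_sym)) {
    idx <- which(bad_sym, arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error at line %d, locus %s: dosage symbol '%s' (expected 0/1/2/.)",
                 idx[1L] + 1L, locus_cols[idx[2L]], dos_chr[bad_sym][1L]))
  }
  dos <- matrix(NA_integer_, nrow(dos_chr), ncol(dos_chr))
  dos[dos_chr != "."] <- as.integer(dos_chr[dos_chr != "."])
  # reorder columns to panel order; loci absent from the file stay all-missing
  full <- matrix(NA_integer_, nrow(dos), nrow(loci),
                 dimnames = list(NULL, loci$id))
  full[, locus_cols] <- dos
  samples <- data.frame(sample_id = meta$sample_id,
                        population = meta$population_code,
                        reported_sex = meta$reported_sex,
                        genotype_sex = meta$genotype_sex %||% "unknown",
                        stringsAsFactors = FALSE)
  if (is.null(meta$genotype_sex)) samples$genotype_sex <- "unknown"
  samples$amplified <- if (is.null(meta$amplified)) FALSE else as.logical(meta$amplified)
  samples$duplicate_of <- if (is.null(meta$duplicate_of)) NA_character_ else
    ifelse(meta$duplicate_of %in% c("", "."), NA_character_, meta$duplicate_of)
  genotype_panel(loci, samples, full, populations)
}

#' @noRd
read_genotypes_vcf <- function(path, loci, populations, sample_info) {
  if (is.null(sample_info)) {
    stop("sample_info (sample_id, population, reported_sex, genotype_sex) is required for VCF input")
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(v)
  if (is.null(dim(fix_raw))) fix_raw <- t(fix_raw)   # single-record files
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1L]))
  ids <- fix$ID
  keep <- ids %in% loci$id
  if (!any(keep)) stop("no VCF records match panel locus ids")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  n_samp <- ncol(gt)
  dos <- matrix(NA_integer_, n_samp, nrow(loci), dimnames = list(colnames(gt), loci$id))
  for (r in seq_len(nrow(fix))) {
    li <- match(fix$ID[r], loci$id)
    ref <- toupper(fix$REF[r]); alt <- toupper(fix$ALT[r])
    der <- loci$derived[li]; anc <- loci$ancestral[li]
    if (ref == anc && alt == der) {
      flip <- FALSE
    } else if (ref == der && alt == anc) {
      flip <- TRUE
    } else {
      stop(sprintf("locus %s: VCF alleles %s/%s match neither ancestral/derived %s/%s",
                   fix$ID[r], ref, alt, anc, der))
    }
    alleles <- strsplit(gsub("\\|", "/", gt[r, ]), "/", fixed = TRUE)
    alt_count <- vapply(alleles, function(a) {
      if (any(is.na(a)) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, 0L)
    dos[, li] <- if (flip) 2L - alt_count else alt_count
  }
  info <- as.data.frame(sample_info, stringsAsFactors = FALSE)
  m <- match(rownames(dos), info$sample_id)
  if (anyNA(m)) {
    stop("sample_info missing entries for: ",
         paste(rownames(dos)[is.na(m)], collapse = ", "))
  }
  info <- info[m, , drop = FALSE]
  samples <- data.frame(sample_id = info$sample_id,
                        population = info$population,
                        reported_sex = info$reported_sex %||% "unknown",
                        genotype_sex = info$genotype_sex %||% "unknown",
                        stringsAsFactors = FALSE)
  genotype_panel(loci, samples, dos, populations)
}

#' Write a genotype panel in the native tabular dialect
#'
#' Writing then reading a panel round-trips dosages, the missingness mask and
#' all sample metadata exactly.
#'
#' @param panel a `genotype_panel`.
#' @param path output file path.
#' @export
write_genotypes <- function(panel, path) {
  dos <- panel$dosages
  chr <- matrix(as.character(dos), nrow(dos), ncol(dos))
  chr[is.na(dos)] <- "."
  s <- panel$samples
  meta <- cbind(s$sample_id, s$population, s$reported_sex, s$genotype_sex,
                as.character(s$amplified),
                ifelse(is.na(s$duplicate_of), ".", s$duplicate_of))
  out <- cbind(meta, chr)
  header <- c(META_COLS, panel$loci$id)
  writeLines(c(paste(header, collapse = "\t"),
               apply(out, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write / read a phased-haplotype table
#'
#' Haplotype strings are over `{0,1}` (ancestral/derived) in panel locus
#' order. The table mirrors the shape of a published haplotype supplement:
#' haplotype id, allele string, frequency and chromosome count.
#'
#' @param hapset a `haplotype_set` from [em_phase()].
#' @param path output path.
#' @export
write_haplotypes <- function(hapset, path) {
  df <- data.frame(haplotype = seq_along(hapset$haplotypes),
                   alleles = hapset$haplotypes,
                   frequency = hapset$frequencies,
                   count = hapset$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
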