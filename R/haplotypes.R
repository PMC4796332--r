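#' Define a core haplotype motif
#'
#' A motif is an ordered subset of panel loci at which a haplotype must be
#' derived to count as a carrier. The default motif is the panel's five
#' core SNPs, whose derived alleles spell the archaic "AGGAA" configuration.
#'
#' @param loci panel locus table.
#' @param locus_ids ids of the motif loci; default = the loci flagged
#'   `core` in the panel.
#' @return list with class `core_motif`: `locus_ids` and integer `index`
#'   positions into the panel.
#' @export
core_motif <- function(loci = default_panel(), locus_ids = loci$id[loci$core]) {
  idx <- match(locus_ids, loci$id)
  if (anyNA(idx)) {
    stop("motif loci absent from panel: ",
         paste(locus_ids[is.na(idx)], collapse = ", "))
  }
  structure(list(locus_ids = locus_ids, index = idx), class = "core_motif")
}

#' Does a haplotype carry the core motif?
#'
#' TRUE iff the haplotype is derived (allele `1`) at every motif locus.
#'
#' @param haplotype allele string(s) over `0`/`1` in panel locus order.
#' @param motif a [core_motif()].
#' @return logical vector.
#' @export
carries_core <- function(haplotype, motif) {
  vapply(haplotype, function(h) {
    bits <- hap_to_bits(h)
    if (max(motif$index) > length(bits)) {
      stop("haplotype does not cover all motif loci")
    }
    all(bits[motif$index] == 1L)
  }, logical(1), USE.NAMES = FALSE)
}

#' Per-population core-haplotype frequencies
#'
#' Counts motif-carrying chromosomes per population from the hard best-pair
#' assignments (two chromosomes per retained sample) and joins residence
#' altitude. Populations with zero phased samples are omitted with a
#' warning. With `weighted = TRUE`, carrier counts are accumulated as
#' posterior-weighted expectations instead of hard calls.
#'
#' @param hapset a `haplotype_set`.
#' @param panel the `genotype_panel` the haplotypes were phased from.
#' @param motif a [core_motif()].
#' @param weighted use posterior-weighted chromosome counts.
#' @return `pop_frequency_table` data.frame: `population`, `altitude_m`,
#'   `n_chromosomes`, `core_count`, `core_frequency`.
#' @export
pop_core_frequencies <- function(hapset, panel, motif = core_motif(panel$loci),
                                 weighted = FALSE) {
  a <- hapset$assignments
  pop <- panel$samples$population[match(a$sample_id, panel$samples$sample_id)]
  if (anyNA(pop)) stop("assignments contain samples absent from the panel")
  is_core1 <- carries_core(a$hap1, motif)
  is_core2 <- carries_core(a$hap2, motif)
  if (weighted) {
    core_per_sample <- a$posterior * (is_core1 + is_core2)
  } else {
    core_per_sample <- as.numeric(is_core1 + is_core2)
  }
  pops <- panel$populations
  empty <- setdiff(pops$code, unique(pop))
  if (length(empty)) {
    warning("populations with no phased samples omitted: ",
            paste(empty, collapse = ", "))
  }
  codes <- intersect(pops$code, unique(pop))
  rows <- lapply(codes, function(cd) {
    sel <- pop == cd
    n_chr <- 2L * sum(sel)
    cc <- sum(core_per_sample[sel])
    data.frame(population = cd,
               altitude_m = pops$altitude_m[pops$code == cd],
               n_chromosomes = n_chr, core_count = cc,
               core_frequency = cc / n_chr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pop_frequency_table", "data.frame")
  out
}

#' Spearman correlation of core-haplotype frequency with altitude
#'
#' Rank correlation (midranks for ties) between population core-haplotype
#' frequency and residence altitude. The p-value uses the t approximation;
#' for `n <= 8` populations an exact permutation p-value is computed by
#' full enumeration over rank orderings (8! = 40320 arrangements; beyond
#' that the enumeration cost outgrows the approximation error). Being rank-based, the statistic is
#' invariant to any strictly monotone transform of altitude.
#'
#' @param freqs a `pop_frequency_table` (or any data.frame with
#'   `altitude_m` and `core_frequency`).
#' @return list: `rho`, `p_value`, `n`, `method`. `rho` is `NA` with an
#'   explanatory `message` when either variable is constant.
#' @export
altitude_correlation <- function(freqs) {
  x <- freqs$altitude_m; y <- freqs$core_frequency
  n <- length(x)
  if (n < 3L) stop("need at least 3 populations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined",
                message = "correlation undefined: constant altitudes or frequencies"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 8L) {
    p <- spearman_exact_p(x, y)
    method <- "exact permutation"
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    p <- ct$p.value
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# exact two-sided permutation p-value for Spearman's rho, full enumeration
#' @noRd
spearman_exact_p <- function(x, y) {
  n <- length(x)
  obs <- abs(stats::cor(x, y, method = "spearman"))
  ry <- rank(y)
  perms <- permutations_of(n)
  vals <- apply(perms, 1L, function(p) abs(stats::cor(rank(x), ry[p])))
  mean(vals >= obs - 1e-12)
}

#' @noRd
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Per-locus derived-allele frequency profile
#'
#' Frequencies are computed over non-missing alleles. Grouping by
#' population or altitude class supports inspection of regional structure
#' along the panel (selection acts unevenly across the gene).
#'
#' @param panel a `genotype_panel`.
#' @param group `"all"`, `"population"` or `"altitude_class"`.
#' @return a matrix (groups x loci) of derived-allele frequencies; `NaN`
#'   where a group has no non-missing call at a locus.
#' @export
derived_freq_profile <- function(panel, group = c("all", "population", "altitude_class")) {
  group <- match.arg(group)
  dos <- panel$dosages
  grp <- switch(group,
    all = rep("all", nrow(dos)),
    population = panel$samples$population,
    altitude_class = {
      alt <- panel$populations$altitude_m[
        match(panel$samples$population, panel$populations$code)]
      altitude_class(alt)
    })
  levels <- unique(grp)
  out <- t(vapply(levels, function(g) {
    sub <- dos[grp == g, , drop = FALSE]
    colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
  }, numeric(ncol(dos))))
  rownames(out) <- levels
  colnames(out) <- panel$loci$id
  out
}

#' Shared-derived-variant filter for candidate functional loci
#'
#' Nominates loci where the derived allele is (i) carried by the archaic
#' reference haplotype, (ii) carried by every carrier haplotype and
#' (iii) absent from every non-carrier haplotype — the pattern expected of
#' a variant specific to the introgressed lineage. Output shrinks (weakly)
#' as the non-carrier set grows.
#'
#' @param carriers character vector of carrier haplotype strings.
#' @param non_carriers character vector of non-carrier haplotype strings.
#' @param archaic single archaic reference haplotype string.
#' @param loci panel locus table (the common locus index).
#' @return character vector of candidate locus ids.
#' @export
shared_variant_filter <- function(carriers, non_carriers, archaic,
                                  loci = default_panel()) {
  L <- nrow(loci)
  all_h <- c(carriers, non_carriers, archaic)
  if (any(nchar(all_h) != L)) {
    stop("haplotype lengths disagree with the locus table")
  }
  arch <- hap_to_bits(archaic)
  car <- do.call(rbind, lapply(carriers, hap_to_bits))
  ok <- arch == 1L & colSums(car) == nrow(car)
  if (length(non_carriers)) {
    non <- do.call(rbind, lapply(non_carriers, hap_to_bits))
    ok <- ok & colSums(non) == 0L
  }
  loci$id[ok]
}
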