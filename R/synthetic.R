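#' Specify a synthetic multi-population genotype panel
#'
#' The generator emulates the statistical structure of a multi-population
#' SNP survey of an introgressed haplotype: two divergent haplotype
#' clusters — one carrying the derived core motif — with the core-cluster
#' frequency a monotone function of each population's residence altitude,
#' plus missing calls, duplicate sample pairs (re-genotyped copies with
#' independent missingness) and sex-discordant samples.
#'
#' Chromosomes are drawn at the haplotype level so that phasing accuracy
#' can be scored against the returned truth. There is no recombination or
#' mutation: the generator imitates the data's structure, not its history.
#'
#' @param n_populations number of populations.
#' @param samples_per_pop samples drawn per population (scalar or vector).
#' @param altitudes residence altitude in metres, one per population.
#' @param core_freq_fn monotone function altitude -> core-cluster frequency
#'   in `[0, 1]`. Default: logistic in altitude, near 0 at sea level and
#'   approaching 0.8 above 4000 m.
#' @param core_haplotype allele string (over `0`/`1`, panel order) of the
#'   core-cluster haplotype; derived at every core-motif locus.
#' @param background_haplotypes named numeric vector: names are non-core
#'   haplotype strings, values their relative weights. The defaults sit at
#'   least six mutational steps from the core cluster.
#' @param missing_rate per-call missing probability in `[0, 1]`.
#' @param duplicate_pairs number of duplicate sample pairs to inject.
#' @param sex_discordant number of samples whose genotype sex is set
#'   discordant with the reported sex.
#' @param seed integer RNG seed.
#' @param loci panel locus table.
#' @return list with class `sim_panel_spec`.
#' @export
sim_panel_spec <- function(n_populations = 12,
                           samples_per_pop = 30,
                           altitudes = round(seq(86, 4550, length.out = n_populations)),
                           core_freq_fn = default_core_freq_fn,
                           core_haplotype = default_core_haplotype(loci),
                           background_haplotypes = default_background_haplotypes(loci),
                           missing_rate = 0.02,
                           duplicate_pairs = 0,
                           sex_discordant = 0,
                           seed = 1L,
                           loci = default_panel()) {
  stopifnot(length(altitudes) == n_populations,
            missing_rate >= 0, missing_rate <= 1,
            duplicate_pairs >= 0, sex_discordant >= 0)
  if (nchar(core_haplotype) != nrow(loci)) {
    stop("core_haplotype length must equal the number of panel loci")
  }
  core_bits <- hap_to_bits(core_haplotype)
  if (any(core_bits[loci$core] != 1L)) {
    stop("core_haplotype must be derived at every core-motif locus")
  }
  structure(list(n_populations = n_populations,
                 samples_per_pop = rep_len(samples_per_pop, n_populations),
                 altitudes = as.numeric(altitudes),
                 core_freq_fn = core_freq_fn,
                 core_haplotype = core_haplotype,
                 background_haplotypes = background_haplotypes,
                 missing_rate = missing_rate,
                 duplicate_pairs = as.integer(duplicate_pairs),
                 sex_discordant = as.integer(sex_discordant),
                 seed = as.integer(seed),
                 loci = loci),
            class = "sim_panel_spec")
}

#' @rdname sim_panel_spec
#' @param altitude_m altitudes in metres.
#' @export
default_core_freq_fn <- function(altitude_m) {
  0.8 / (1 + exp(-(altitude_m - 2500) / 600))
}

#' @rdname sim_panel_spec
#' @export
default_core_haplotype <- function(loci = default_panel()) {
  bits <- integer(nrow(loci))
  # derived across region 1 (which contains the core motif) and at the
  # final region-3 locus, mimicking the extended introgressed haplotype
  bits[1:8] <- 1L
  bits[nrow(loci)] <- 1L
  bits_to_hap(bits)
}

#' @rdname sim_panel_spec
#' @export
default_background_haplotypes <- function(loci = default_panel()) {
  n <- nrow(loci)
  zero <- integer(n)
  h1 <- zero                                  # fully ancestral
  h2 <- zero; h2[c(9, 10)] <- 1L              # region-2 variant
  h3 <- zero; h3[c(9, 14, 15)] <- 1L          # region-2/3 variant
  h4 <- zero; h4[c(15, 16, 19)] <- 1L         # region-3 variant
  haps <- vapply(list(h1, h2, h3, h4), bits_to_hap, "")
  stats::setNames(c(0.5, 0.25, 0.15, 0.10), haps)
}

#' Simulate a genotype panel with ground-truth phase
#'
#' Each chromosome is the core haplotype with probability
#' `core_freq_fn(altitude)` and otherwise a background haplotype drawn by
#' weight. Dosages are sums of the two chromosomes' derived alleles;
#' missing calls, duplicate samples and sex-discordant samples are injected
#' per the spec. The truth table gives the two haplotype strings actually
#' drawn for every sample (duplicates share their source's haplotypes).
#'
#' @param spec a [sim_panel_spec()].
#' @return list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (data.frame: `sample_id`, `hap1`, `hap2`).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "sim_panel_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  loci <- spec$loci
  n_loci <- nrow(loci)
  bg_haps <- names(spec$background_haplotypes)
  bg_w <- spec$background_haplotypes / sum(spec$background_haplotypes)
  pf <- spec$core_freq_fn(spec$altitudes)
  if (any(!is.finite(pf)) || any(pf < 0) || any(pf > 1)) {
    stop("core_freq_fn returned values outside [0, 1]")
  }

  pop_codes <- sprintf("P%02d", seq_len(spec$n_populations))
  populations <- population_table(pop_codes, "Synthetic", spec$altitudes)

  hap_pool <- c(spec$core_haplotype, bg_haps)
  pool_bits <- do.call(rbind, lapply(hap_pool, hap_to_bits))

  samp_list <- vector("list", spec$n_populations)
  truth_list <- vector("list", spec$n_populations)
  dos_list <- vector("list", spec$n_populations)
  for (i in seq_len(spec$n_populations)) {
    n <- spec$samples_per_pop[i]
    draw_chrom <- function(n) {
      is_core <- stats::runif(n) < pf[i]
      idx <- rep(1L, n)
      nb <- sum(!is_core)
      if (nb) idx[!is_core] <- 1L + sample.int(length(bg_haps), nb,
                                               replace = TRUE, prob = bg_w)
      idx
    }
    i1 <- draw_chrom(n); i2 <- draw_chrom(n)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    sid <- sprintf("%s_S%03d", pop_codes[i], seq_len(n))
    samp_list[[i]] <- data.frame(sample_id = sid, population = pop_codes[i],
                                 reported_sex = sex, genotype_sex = sex,
                                 amplified = TRUE, duplicate_of = NA_character_,
                                 stringsAsFactors = FALSE)
    truth_list[[i]] <- data.frame(sample_id = sid, hap1 = hap_pool[i1],
                                  hap2 = hap_pool[i2], stringsAsFactors = FALSE)
    dos_list[[i]] <- pool_bits[i1, , drop = FALSE] + pool_bits[i2, , drop = FALSE]
  }
  samples <- do.call(rbind, samp_list)
  truth <- do.call(rbind, truth_list)
  dosages <- do.call(rbind, dos_list)

  # duplicate pairs: copies of existing samples with independent missingness
  if (spec$duplicate_pairs > 0L) {
    src <- sample(nrow(samples), spec$duplicate_pairs)
    for (k in seq_along(src)) {
      j <- src[k]
      dup <- samples[j, , drop = FALSE]
      dup$sample_id <- paste0(samples$sample_id[j], "_dup")
      dup$duplicate_of <- samples$sample_id[j]
      dup$amplified <- !samples$amplified[j]
      samples <- rbind(samples, dup)
      truth <- rbind(truth, data.frame(sample_id = dup$sample_id,
                                       hap1 = truth$hap1[j], hap2 = truth$hap2[j],
                                       stringsAsFactors = FALSE))
      dosages <- rbind(dosages, dosages[j, ])
    }
  }

  # sex-discordant injections among non-duplicate samples
  if (spec$sex_discordant > 0L) {
    pool <- which(is.na(samples$duplicate_of))
    disc <- sample(pool, spec$sex_discordant)
    samples$genotype_sex[disc] <-
      ifelse(samples$reported_sex[disc] == "male", "female", "male")
  }

  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dosages)) < spec$missing_rate,
                   nrow(dosages), ncol(dosages))
    dosages[mask] <- NA_integer_
  }

  panel <- genotype_panel(loci, samples, dosages, populations)
  list(panel = panel, truth = truth)
}
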