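test_that("core-motif carriage requires the derived allele at every motif locus", {
  loci <- default_panel()
  motif <- core_motif(loci)
  expect_true(carries_core(strrep("1", 19), motif))
  # derived at 4 of 5 motif loci is not a carrier
  h <- rep(1L, 19); h[loci$id == "rs55981512"] <- 0L
  expect_false(carries_core(unbits(h), motif))
  expect_error(core_motif(loci, c("rs115321619", "nope")), "nope")
  expect_error(carries_core("101", motif), "cover")
})

test_that("carriers split into the expected network clusters, recombinant included", {
  loci <- default_panel()
  motif <- core_motif(loci)
  core_cluster <- c(default_core_haplotype(loci),
                    unbits(c(rep(1L, 8), rep(0L, 10), 1L)))
  # a recombinant: core motif present but background elsewhere
  recomb <- rep(0L, 19); recomb[motif$index] <- 1L; recomb[9:10] <- 1L
  grey <- c(core_cluster, unbits(recomb))
  orange <- names(default_background_haplotypes(loci))
  expect_true(all(carries_core(grey, motif)))
  expect_false(any(carries_core(orange, motif)))
})

test_that("population core frequencies count chromosomes and sum consistently", {
  spec <- sim_panel_spec(n_populations = 6, samples_per_pop = 100,
                         altitudes = c(100, 800, 1600, 2400, 3200, 4400),
                         missing_rate = 0, seed = 17)
  sim <- simulate_panel(spec)
  hs <- em_phase(sim$panel)
  motif <- core_motif(sim$panel$loci)
  ft <- pop_core_frequencies(hs, sim$panel, motif)
  expect_equal(ft$core_frequency, ft$core_count / ft$n_chromosomes)
  expect_equal(ft$n_chromosomes, rep(200L, 6))
  # sum invariant: total core counts = total motif-carrying assigned chromosomes
  a <- hs$assignments
  total_core <- sum(carries_core(a$hap1, motif)) + sum(carries_core(a$hap2, motif))
  expect_equal(sum(ft$core_count), total_core)
  # within 3 binomial SE of the generator truth per population
  p_true <- spec$core_freq_fn(ft$altitude_m)
  se <- sqrt(pmax(p_true * (1 - p_true), 1e-4) / ft$n_chromosomes)
  expect_true(all(abs(ft$core_frequency - p_true) < 3 * se + 0.02))
})

test_that("identical genotypes in two populations give identical frequencies", {
  dos <- rbind(matrix(2L, 5, 19), matrix(2L, 5, 19), matrix(0L, 2, 19))
  p <- make_panel(dos, c(rep("AAA", 5), rep("BBB", 5), rep("CCC", 2)),
                  c(AAA = 1000, BBB = 4000, CCC = 100), loci = default_panel())
  hs <- em_phase(p)
  ft <- pop_core_frequencies(hs, p, core_motif(p$loci))
  expect_equal(ft$core_frequency[ft$population == "AAA"],
               ft$core_frequency[ft$population == "BBB"])
})

test_that("altitude correlation hits the rank-correlation extremes", {
  up <- data.frame(altitude_m = c(100, 500, 1500, 2500, 4000),
                   core_frequency = c(0.01, 0.1, 0.3, 0.5, 0.8))
  expect_equal(altitude_correlation(up)$rho, 1)
  down <- up; down$core_frequency <- rev(down$core_frequency)
  expect_equal(altitude_correlation(down)$rho, -1)
  flat <- up; flat$core_frequency <- 0.5
  res <- altitude_correlation(flat)
  expect_true(is.na(res$rho))
  expect_match(res$message, "constant")
})

test_that("small-n Spearman p-value matches exhaustive permutation enumeration", {
  tab <- data.frame(altitude_m = c(100, 700, 1500, 2600, 3400, 4300),
                    core_frequency = c(0.05, 0.22, 0.1, 0.55, 0.34, 0.71))
  res <- altitude_correlation(tab)
  # independent oracle: enumerate all 720 rank orderings with base R
  rx <- rank(tab$altitude_m); ry <- rank(tab$core_frequency)
  obs <- abs(cor(rx, ry))
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  all_rho <- apply(perms, 1, function(p) abs(cor(rx, ry[unlist(p)])))
  expect_equal(res$p_value, mean(all_rho >= obs - 1e-12))
  expect_equal(res$rho, cor(tab$altitude_m, tab$core_frequency, method = "spearman"))
})

test_that("rank correlation is invariant to monotone altitude transforms", {
  set.seed(2)
  tab <- data.frame(altitude_m = sort(runif(15, 100, 4500)),
                    core_frequency = runif(15))
  r1 <- altitude_correlation(tab)
  tab2 <- tab; tab2$altitude_m <- log(tab2$altitude_m)^3
  r2 <- altitude_correlation(tab2)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("derived-allele frequency profiles follow mixture arithmetic", {
  # all-derived group
  p <- make_panel(matrix(2L, 4, 3), rep("AAA", 4), c(AAA = 100))
  expect_true(all(derived_freq_profile(p) == 1))
  # known mixture
  spec <- sim_panel_spec(n_populations = 1, samples_per_pop = 3000,
                         altitudes = 2500,
                         core_freq_fn = function(a) rep(0.3, length(a)),
                         missing_rate = 0, seed = 23)
  sim <- simulate_panel(spec)
  prof <- derived_freq_profile(sim$panel)
  core_bits <- bits(spec$core_haplotype)
  bg_w <- spec$background_haplotypes / sum(spec$background_haplotypes)
  bg_bits <- vapply(names(bg_w), bits, integer(19))
  expected <- 0.3 * core_bits + 0.7 * as.vector(bg_bits %*% bg_w)
  expect_true(all(abs(prof[1, ] - expected) < 0.03))
  # a locus missing in every sample of the group is NaN there only
  dos <- matrix(1L, 3, 3); dos[, 2] <- NA
  p2 <- make_panel(dos, rep("AAA", 3), c(AAA = 100))
  prof2 <- derived_freq_profile(p2)
  expect_true(is.nan(prof2[1, 2]))
  expect_false(anyNA(prof2[1, c(1, 3)]))
})

test_that("profiles group by altitude class", {
  spec <- sim_panel_spec(n_populations = 3, samples_per_pop = 50,
                         altitudes = c(500, 2500, 4000), seed = 3)
  sim <- simulate_panel(spec)
  prof <- derived_freq_profile(sim$panel, "altitude_class")
  expect_setequal(rownames(prof), c("low", "medium", "high"))
  # core-locus frequency rises with the altitude class
  core_idx <- which(sim$panel$loci$core)
  expect_true(mean(prof["high", core_idx]) > mean(prof["low", core_idx]))
})

test_that("shared-derived-variant filter applies all four conditions", {
  loci <- locus_table(sprintf("V%02d", 1:13), rep("A", 13), rep("G", 13))
  # construct 13 candidate loci where exactly 2 (V03, V07) are: derived in
  # the archaic, fixed derived in carriers, absent from non-carriers
  arch <- rep(0L, 13); arch[c(3, 7, 9, 11)] <- 1L
  carrier1 <- rep(0L, 13); carrier1[c(3, 7, 11)] <- 1L
  carrier2 <- rep(0L, 13); carrier2[c(3, 7, 11, 12)] <- 1L
  non1 <- rep(0L, 13); non1[c(1, 11)] <- 1L    # shares V11 -> disqualifies it
  non2 <- rep(0L, 13); non2[2] <- 1L
  got <- shared_variant_filter(c(unbits(carrier1), unbits(carrier2)),
                               c(unbits(non1), unbits(non2)),
                               unbits(arch), loci)
  expect_equal(got, c("V03", "V07"))
  # a locus derived in carriers but ancestral in the archaic is excluded
  expect_false("V12" %in% got)
  # with no non-carriers, every carrier-fixed archaic-derived locus passes
  got_all <- shared_variant_filter(c(unbits(carrier1), unbits(carrier2)),
                                   character(0), unbits(arch), loci)
  expect_equal(got_all, c("V03", "V07", "V11"))
  expect_error(shared_variant_filter("10", "010", "10", loci), "length")
})

test_that("the candidate list shrinks weakly as non-carriers accumulate", {
  set.seed(8)
  loci <- locus_table(sprintf("V%02d", 1:10), rep("A", 10), rep("G", 10))
  arch <- unbits(rbinom(10, 1, 0.7))
  carriers <- replicate(3, unbits(bits(arch) * rbinom(10, 1, 0.9)))
  nons <- replicate(6, unbits(rbinom(10, 1, 0.3)))
  prev <- NULL
  for (k in 0:6) {
    got <- shared_variant_filter(carriers, nons[seq_len(k)], arch, loci)
    if (!is.null(prev)) expect_true(all(got %in% prev))
    prev <- got
  }
})
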