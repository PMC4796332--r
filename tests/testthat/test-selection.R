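test_that("fitness maps encode additive, dominant and recessive selection", {
  expect_equal(fitness_model("additive", 0.02)$fitness,
               c(AA = 1.02, Aa = 1.01, aa = 1))
  expect_equal(fitness_model("dominant", 0.02)$fitness,
               c(AA = 1.02, Aa = 1.02, aa = 1))
  expect_equal(fitness_model("recessive", 0.02)$fitness,
               c(AA = 1.02, Aa = 1, aa = 1))
  expect_error(fitness_model("additive", -0.1))
})

test_that("stationary density reduces to Beta at sigma = 0", {
  for (p in c(0.05, 0.3, 0.9)) {
    expect_equal(stationary_log_density(p, M = 10, pi_tilde = 0.2, sigma = 0),
                 dbeta(p, 2, 8, log = TRUE), tolerance = 1e-12)
  }
})

test_that("stationary density integrates to one (quadrature oracle)", {
  set.seed(12)
  for (i in 1:6) {
    M <- runif(1, 0.5, 50); pt <- runif(1, 0.05, 0.95); sig <- runif(1, 0, 120)
    z <- integrate(function(x) {
      vapply(x, function(p) exp(stationary_log_density(p, M, pt, sig)), 0)
    }, 0, 1, rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("strong selection concentrates the density near fixation", {
  m <- integrate(function(x) {
    x * vapply(x, function(p) exp(stationary_log_density(p, 10, 0.1, 118)), 0)
  }, 0, 1, rel.tol = 1e-9)$value
  expect_gt(m, 0.9)
})

test_that("boundary frequencies are rejected", {
  expect_error(stationary_log_density(0, 10, 0.5, 1), "strictly")
  expect_error(stationary_log_density(1, 10, 0.5, 1), "strictly")
})

test_that("MCMC posterior matches the grid-integration posterior on a two-deme toy", {
  k <- rbind(45, 4); n <- rbind(50, 50)
  M <- 20; pi_t <- 0.5; delta <- 0.1
  fit <- fit_selection(k, n, pilot_runs = 5, pilot_len = 200, burn_in = 4000,
                       thin = 5, n_samples = 2000, seed = 11,
                       fix_M = M, fix_pi_tilde = pi_t, fix_delta = delta)
  # demes factorize given fixed hyper-parameters: compare each marginal mean
  for (i in 1:2) {
    oracle <- oracle_sigma_posterior_mean(k[i, 1], n[i, 1], M, pi_t, delta)
    expect_equal(fit$summary$mean[i], oracle, tolerance = 0.05)
  }
  # the high-frequency deme carries the (much) larger sigma
  expect_gt(fit$summary$mean[1], 5 * fit$summary$mean[2])
})

test_that("null data keep sigma's credible interval below the prior tail", {
  set.seed(31)
  D <- 5; L <- 8; M <- 20; pi_t <- 0.4; delta <- 0.05
  p <- matrix(rbeta(D * L, M * pi_t, M * (1 - pi_t)), D, L)
  n <- matrix(100L, D, L)
  k <- matrix(rbinom(D * L, 100, p), D, L)
  # conditioning on the true migration rate isolates sigma's shrinkage
  # (M and a one-sided sigma are only jointly identified at larger scale)
  fit <- suppressWarnings(
    fit_selection(k, n, pilot_runs = 3, pilot_len = 150, burn_in = 1000,
                  thin = 2, n_samples = 400, seed = 7, fix_delta = delta,
                  fix_M = M))
  prior_q95 <- qexp(0.95, delta)
  frac_ok <- mean(fit$summary$q97.5 < prior_q95)
  expect_gte(frac_ok, 0.9)
})

test_that("exchangeable demes get matching posterior summaries", {
  k <- rbind(c(30, 5), c(30, 5)); n <- matrix(60L, 2, 2)
  fit <- suppressWarnings(
    fit_selection(k, n, pilot_runs = 3, pilot_len = 150, burn_in = 2000,
                  thin = 3, n_samples = 800, seed = 19))
  s <- fit$summary
  for (j in unique(s$locus)) {
    m <- s$mean[s$locus == j]
    expect_lt(abs(m[1] - m[2]), 0.35 * mean(m) + 0.5)
  }
})

test_that("a selected deme is recovered with the top posterior sigma", {
  # one deme under strong selection among 20 neutral demes, 200 chromosomes
  M <- 20; pi_t <- 0.2; sig_true <- 100
  hits <- 0L
  for (rep in 1:3) {
    set.seed(100 + rep)
    # draw the selected deme's frequency from the stationary density by
    # inverse-CDF on a fine grid (independent of the package's sampler)
    grid <- seq(0.001, 0.999, length.out = 2000)
    a <- M * pi_t; b <- M * (1 - pi_t)
    dens <- grid^(a - 1) * (1 - grid)^(b - 1) * exp(sig_true * grid)
    p_sel <- sample(grid, 1, prob = dens / sum(dens))
    p <- c(p_sel, rbeta(19, a, b))
    k <- matrix(rbinom(20, 200, p), 20, 1)
    fit <- suppressWarnings(
      fit_selection(k, matrix(200L, 20, 1), pilot_runs = 3,
                    pilot_len = 100, burn_in = 800, thin = 2,
                    n_samples = 300, seed = rep))
    if (which.max(fit$summary$mean) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("association recovers the altitude signal and its degenerate cases", {
  # perfectly collinear genotype and altitude: p floored, not NaN
  dos <- matrix(rep(c(0L, 1L, 2L), each = 4), 12, 1)
  loci <- locus_table("L1", "A", "G")
  p <- make_panel(dos, rep(c("AAA", "BBB", "CCC"), each = 4),
                  c(AAA = 0, BBB = 1000, CCC = 2000), loci = loci)
  res <- altitude_association(p, "additive")
  expect_equal(res$p_value, 1e-300)
  # monomorphic locus gives an NA row
  dos2 <- cbind(dos, 1L)
  loci2 <- locus_table(c("L1", "L2"), c("A", "C"), c("G", "T"))
  p2 <- make_panel(dos2, rep(c("AAA", "BBB", "CCC"), each = 4),
                   c(AAA = 0, BBB = 1000, CCC = 2000), loci = loci2)
  res2 <- altitude_association(p2, "additive")
  expect_true(is.na(res2$p_value[res2$locus == "L2"]))
})

test_that("association p-values are uniform under the null", {
  set.seed(55)
  n <- 1000
  pops <- paste0("P", sprintf("%02d", 1:10))
  alts <- setNames(seq(100, 4500, length.out = 10), pops)
  dos <- matrix(rbinom(n * 19, 2, 0.35), n, 19)
  storage.mode(dos) <- "integer"
  panel <- make_panel(dos, sample(pops, n, replace = TRUE), alts,
                      loci = default_panel())
  for (mode in c("additive", "dominant", "recessive")) {
    res <- altitude_association(panel, mode)
    ks <- suppressWarnings(ks.test(res$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("additive signal at core loci dominates background loci", {
  spec <- sim_panel_spec(n_populations = 10, samples_per_pop = 60,
                         altitudes = round(seq(100, 4500, length.out = 10)),
                         missing_rate = 0.02, seed = 71)
  panel <- simulate_panel(spec)$panel
  res <- altitude_association(panel, "additive")
  core_lp <- -log10(res$p_value[panel$loci$core])
  # polymorphic loci outside the introgressed block (background clusters)
  bg_idx <- c(9, 10, 14, 15, 16)
  bg_lp <- -log10(res$p_value[bg_idx])
  expect_gt(min(core_lp), max(bg_lp))
})

test_that("additive coding agrees with frequency-level regression on HWE data", {
  # exact Hardy-Weinberg genotype counts per population: within-population
  # dosage mean is 2p, so the dosage-altitude covariance equals the
  # frequency-altitude covariance; slopes differ by the variance ratio
  freqs <- c(0.1, 0.3, 0.5); alts <- c(AAA = 200, BBB = 2200, CCC = 4200)
  n_pop <- 50
  dos <- integer(0); pop <- character(0)
  for (i in 1:3) {
    pf <- freqs[i]
    counts <- round(n_pop * c(pf^2, 2 * pf * (1 - pf), (1 - pf)^2))
    counts[3] <- n_pop - sum(counts[1:2])
    dos <- c(dos, rep(c(2L, 1L, 0L), counts))
    pop <- c(pop, rep(names(alts)[i], n_pop))
  }
  panel <- make_panel(matrix(dos, ncol = 1), pop, alts,
                      loci = locus_table("L1", "A", "G"))
  ind <- altitude_association(panel, "additive")
  byp <- altitude_association(panel, "additive", by_population = TRUE)
  alt_s <- alts[pop]
  g <- as.numeric(dos)
  gm <- tapply(g, pop, mean)[names(alts)]
  # identical covariances => beta_ind * var(g) == beta_pop * var(group means)
  v_ind <- mean((g - mean(g))^2)
  v_pop <- mean((gm - mean(gm))^2)
  expect_equal(ind$beta * v_ind, byp$beta * v_pop, tolerance = 1e-9)
})

test_that("region summaries average posterior sigma per deme", {
  sam <- array(0, c(100, 2, 4), dimnames = list(NULL, c("d1", "d2"), NULL))
  sam[, 1, ] <- rep(c(110, 110, 1, 1), each = 100)
  sam[, 2, ] <- 1
  fit <- structure(list(sigma_samples = sam), class = "selection_fit")
  rs <- region_summary(fit, list(r1 = 1:2, r2 = 3:4))
  expect_equal(rs["d1", "r1"], 110)
  expect_equal(rs["d1", "r2"], 1)
  expect_true(all(rs["d2", ] == 1))
  expect_gt(rs["d1", "r1"], rs["d1", "r2"])
  # single-locus regions equal the per-locus values; empty regions error
  rs2 <- region_summary(fit, list(a = 1, b = 3))
  expect_equal(unname(rs2["d1", ]), c(110, 1))
  expect_error(region_summary(fit, list(a = integer(0))), "empty")
  expect_error(region_summary(fit, list(a = 1:2, b = 2:3)), "overlap")
})
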