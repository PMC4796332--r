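test_that("deterministic selection update matches hand algebra and fixes boundaries", {
  fit <- fitness_model("additive", 0)
  for (p in c(0, 0.2, 0.5, 1)) expect_equal(selection_update(p, fit), p)
  expect_equal(selection_update(0, fitness_model("additive", 0.5)), 0)
  expect_equal(selection_update(1, fitness_model("recessive", 0.5)), 1)
  # hand evaluation, additive s = 0.01 at p = 0.05
  s <- 0.01; p <- 0.05
  num <- p^2 * (1 + s) + p * (1 - p) * (1 + s / 2)
  den <- p^2 * (1 + s) + 2 * p * (1 - p) * (1 + s / 2) + (1 - p)^2
  expect_equal(selection_update(p, fitness_model("additive", s)), num / den,
               tolerance = 1e-12)
  # dominant / recessive hand checks
  expect_equal(selection_update(0.3, fitness_model("dominant", 0.1)),
               (0.09 * 1.1 + 0.21 * 1.1) / (0.09 * 1.1 + 0.42 * 1.1 + 0.49),
               tolerance = 1e-12)
})

test_that("one Wright-Fisher generation is binomial resampling around the update", {
  set.seed(77)
  expect_equal(wf_generation(0, 100, fitness_model("additive", 0.1)), 0)
  expect_equal(wf_generation(1, 100, fitness_model("additive", 0.1)), 1)
  # huge N, no selection: frequency barely moves
  moves <- replicate(20, abs(wf_generation(0.4, 1e7, fitness_model("additive", 0)) - 0.4))
  expect_true(mean(moves < 1e-3) > 0.95)
  # distribution check: counts over many draws match Binomial(2N, p')
  N <- 10; p <- 0.3; fit <- fitness_model("additive", 0.2)
  p_exp <- selection_update(p, fit)
  draws <- replicate(30000, wf_generation(p, N, fit)) * 2 * N
  obs <- tabulate(draws + 1, nbins = 2 * N + 1)
  expected <- dbinom(0:(2 * N), 2 * N, p_exp) * 30000
  keep <- expected > 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi, qchisq(0.99, sum(keep) - 1))
})

test_that("neutral scenarios keep the martingale mean and copy state at the split", {
  scen <- sim_scenario(split_years = 2800, p0 = 0.05, sigma = 0,
                       replicates = 100, seed = 3)
  res <- run_scenario(scen)
  se <- sqrt(0.05 * 0.95 / (2 * 1000)) + 0.05 / sqrt(100)
  expect_lt(abs(res$summary$mean_final[1] - 0.05), 3 * se)
  expect_lt(abs(res$summary$mean_final[2] - 0.05), 3 * se)
  # both daughters start at the identical split frequency in every replicate
  expect_equal(res$trajectories[, 1, 1], res$trajectories[, 2, 1])
})

test_that("frequencies stay in [0,1] and absorption is permanent", {
  scen <- sim_scenario(split_years = 10000, p0 = 0.1, sigma = 118,
                       replicates = 20, seed = 9)
  res <- run_scenario(scen)
  expect_true(all(res$trajectories >= 0 & res$trajectories <= 1))
  for (r in 1:20) {
    tr <- res$trajectories[r, 2, ]
    hit1 <- which(tr == 1)
    if (length(hit1)) expect_true(all(tr[hit1[1]:length(tr)] == 1))
    hit0 <- which(tr == 0)
    if (length(hit0)) expect_true(all(tr[hit0[1]:length(tr)] == 0))
  }
})

test_that("strong selection fixes the derived allele within 1000 generations", {
  # deterministic recursion: time to reach 0.99 from 0.1 at the additive
  # heterozygote rate s/2 is about (2/s) * log((0.99*0.9)/(0.01*0.1))
  scen <- sim_scenario(split_years = 30000, p0 = 0.1, sigma = 118,
                       replicates = 60, seed = 13)
  s <- scen$sigma / (2 * scen$pop2_Ne)
  t99 <- (2 / s) * log((0.99 * 0.9) / (0.01 * 0.1))
  expect_lt(t99, scen$n_generations)
  res <- run_scenario(scen)
  expect_gt(mean(!is.na(res$fixation_generation)), 0.95)
  # and the deterministic recursion predicts the sweep midpoint well
  p <- 0.1; fit <- fitness_model("additive", s)
  det <- numeric(scen$n_generations)
  for (g in seq_len(scen$n_generations)) { p <- selection_update(p, fit); det[g] <- p }
  t50_det <- which(det >= 0.5)[1]
  med_traj <- apply(res$trajectories[, 2, -1], 2, median)
  t50_sim <- which(med_traj >= 0.5)[1]
  expect_lt(abs(t50_sim - t50_det), 0.5 * t50_det)
})

test_that("neutral heterozygosity decays like (1 - 1/2N)^t", {
  set.seed(17)
  N <- 50; t_max <- 40; reps <- 400; p0 <- 0.5
  fit <- fitness_model("additive", 0)
  H <- matrix(0, reps, t_max)
  for (r in seq_len(reps)) {
    p <- p0
    for (t in seq_len(t_max)) {
      p <- wf_generation(p, N, fit)
      H[r, t] <- 2 * p * (1 - p)
    }
  }
  h_obs <- colMeans(H)
  h_theory <- 2 * p0 * (1 - p0) * (1 - 1 / (2 * N))^(1:t_max)
  h_se <- apply(H, 2, sd) / sqrt(reps)
  covered <- abs(h_obs - h_theory) < 3 * h_se + 1e-6
  expect_gt(mean(covered), 0.9)
})

test_that("the large-N mean trajectory converges to the deterministic recursion", {
  set.seed(29)
  N <- 1e6; s <- 0.02; fit <- fitness_model("additive", s)
  p_sim <- 0.05; p_det <- 0.05; dev <- 0
  for (g in 1:200) {
    p_sim <- wf_generation(p_sim, N, fit)
    p_det <- selection_update(p_det, fit)
    dev <- max(dev, abs(p_sim - p_det))
  }
  expect_lt(dev, 0.01)
})

test_that("the scenario grid is monotone in p0 under selection and flat without", {
  g <- scenario_grid(p0_set = c(0.01, 0.05, 0.1), split_set = 2800,
                     sigma = 118, replicates = 40, seed = 21)
  expect_true(all(diff(g$mean_final) > 0))
  g0 <- scenario_grid(p0_set = c(0.05, 0.2), split_set = 2800, sigma = 0,
                      replicates = 60, seed = 22)
  expect_lt(abs(g0$mean_final[1] - 0.05), 0.03)
  expect_lt(abs(g0$mean_final[2] - 0.2), 0.05)
  # a singleton grid equals the corresponding single scenario run
  g1 <- scenario_grid(p0_set = 0.05, split_set = 2800, sigma = 50,
                      replicates = 10, seed = 5)
  single <- run_scenario(sim_scenario(split_years = 2800, p0 = 0.05,
                                      sigma = 50, replicates = 10,
                                      seed = himalhap:::derive_seed(5, 1)))
  expect_equal(g1$mean_final, single$summary$mean_final[2])
})

test_that("generation counts follow the 30-year convention", {
  expect_equal(sim_scenario(split_years = 2800)$n_generations, 93L)
  expect_equal(sim_scenario(split_years = 10000)$n_generations, 333L)
  expect_equal(sim_scenario(split_years = 30000)$n_generations, 1000L)
})
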