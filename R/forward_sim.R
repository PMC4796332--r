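#' Deterministic one-generation selection update
#'
#' Expected next-generation derived-allele frequency under random mating
#' (Hardy-Weinberg proportions within a generation):
#' `p' = (p^2*wAA + p(1-p)*wAa) / (p^2*wAA + 2p(1-p)*wAa + (1-p)^2*waa)`.
#' Fixed states (p = 0 or 1) are absorbing; with no selection `p' = p`.
#'
#' @param p derived-allele frequency in `[0, 1]` (vectorized).
#' @param fitness a [fitness_model()].
#' @return expected next-generation frequency.
#' @export
selection_update <- function(p, fitness) {
  w <- fitness$fitness
  num <- p^2 * w[["AA"]] + p * (1 - p) * w[["Aa"]]
  den <- p^2 * w[["AA"]] + 2 * p * (1 - p) * w[["Aa"]] + (1 - p)^2 * w[["aa"]]
  out <- ifelse(den > 0, num / den, p)
  ifelse(p <= 0, 0, ifelse(p >= 1, 1, out))
}

#' One Wright-Fisher generation
#'
#' Binomial resampling of 2N chromosomes around the post-selection expected
#' frequency: `k ~ Binomial(2N, selection_update(p))`, returning `k / 2N`.
#'
#' @param p current frequency.
#' @param N diploid population size (>= 2).
#' @param fitness a [fitness_model()].
#' @return next-generation frequency.
#' @export
wf_generation <- function(p, N, fitness) {
  stopifnot(N >= 2)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  stats::rbinom(1L, 2L * N, selection_update(p, fitness)) / (2 * N)
}

#' Define a two-population split scenario
#'
#' An ancestral population evolves for a fixed spin-up, splits into two
#' daughter populations (a lowland and a highland proxy), and selection on
#' the derived allele acts only in the selected population after the split.
#' The number of post-split generations is `round(split_years / generation_years)`
#' (2800 y -> 93, 10000 y -> 333, 30000 y -> 1000 at 30 y/generation).
#' Selection strength is supplied as the scaled coefficient `sigma`; the
#' per-generation coefficient is recovered as `s = sigma / (2 * Ne)` of the
#' selected population, keeping sigma the invariant across size configs.
#' Effective sizes default to documented stand-ins: ancestral and lowland
#' populations at 10000, the selected highland population at 1000 — the
#' small-isolate picture under which a scaled coefficient near 118 drives a
#' sweep on the observed timescale. Piecewise-constant schedules may be
#' given as functions of generation index.
#'
#' @param split_years years before present of the population split
#'   (typically 2800, 10000 or 30000).
#' @param p0 initial derived frequency before the split, in (0, 1).
#' @param sigma scaled selection coefficient in the selected population.
#' @param mode fitness mode for the selected population.
#' @param generation_years years per generation.
#' @param ancestral_Ne,pop1_Ne,pop2_Ne diploid effective sizes; `pop1_Ne`
#'   and `pop2_Ne` may be functions of generation index (1-based, post-split)
#'   returning a size.
#' @param selected_pop which daughter population experiences selection
#'   (1 or 2; 2 = the highland proxy by convention).
#' @param ancestral_generations neutral spin-up generations before the split.
#' @param replicates number of replicate trajectories.
#' @param seed scenario seed; each replicate runs on a derived substream.
#' @return list with class `sim_scenario`.
#' @export
sim_scenario <- function(split_years = 2800, p0 = 0.05, sigma = 118,
                         mode = "additive", generation_years = 30,
                         ancestral_Ne = 10000, pop1_Ne = 10000, pop2_Ne = 1000,
                         selected_pop = 2L, ancestral_generations = 20L,
                         replicates = 100L, seed = 1L) {
  stopifnot(p0 > 0, p0 < 1, sigma >= 0, ancestral_Ne >= 2)
  n_gen <- max(1L, as.integer(round(split_years / generation_years)))
  structure(list(split_years = split_years, generation_years = generation_years,
                 n_generations = n_gen, p0 = p0, sigma = sigma, mode = mode,
                 ancestral_Ne = ancestral_Ne, pop1_Ne = pop1_Ne,
                 pop2_Ne = pop2_Ne, selected_pop = as.integer(selected_pop),
                 ancestral_generations = as.integer(ancestral_generations),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @noRd
size_at <- function(Ne, g) {
  if (is.function(Ne)) Ne(g) else Ne
}

#' Run a two-population forward simulation scenario
#'
#' Each replicate: the ancestral population drifts neutrally to the split;
#' both daughters start at the identical split frequency; each daughter then
#' iterates [wf_generation()] for `n_generations`, with the fitness model
#' applied only in the selected population. Replicates use derived seed
#' substreams, so any replicate is reproducible in isolation.
#'
#' @param scen a [sim_scenario()].
#' @return a `sim_result`: `trajectories` (array replicate x population x
#'   generation, generation 0 = split state), `fixation_generation` /
#'   `loss_generation` per replicate for the selected population (NA if not
#'   absorbed), and `summary` (per population: mean and 2.5/97.5% quantiles
#'   of final frequency).
#' @export
run_scenario <- function(scen) {
  stopifnot(inherits(scen, "sim_scenario"))
  G <- scen$n_generations
  R <- scen$replicates
  s_sel <- scen$sigma / (2 * size_at(if (scen$selected_pop == 1L) scen$pop1_Ne else scen$pop2_Ne, 1L))
  fit_sel <- fitness_model(scen$mode, s_sel)
  fit_neu <- fitness_model(scen$mode, 0)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  traj <- array(NA_real_, c(R, 2L, G + 1L),
                dimnames = list(NULL, c("pop1", "pop2"), NULL))
  fix_gen <- rep(NA_integer_, R)
  loss_gen <- rep(NA_integer_, R)

  for (r in seq_len(R)) {
    set.seed(derive_seed(scen$seed, r))
    p <- scen$p0
    for (g in seq_len(scen$ancestral_generations)) {
      p <- wf_generation(p, scen$ancestral_Ne, fit_neu)
    }
    p1 <- p; p2 <- p                       # split copies state
    traj[r, , 1L] <- c(p1, p2)
    for (g in seq_len(G)) {
      f1 <- if (scen$selected_pop == 1L) fit_sel else fit_neu
      f2 <- if (scen$selected_pop == 2L) fit_sel else fit_neu
      p1 <- wf_generation(p1, size_at(scen$pop1_Ne, g), f1)
      p2 <- wf_generation(p2, size_at(scen$pop2_Ne, g), f2)
      traj[r, , g + 1L] <- c(p1, p2)
    }
    sel_traj <- traj[r, scen$selected_pop, ]
    if (any(sel_traj == 1)) fix_gen[r] <- which(sel_traj == 1)[1L] - 1L
    if (any(sel_traj == 0)) loss_gen[r] <- which(sel_traj == 0)[1L] - 1L
  }

  final <- traj[, , G + 1L, drop = FALSE][, , 1L]
  if (R == 1L) final <- matrix(final, 1L, 2L, dimnames = list(NULL, c("pop1", "pop2")))
  summary <- data.frame(
    population = c("pop1", "pop2"),
    mean_final = colMeans(final),
    q2.5 = apply(final, 2L, stats::quantile, 0.025),
    q97.5 = apply(final, 2L, stats::quantile, 0.975),
    prop_fixed = colMeans(final == 1),
    row.names = NULL)
  structure(list(trajectories = traj, fixation_generation = fix_gen,
                 loss_generation = loss_gen, summary = summary,
                 scenario = scen),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d replicates, %d generations post-split (split %g y)\n",
              x$scenario$replicates, x$scenario$n_generations,
              x$scenario$split_years))
  print(x$summary)
  invisible(x)
}

#' Final-frequency summaries over a grid of scenarios
#'
#' Runs [run_scenario()] for every combination of initial frequency and
#' split time, summarising the selected population's final frequency.
#'
#' @param p0_set initial derived frequencies (e.g. `c(0.01, 0.05, 0.1)`).
#' @param split_set split times in years (e.g. `c(2800, 10000, 30000)`).
#' @param sigma scaled selection coefficient in the selected population.
#' @param mode fitness mode.
#' @param replicates replicates per cell.
#' @param seed base seed; each cell derives its own substream.
#' @param ... further arguments to [sim_scenario()].
#' @return data.frame: `p0`, `split_years`, `mean_final`, `q2.5`, `q97.5`,
#'   `prop_fixed` for the selected population.
#' @export
scenario_grid <- function(p0_set = c(0.01, 0.05, 0.1),
                          split_set = c(2800, 10000, 30000),
                          sigma = 118, mode = "additive",
                          replicates = 100L, seed = 1L, ...) {
  stopifnot(length(p0_set) >= 1L, length(split_set) >= 1L)
  cells <- expand.grid(p0 = p0_set, split_years = split_set)
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    scen <- sim_scenario(split_years = cells$split_years[ci], p0 = cells$p0[ci],
                         sigma = sigma, mode = mode, replicates = replicates,
                         seed = derive_seed(seed, ci), ...)
    res <- run_scenario(scen)
    sel <- res$summary[res$scenario$selected_pop, ]
    data.frame(p0 = cells$p0[ci], split_years = cells$split_years[ci],
               mean_final = sel$mean_final, q2.5 = sel$q2.5,
               q97.5 = sel$q97.5, prop_fixed = sel$prop_fixed)
  })
  do.call(rbind, rows)
}
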