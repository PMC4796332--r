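#' Genotype-to-fitness map
#'
#' Relative fitnesses for the derived allele A against ancestral a with
#' advantage `w`: additive (AA: 1+w, Aa: 1+w/2, aa: 1), dominant
#' (AA = Aa: 1+w, aa: 1) or recessive (AA: 1+w, Aa = aa: 1).
#'
#' @param mode one of `"additive"`, `"dominant"`, `"recessive"`.
#' @param w selective advantage, >= 0.
#' @return list with class `fitness_model`: `mode`, `w` and `fitness`
#'   (named vector `AA`, `Aa`, `aa`).
#' @export
fitness_model <- function(mode = c("additive", "dominant", "recessive"), w = 0) {
  mode <- match.arg(mode)
  stopifnot(w >= 0)
  fitness <- switch(mode,
    additive  = c(AA = 1 + w, Aa = 1 + w / 2, aa = 1),
    dominant  = c(AA = 1 + w, Aa = 1 + w,     aa = 1),
    recessive = c(AA = 1 + w, Aa = 1,         aa = 1))
  structure(list(mode = mode, w = w, fitness = fitness),
            class = "fitness_model")
}

# log of Kummer's confluent hypergeometric 1F1(a; c; x), x >= 0,
# by log-sum-exp over the series -- stable up to very large x
#' @noRd
log1F1 <- function(a, c, x) {
  if (x < 0) stop("log1F1 requires x >= 0")
  if (x == 0) return(0)
  K <- max(200L, ceiling(x + 12 * sqrt(x) + 60))
  k <- 0:K
  terms <- lgamma(a + k) - lgamma(a) - (lgamma(c + k) - lgamma(c)) +
    k * log(x) - lgamma(k + 1)
  logsumexp(terms)
}

#' Stationary log-density of allele frequency under the island model
#'
#' The diffusion stationary distribution for the derived-allele frequency
#' in one deme of Wright's island model with genic selection:
#' `pi(p) ∝ p^(M*pi_tilde - 1) * (1-p)^(M*(1-pi_tilde) - 1) * exp(sigma*p)`,
#' where `M` is the scaled migration rate, `pi_tilde` the migrant-pool
#' derived-allele frequency and `sigma = 2*Ne*s` the scaled selection
#' coefficient. The normalizing constant is
#' `B(a, b) * 1F1(a; a + b; sigma)` with `a = M*pi_tilde`,
#' `b = M*(1 - pi_tilde)`, evaluated by a log-sum-exp series so the density
#' is usable at sigma of order 100. At `sigma = 0` it reduces exactly to
#' the Beta(a, b) log-density.
#'
#' @param p allele frequency strictly inside (0, 1) (callers must reflect
#'   boundary values).
#' @param M scaled migration rate, > 0.
#' @param pi_tilde migrant-pool frequency in (0, 1).
#' @param sigma scaled selection coefficient, >= 0.
#' @return log density (integrates to 1 over (0, 1)).
#' @export
stationary_log_density <- function(p, M, pi_tilde, sigma) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  stopifnot(M > 0, pi_tilde > 0, pi_tilde < 1, sigma >= 0)
  a <- M * pi_tilde
  b <- M * (1 - pi_tilde)
  (a - 1) * log(p) + (b - 1) * log1p(-p) + sigma * p -
    (lbeta(a, b) + log1F1(a, a + b, sigma))
}

# unnormalized kernel (for p-updates, where the normalizer is constant)
#' @noRd
stationary_log_kernel <- function(p, a, b, sigma) {
  (a - 1) * log(p) + (b - 1) * log1p(-p) + sigma * p
}

#' @noRd
log_normalizer <- function(a, b, sigma) {
  lbeta(a, b) + log1F1(a, a + b, sigma)
}

#' Fit deme- and locus-specific scaled selection coefficients
#'
#' Hierarchical Bayesian inference of sigma_ij = 2*N_i*s_ij from per-deme
#' derived-allele counts, by component-wise Metropolis-within-Gibbs.
#' Model: counts k_ij ~ Binomial(n_ij, p_ij); p_ij follows the island-model
#' stationary density ([stationary_log_density()]) with shared scaled
#' migration rate M (log-uniform prior on `[0.1, 1000]`), per-locus
#' migrant-pool frequency pi_tilde_j (uniform prior) and sigma_ij with an
#' Exponential(delta_j) prior whose rate gets a conjugate Gamma hyper-prior
#' (Gibbs-updated). Short pilot runs adapt random-walk proposal widths
#' toward 25-45% acceptance before the burn-in.
#'
#' @param derived_counts integer matrix demes x loci of derived-allele counts.
#' @param total_counts matrix of total allele counts (chromosomes sampled).
#' @param pilot_runs,pilot_len number and length of adaptation runs.
#' @param burn_in discarded iterations after adaptation.
#' @param thin keep one sample every `thin` iterations.
#' @param n_samples posterior samples to retain.
#' @param seed RNG seed.
#' @param fix_M,fix_pi_tilde optionally freeze hyper-parameters at given
#'   values (useful for validation against numerical posteriors).
#' @param fix_delta optionally freeze the Exponential rate on sigma.
#' @param delta_hyper shape/rate of the Gamma hyper-prior on delta_j.
#' @return a `selection_fit`: posterior summary data.frame (`deme`, `locus`,
#'   `mean`, `median`, `q2.5`, `q97.5`, `ess`), acceptance rates, retained
#'   sigma samples (array samples x demes x loci) and the run settings.
#' @export
fit_selection <- function(derived_counts, total_counts,
                          pilot_runs = 25L, pilot_len = 1000L,
                          burn_in = 25000L, thin = 25L, n_samples = 1000L,
                          seed = 1L, fix_M = NULL, fix_pi_tilde = NULL,
                          fix_delta = NULL, delta_hyper = c(shape = 1, rate = 1)) {
  k <- as.matrix(derived_counts); n <- as.matrix(total_counts)
  stopifnot(all(dim(k) == dim(n)), all(k >= 0), all(n > 0), all(k <= n),
            nrow(k) >= 2L)
  D <- nrow(k); L <- ncol(k)
  deme_names <- rownames(k) %||% paste0("deme", seq_len(D))
  locus_names <- colnames(k) %||% paste0("locus", seq_len(L))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  clamp <- function(x, lo = 1e-6, hi = 1 - 1e-6) pmin(pmax(x, lo), hi)

  # state
  p <- clamp((k + 0.5) / (n + 1))
  sigma <- matrix(1, D, L)
  pi_t <- if (is.null(fix_pi_tilde)) clamp(colSums(k) / colSums(n)) else
    rep_len(fix_pi_tilde, L)
  M <- fix_M %||% 10
  delta <- if (is.null(fix_delta)) rep(0.1, L) else rep_len(fix_delta, L)

  # proposal sds
  sd_p <- matrix(0.5, D, L); sd_sig <- matrix(5, D, L)
  sd_pi <- rep(0.3, L); sd_M <- 0.5

  logit <- function(x) log(x / (1 - x))
  inv_logit <- function(x) 1 / (1 + exp(-x))

  # cached per-locus normalizers: logZ[i, j] for current (M, pi_t[j], sigma[i, j])
  logZ <- matrix(0, D, L)
  recompute_Z <- function() {
    for (j in seq_len(L)) {
      a <- M * pi_t[j]; b <- M * (1 - pi_t[j])
      for (i in seq_len(D)) logZ[i, j] <<- log_normalizer(a, b, sigma[i, j])
    }
  }
  recompute_Z()

  acc <- list(p = 0, sigma = 0, pi = 0, M = 0)
  try_n <- list(p = 0, sigma = 0, pi = 0, M = 0)

  sweep_once <- function() {
    a_vec <- M * pi_t; b_vec <- M * (1 - pi_t)
    # p updates (normalizer constant in p)
    for (j in seq_len(L)) {
      for (i in seq_len(D)) {
        cur <- p[i, j]
        prop <- inv_logit(logit(cur) + stats::rnorm(1, 0, sd_p[i, j]))
        prop <- clamp(prop)
        ll_cur <- stats::dbinom(k[i, j], n[i, j], cur, log = TRUE) +
          stationary_log_kernel(cur, a_vec[j], b_vec[j], sigma[i, j]) +
          log(cur) + log1p(-cur)          # logit-scale jacobian
        ll_prop <- stats::dbinom(k[i, j], n[i, j], prop, log = TRUE) +
          stationary_log_kernel(prop, a_vec[j], b_vec[j], sigma[i, j]) +
          log(prop) + log1p(-prop)
        try_n$p <<- try_n$p + 1
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          p[i, j] <<- prop; acc$p <<- acc$p + 1
        }
      }
    }
    # sigma updates (reflected random walk at 0)
    for (j in seq_len(L)) {
      for (i in seq_len(D)) {
        cur <- sigma[i, j]
        prop <- abs(cur + stats::rnorm(1, 0, sd_sig[i, j]))
        Zp <- log_normalizer(a_vec[j], b_vec[j], prop)
        ll_cur <- sigma_llik(p[i, j], a_vec[j], b_vec[j], cur, logZ[i, j], delta[j])
        ll_prop <- sigma_llik(p[i, j], a_vec[j], b_vec[j], prop, Zp, delta[j])
        try_n$sigma <<- try_n$sigma + 1
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          sigma[i, j] <<- prop; logZ[i, j] <<- Zp; acc$sigma <<- acc$sigma + 1
        }
      }
    }
    # pi_tilde updates
    if (is.null(fix_pi_tilde)) {
      for (j in seq_len(L)) {
        cur <- pi_t[j]
        prop <- clamp(inv_logit(logit(cur) + stats::rnorm(1, 0, sd_pi[j])))
        ap <- M * prop; bp <- M * (1 - prop)
        Zp <- vapply(seq_len(D), function(i) log_normalizer(ap, bp, sigma[i, j]), 0)
        ll_cur <- sum(stationary_log_kernel(p[, j], M * cur, M * (1 - cur), sigma[, j]) -
                        logZ[, j]) + log(cur) + log1p(-cur)
        ll_prop <- sum(stationary_log_kernel(p[, j], ap, bp, sigma[, j]) - Zp) +
          log(prop) + log1p(-prop)
        try_n$pi <<- try_n$pi + 1
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          pi_t[j] <<- prop; logZ[, j] <<- Zp; acc$pi <<- acc$pi + 1
        }
      }
    }
    # M update (log-scale walk, log-uniform prior on [0.1, 1000])
    if (is.null(fix_M)) {
      prop <- exp(log(M) + stats::rnorm(1, 0, sd_M))
      try_n$M <<- try_n$M + 1
      if (prop >= 0.1 && prop <= 1000) {
        Zp <- matrix(0, D, L)
        ll_cur <- 0; ll_prop <- 0
        for (j in seq_len(L)) {
          ac <- M * pi_t[j]; bc <- M * (1 - pi_t[j])
          ap <- prop * pi_t[j]; bp <- prop * (1 - pi_t[j])
          for (i in seq_len(D)) {
            Zp[i, j] <- log_normalizer(ap, bp, sigma[i, j])
            ll_cur <- ll_cur + stationary_log_kernel(p[i, j], ac, bc, sigma[i, j]) - logZ[i, j]
            ll_prop <- ll_prop + stationary_log_kernel(p[i, j], ap, bp, sigma[i, j]) - Zp[i, j]
          }
        }
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          M <<- prop; logZ <<- Zp; acc$M <<- acc$M + 1
        }
      }
    }
    # delta Gibbs update
    if (is.null(fix_delta)) {
      for (j in seq_len(L)) {
        delta[j] <<- stats::rgamma(1, shape = delta_hyper[["shape"]] + D,
                                   rate = delta_hyper[["rate"]] + sum(sigma[, j]))
      }
    }
  }

  sigma_llik <- function(pv, a, b, sig, lz, del) {
    stationary_log_kernel(pv, a, b, sig) - lz + stats::dexp(sig, del, log = TRUE)
  }

  adapt <- function(rate, sd) {
    if (is.nan(rate)) return(sd)
    if (rate < 0.25) sd * 0.8 else if (rate > 0.45) sd * 1.25 else sd
  }

  for (pr in seq_len(pilot_runs)) {
    acc <- list(p = 0, sigma = 0, pi = 0, M = 0)
    try_n <- list(p = 0, sigma = 0, pi = 0, M = 0)
    for (it in seq_len(pilot_len)) sweep_once()
    sd_p[] <- adapt(acc$p / max(try_n$p, 1), sd_p[1, 1])
    sd_sig[] <- adapt(acc$sigma / max(try_n$sigma, 1), sd_sig[1, 1])
    sd_pi[] <- adapt(acc$pi / max(try_n$pi, 1), sd_pi[1])
    sd_M <- adapt(acc$M / max(try_n$M, 1), sd_M)
  }

  acc <- list(p = 0, sigma = 0, pi = 0, M = 0)
  try_n <- list(p = 0, sigma = 0, pi = 0, M = 0)
  for (it in seq_len(burn_in)) sweep_once()

  sig_samples <- array(NA_real_, c(n_samples, D, L),
                       dimnames = list(NULL, deme_names, locus_names))
  M_samples <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    for (it in seq_len(thin)) sweep_once()
    sig_samples[s, , ] <- sigma
    M_samples[s] <- M
  }

  summaries <- do.call(rbind, lapply(seq_len(D), function(i) {
    do.call(rbind, lapply(seq_len(L), function(j) {
      x <- sig_samples[, i, j]
      data.frame(deme = deme_names[i], locus = locus_names[j],
                 mean = mean(x), median = stats::median(x),
                 q2.5 = unname(stats::quantile(x, 0.025)),
                 q97.5 = unname(stats::quantile(x, 0.975)),
                 ess = ess_estimate(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summaries) <- NULL
  low_ess <- summaries$ess < 50
  if (any(low_ess)) {
    warning(sprintf("effective sample size < 50 for %d sigma component(s); consider longer runs",
                    sum(low_ess)))
  }

  structure(list(
    summary = summaries,
    sigma_samples = sig_samples,
    M_samples = M_samples,
    acceptance = vapply(names(acc), function(nm) acc[[nm]] / max(try_n[[nm]], 1), 0),
    settings = list(pilot_runs = pilot_runs, pilot_len = pilot_len,
                    burn_in = burn_in, thin = thin, n_samples = n_samples,
                    seed = seed)),
    class = "selection_fit")
}

# initial-monotone-sequence flavoured ESS from the autocorrelation function
#' @noRd
ess_estimate <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1L] - 1L else length(ac)
  tau <- 1 + 2 * sum(ac[seq_len(cut)])
  max(1, n / max(tau, 1))
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("selection_fit: %d demes x %d loci, %d posterior samples\n",
              dim(x$sigma_samples)[2L], dim(x$sigma_samples)[3L],
              dim(x$sigma_samples)[1L]))
  cat("acceptance rates: ",
      paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Genotype-altitude association per locus
#'
#' Ordinary least-squares regression of residence altitude (the quantitative
#' phenotype) on genotype, coded by fitness-model mode: additive = dosage
#' 0/1/2, dominant = carrier indicator (dosage >= 1), recessive = homozygote
#' indicator (dosage = 2). Missing dosages are dropped per locus. With
#' `by_population = TRUE` the regression is on population mean coded
#' genotype, weighted by sample count.
#'
#' @param panel a `genotype_panel`; per-sample altitude is joined from the
#'   panel's population table.
#' @param mode genotype coding (`"additive"`, `"dominant"`, `"recessive"`).
#' @param by_population population-level weighted regression instead of
#'   individual-level.
#' @return data.frame: `locus`, `beta`, `se`, `t`, `p_value`, `n`,
#'   `p_bonferroni`. Monomorphic loci give an NA row; degenerate perfect
#'   fits are floored at `p = 1e-300`.
#' @export
altitude_association <- function(panel, mode = c("additive", "dominant", "recessive"),
                                 by_population = FALSE) {
  mode <- match.arg(mode)
  alt <- panel$populations$altitude_m[
    match(panel$samples$population, panel$populations$code)]
  if (length(unique(alt)) < 3L) stop("need >= 3 distinct altitude values")
  dos <- panel$dosages
  code <- switch(mode,
    additive = dos,
    dominant = (dos >= 1L) * 1L,
    recessive = (dos == 2L) * 1L)

  rows <- lapply(seq_len(ncol(dos)), function(j) {
    g <- code[, j]; y <- alt
    ok <- !is.na(g)
    g <- g[ok]; y <- y[ok]
    if (by_population) {
      pops <- panel$samples$population[ok]
      gm <- tapply(g, pops, mean)
      ym <- panel$populations$altitude_m[match(names(gm), panel$populations$code)]
      wm <- as.numeric(table(pops)[names(gm)])
      g <- as.numeric(gm); y <- ym; w <- wm
    } else {
      w <- rep(1, length(g))
    }
    na_row <- data.frame(locus = panel$loci$id[j], beta = NA_real_,
                         se = NA_real_, t = NA_real_, p_value = NA_real_,
                         n = length(g), p_bonferroni = NA_real_,
                         stringsAsFactors = FALSE)
    if (length(unique(g)) < 2L || length(g) < 3L) return(na_row)
    # weighted OLS of y on g, computed explicitly to control degenerate fits
    W <- sum(w)
    gbar <- sum(w * g) / W; ybar <- sum(w * y) / W
    sxx <- sum(w * (g - gbar)^2)
    beta <- sum(w * (g - gbar) * (y - ybar)) / sxx
    resid <- y - ybar - beta * (g - gbar)
    df <- length(g) - 2L
    s2 <- sum(w * resid^2) / df
    if (s2 <= .Machine$double.eps * sum(w * y^2)) {
      return(data.frame(locus = panel$loci$id[j], beta = beta, se = 0,
                        t = Inf, p_value = 1e-300, n = length(g),
                        p_bonferroni = NA_real_, stringsAsFactors = FALSE))
    }
    se <- sqrt(s2 / sxx)
    tval <- beta / se
    pval <- max(2 * stats::pt(abs(tval), df, lower.tail = FALSE), 1e-300)
    data.frame(locus = panel$loci$id[j], beta = beta, se = se, t = tval,
               p_value = pval, n = length(g), p_bonferroni = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * sum(!is.na(out$p_value)), 1)
  out
}

#' Mean scaled selection coefficient per gene region
#'
#' Averages posterior-mean sigma over the loci of each region, per deme.
#' Regions must be non-empty index sets partitioning a subset of the loci.
#'
#' @param fit a `selection_fit`.
#' @param regions named list of integer locus-index vectors (see
#'   [default_regions()]).
#' @return matrix demes x regions of mean posterior-mean sigma.
#' @export
region_summary <- function(fit, regions) {
  if (any(lengths(regions) == 0L)) stop("empty region")
  all_idx <- unlist(regions)
  L <- dim(fit$sigma_samples)[3L]
  if (any(all_idx < 1L | all_idx > L)) stop("region index outside locus range")
  if (anyDuplicated(all_idx)) stop("regions must not overlap")
  post_mean <- apply(fit$sigma_samples, c(2L, 3L), mean)
  out <- vapply(regions, function(idx) {
    rowMeans(post_mean[, idx, drop = FALSE])
  }, numeric(nrow(post_mean)))
  out
}
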