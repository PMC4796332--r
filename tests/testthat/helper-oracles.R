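# Fixture builders and independent brute-force oracles. Everything here is
# written against the definitions, not against the package internals, so the
# two routes stay independent.

# quick panel: dosage matrix + one altitude per population code
make_panel <- function(dos, pop_of_sample, altitudes, loci = NULL,
                       reported_sex = "female", genotype_sex = reported_sex) {
  n <- nrow(dos)
  if (is.null(loci)) {
    L <- ncol(dos)
    loci <- locus_table(sprintf("L%02d", seq_len(L)),
                        rep("A", L), rep("G", L),
                        core = seq_len(L) <= min(5L, L))
  }
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = pop_of_sample,
    reported_sex = rep_len(reported_sex, n),
    genotype_sex = rep_len(genotype_sex, n),
    stringsAsFactors = FALSE)
  pops <- population_table(names(altitudes), "X", unname(altitudes))
  genotype_panel(loci, samples, dos, pops)
}

bits <- function(s) as.integer(strsplit(s, "")[[1]])
unbits <- function(b) paste(b, collapse = "")

# ---- phasing oracle -------------------------------------------------------

# all unordered haplotype pairs compatible with a dosage vector (NA = missing)
oracle_pairs <- function(d) {
  L <- length(d)
  base <- integer(L); base[!is.na(d) & d == 2] <- 1L
  het <- which(!is.na(d) & d == 1)
  mis <- which(is.na(d))
  slots <- c(het, mis, mis)
  combos <- if (length(slots) == 0) matrix(0L, 1, 0) else
    as.matrix(expand.grid(rep(list(0:1), length(slots))))
  out <- character(0)
  for (r in seq_len(nrow(combos))) {
    h1 <- base; h2 <- base
    v <- combos[r, ]
    if (length(het)) { h1[het] <- v[seq_along(het)]; h2[het] <- 1 - v[seq_along(het)] }
    if (length(mis)) {
      h1[mis] <- v[length(het) + seq_along(mis)]
      h2[mis] <- v[length(het) + length(mis) + seq_along(mis)]
    }
    a <- unbits(h1); b <- unbits(h2)
    out <- c(out, paste(sort(c(a, b)), collapse = "|"))
  }
  unique(out)
}

# global maximum of the phasing likelihood: enumerate every joint phase
# configuration, then polish each distinct complete-data frequency candidate
# with a plain fixed-point iteration (written out here independently of the
# package). Returns NULL when the configuration space exceeds max_configs.
oracle_max_loglik <- function(dos, max_configs = 4000) {
  pair_strs <- apply(dos, 1, oracle_pairs, simplify = FALSE)
  haps <- unique(unlist(strsplit(unlist(pair_strs), "|", fixed = TRUE)))
  pl <- lapply(pair_strs, function(ps) {
    t(vapply(strsplit(ps, "|", fixed = TRUE),
             function(h) match(h, haps), integer(2)))
  })
  n_cfg <- prod(vapply(pl, nrow, 0L))
  if (n_cfg > max_configs) return(NULL)
  cfg <- as.matrix(expand.grid(lapply(pl, function(m) seq_len(nrow(m)))))
  n2 <- 2 * nrow(dos)
  H <- length(haps)
  ll_at <- function(f) {
    sum(vapply(pl, function(m) {
      log(sum(f[m[, 1]] * f[m[, 2]] * ifelse(m[, 1] == m[, 2], 1, 2)))
    }, 0))
  }
  best <- -Inf
  seen <- character(0)
  for (r in seq_len(nrow(cfg))) {
    cnt <- numeric(H)
    for (s in seq_along(pl)) {
      ij <- pl[[s]][cfg[r, s], ]
      cnt[ij[1]] <- cnt[ij[1]] + 1
      cnt[ij[2]] <- cnt[ij[2]] + 1
    }
    key <- paste(cnt, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    f <- cnt / n2
    for (it in 1:300) {
      newc <- numeric(H)
      for (s in seq_along(pl)) {
        m <- pl[[s]]
        w <- f[m[, 1]] * f[m[, 2]] * ifelse(m[, 1] == m[, 2], 1, 2)
        sw <- sum(w)
        if (sw == 0) next
        w <- w / sw
        for (k in seq_len(nrow(m))) {
          newc[m[k, 1]] <- newc[m[k, 1]] + w[k]
          newc[m[k, 2]] <- newc[m[k, 2]] + w[k]
        }
      }
      f <- newc / n2
    }
    ll <- ll_at(f)
    if (ll > best) best <- ll
  }
  best
}

# ---- Steiner-tree oracle for the haplotype network ------------------------

oracle_mst_cost <- function(haps) {
  B <- do.call(rbind, lapply(haps, bits))
  n <- nrow(B)
  if (n == 1) return(0)
  D <- as.matrix(dist(B, method = "manhattan"))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  cost <- 0
  while (any(!in_tree)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + unname(best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  cost
}

# exact minimum Steiner-tree cost in Hamming space by the Dreyfus-Wagner
# dynamic programme over the full hypercube (L <= 10): an algorithm wholly
# unlike the median-joining heuristic it checks
oracle_steiner_cost <- function(haps) {
  L <- nchar(haps[1])
  stopifnot(L <= 10)
  V <- 2^L
  bitsv <- function(k) as.integer(intToBits(k))[1:L]
  term <- unique(vapply(haps, function(h) sum(bits(h) * 2^(0:(L - 1))), 0))
  term <- as.integer(term)
  k <- length(term)
  if (k == 1) return(0)
  popcount <- vapply(0:(V - 1), function(x) sum(bitsv(x)), 0L)
  dvu <- function(v, u) popcount[bitwXor(v, u) + 1L]
  root <- term[k]; T2 <- term[-k]; m <- k - 1
  f <- matrix(Inf, 2^m, V)
  for (i in seq_len(m)) {
    S <- bitwShiftL(1L, i - 1L)
    f[S + 1L, ] <- vapply(0:(V - 1), function(v) dvu(T2[i], v), 0)
  }
  sizes <- vapply(1:(2^m - 1), function(S) sum(as.integer(intToBits(S))[1:m]), 0L)
  for (S in (1:(2^m - 1))[order(sizes)]) {
    if (sizes[S] < 2) next
    g <- rep(Inf, V)
    sub <- bitwAnd(S - 1L, S)
    while (sub > 0) {
      if (sub <= S - sub) g <- pmin(g, f[sub + 1L, ] + f[(S - sub) + 1L, ])
      sub <- bitwAnd(sub - 1L, S)
    }
    for (v in 0:(V - 1)) {
      f[S + 1L, v + 1L] <- min(vapply(0:(V - 1), function(u) dvu(v, u), 0) + g)
    }
  }
  f[2^m, root + 1L]
}

# ---- grid-integration posterior oracle for the selection model ------------

# marginal posterior mean of sigma for ONE deme (demes factorize when the
# hyper-parameters are fixed): p integrated by quadrature, sigma on a grid
oracle_sigma_posterior_mean <- function(k, n, M, pi_t, delta,
                                        sigma_grid = seq(0, 80, by = 0.25)) {
  a <- M * pi_t; b <- M * (1 - pi_t)
  marg <- vapply(sigma_grid, function(sig) {
    kern <- function(p) p^(a - 1) * (1 - p)^(b - 1) * exp(sig * p)
    Z <- stats::integrate(kern, 0, 1, rel.tol = 1e-10)$value
    like <- stats::integrate(function(p) stats::dbinom(k, n, p) * kern(p) / Z,
                             0, 1, rel.tol = 1e-10)$value
    like * stats::dexp(sig, delta)
  }, 0)
  sum(sigma_grid * marg) / sum(marg)
}
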