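#' Phase multilocus genotypes by expectation-maximization
#'
#' Estimates population haplotype frequencies from unphased derived-allele
#' dosages by maximum likelihood under random pairing (the classic
#' multinomial EM of Excoffier & Slatkin), then assigns each sample the
#' compatible haplotype pair with the largest frequency product. The
#' likelihood is `L = prod_samples sum_{(h,k) compatible} c * f_h * f_k`
#' with `c = 2` for heterozygous pairs; missing genotypes are handled by
#' summing over every dosage completion. This is a deliberate, deterministic
#' stand-in for coalescent-informed phasing software, adequate for a short
#' panel of tightly linked SNPs.
#'
#' @param panel a `genotype_panel` (typically post-QC).
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the log-likelihood change.
#' @param n_restarts additional random-initialization restarts (the best
#'   likelihood wins); 0 = deterministic single run from frequency-weighted
#'   observed haplotypes.
#' @param seed RNG seed for restarts.
#' @param max_ambiguity cap on the per-sample enumeration cost `h + 2m`
#'   (`h` heterozygous, `m` missing sites); samples above it raise an error
#'   advising locus windowing.
#' @return a `haplotype_set`: haplotype strings (over 0/1, panel locus
#'   order), ML frequencies, hard-assignment chromosome counts, per-sample
#'   assignments with posterior probabilities, the log-likelihood trace and
#'   iteration count.
#' @export
em_phase <- function(panel, max_iter = 1000L, tol = 1e-8, n_restarts = 0L,
                     seed = 1L, max_ambiguity = 20L) {
  dos <- panel$dosages
  n <- nrow(dos)
  if (n < 1L) stop("panel has no samples")
  L <- ncol(dos)

  # group samples sharing a dosage pattern: identical likelihood terms
  keys <- apply(dos, 1L, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  u_keys <- unique(keys)
  pattern_of <- match(keys, u_keys)

  if (L > 30L) stop("panels longer than 30 loci are not supported")
  pow <- 2^(seq_len(L) - 1L)            # haplotypes packed as integer bit keys
  hap_index <- new.env(hash = TRUE, parent = emptyenv())
  hap_list <- character(0)
  get_hap_by_key <- function(key) {
    ks <- as.character(key)
    i <- hap_index[[ks]]
    if (is.null(i)) {
      i <- length(hap_list) + 1L
      hap_list[[i]] <<- bits_to_hap(as.integer(floor(key / pow) %% 2))
      hap_index[[ks]] <- i
    }
    i
  }

  pattern_pairs <- vector("list", length(u_keys))
  for (ui in seq_along(u_keys)) {
    d <- dos[match(ui, pattern_of), ]
    het <- which(!is.na(d) & d == 1L)
    mis <- which(is.na(d))
    nh <- length(het); nm <- length(mis)
    cost <- nh + 2L * nm
    if (cost > max_ambiguity) {
      stop(sprintf(
        "sample %s has ambiguity cost %d (> %d); phase the panel in locus windows",
        panel$samples$sample_id[match(ui, pattern_of)][1L], cost, max_ambiguity))
    }
    base_key <- sum(pow[!is.na(d) & d == 2L])
    nf <- nh + 2L * nm
    V <- if (nf == 0L) matrix(0L, 1L, 0L) else
      as.matrix(expand.grid(rep(list(0:1), nf), KEEP.OUT.ATTRS = FALSE))
    k1 <- rep(base_key, nrow(V)); k2 <- k1
    if (nh) {
      k1 <- k1 + as.vector(V[, seq_len(nh), drop = FALSE] %*% pow[het])
      k2 <- k2 + as.vector((1L - V[, seq_len(nh), drop = FALSE]) %*% pow[het])
    }
    if (nm) {
      k1 <- k1 + as.vector(V[, nh + seq_len(nm), drop = FALSE] %*% pow[mis])
      k2 <- k2 + as.vector(V[, nh + nm + seq_len(nm), drop = FALSE] %*% pow[mis])
    }
    kmin <- pmin(k1, k2); kmax <- pmax(k1, k2)
    keep_pair <- !duplicated(paste(kmin, kmax))
    i1 <- vapply(kmin[keep_pair], get_hap_by_key, 0L)
    i2 <- vapply(kmax[keep_pair], get_hap_by_key, 0L)
    pattern_pairs[[ui]] <- cbind(pmin(i1, i2), pmax(i1, i2))
  }
  n_hap <- length(hap_list)
  pattern_n <- tabulate(pattern_of, nbins = length(u_keys))

  run_em <- function(f0) {
    f <- f0 / sum(f0)
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      counts <- numeric(n_hap)
      ll <- 0
      for (ui in seq_along(u_keys)) {
        P <- pattern_pairs[[ui]]
        w <- f[P[, 1L]] * f[P[, 2L]] * ifelse(P[, 1L] == P[, 2L], 1, 2)
        s <- sum(w)
        if (s <= 0) stop("zero-likelihood pattern encountered (corrupt data) for sample ",
                         panel$samples$sample_id[match(ui, pattern_of)][1L])
        ll <- ll + pattern_n[ui] * log(s)
        wn <- pattern_n[ui] * w / s
        # accumulate with duplicate-safe indexing (a haplotype can appear in
        # several pairs of the same pattern)
        add <- rowsum(c(wn, wn), c(P[, 1L], P[, 2L]))
        ai <- as.integer(rownames(add))
        counts[ai] <- counts[ai] + add[, 1L]
      }
      ll_trace <- c(ll_trace, ll)
      f <- counts / (2 * n)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
      ll_prev <- ll
    }
    list(f = f, ll = ll_trace[length(ll_trace)], trace = ll_trace, iters = length(ll_trace))
  }

  # default init: unambiguous-completion counts plus a small floor so every
  # compatible haplotype stays reachable
  f0 <- rep(1e-6, n_hap)
  for (ui in seq_along(u_keys)) {
    P <- pattern_pairs[[ui]]
    if (nrow(P) == 1L) {
      f0[P[1L, 1L]] <- f0[P[1L, 1L]] + pattern_n[ui]
      f0[P[1L, 2L]] <- f0[P[1L, 2L]] + pattern_n[ui]
    }
  }
  if (sum(f0) <= n_hap * 1e-6 + 1e-12) f0 <- rep(1, n_hap)

  best <- run_em(f0)
  if (n_restarts > 0L) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      cand <- run_em(stats::rexp(n_hap))
      if (cand$ll > best$ll + 1e-12) best <- cand
    }
  }
  f <- best$f

  # hard assignments: compatible pair maximizing f_h * f_k; ties broken by
  # the lexicographically smallest (string-ordered) pair
  assign_rows <- vector("list", length(u_keys))
  for (ui in seq_along(u_keys)) {
    P <- pattern_pairs[[ui]]
    w <- f[P[, 1L]] * f[P[, 2L]] * ifelse(P[, 1L] == P[, 2L], 1, 2)
    post <- w / sum(w)
    score <- f[P[, 1L]] * f[P[, 2L]]
    top <- which(score >= max(score) - 1e-15)
    if (length(top) > 1L) {
      key <- paste(hap_list[P[top, 1L]], hap_list[P[top, 2L]])
      top <- top[order(key)][1L]
    }
    assign_rows[[ui]] <- list(h1 = hap_list[P[top, 1L]], h2 = hap_list[P[top, 2L]],
                              posterior = post[top])
  }
  assignments <- data.frame(
    sample_id = panel$samples$sample_id,
    hap1 = vapply(pattern_of, function(ui) assign_rows[[ui]]$h1, ""),
    hap2 = vapply(pattern_of, function(ui) assign_rows[[ui]]$h2, ""),
    posterior = vapply(pattern_of, function(ui) assign_rows[[ui]]$posterior, 0),
    stringsAsFactors = FALSE)

  hard_counts <- table(factor(c(assignments$hap1, assignments$hap2),
                              levels = hap_list))
  keep <- f > 1e-9 | hard_counts > 0
  ord <- order(-f[keep], hap_list[keep])
  haps <- hap_list[keep][ord]
  freqs <- f[keep][ord] / sum(f[keep])
  counts <- as.integer(hard_counts[keep][ord])

  structure(list(haplotypes = haps, frequencies = freqs, counts = counts,
                 assignments = assignments, loglik = best$ll,
                 loglik_trace = best$trace, n_iter = best$iters,
                 loci = panel$loci),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes over %d loci, %d samples, logLik %.4f (%d EM iterations)\n",
              length(x$haplotypes), nrow(x$loci), nrow(x$assignments),
              x$loglik, x$n_iter))
  invisible(x)
}

#' Switch-error rate of an inferred phasing against truth
#'
#' The standard phasing accuracy metric: across each sample's heterozygous
#' sites, the fraction of adjacent informative junctions whose relative
#' phase is inferred incorrectly. Sites are informative when heterozygous
#' in both truth and inference (missing-data completions can legitimately
#' differ). Perfect phasing scores 0; a sample needs at least two
#' informative sites to contribute.
#'
#' @param hapset a `haplotype_set` from [em_phase()].
#' @param truth data.frame with `sample_id`, `hap1`, `hap2` (allele strings).
#' @return overall switch-error fraction (total switches / total junctions);
#'   `NA` if no sample has an informative junction.
#' @export
switch_error <- function(hapset, truth) {
  a <- hapset$assignments
  m <- match(a$sample_id, truth$sample_id)
  if (anyNA(m)) stop("truth table missing samples: ",
                     paste(a$sample_id[is.na(m)], collapse = ", "))
  tot_sw <- 0L; tot_junc <- 0L
  for (i in seq_len(nrow(a))) {
    i1 <- hap_to_bits(a$hap1[i]); i2 <- hap_to_bits(a$hap2[i])
    t1 <- hap_to_bits(truth$hap1[m[i]]); t2 <- hap_to_bits(truth$hap2[m[i]])
    if (length(i1) != length(t1)) stop("haplotype length mismatch for sample ", a$sample_id[i])
    het <- which(i1 != i2 & t1 != t2)
    if (length(het) < 2L) next
    agree <- i1[het] == t1[het]
    sw <- sum(agree[-1L] != agree[-length(agree)])
    tot_sw <- tot_sw + sw
    tot_junc <- tot_junc + length(het) - 1L
  }
  if (tot_junc == 0L) return(NA_real_)
  tot_sw / tot_junc
}
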