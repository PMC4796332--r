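#' Hamming distance between two haplotype strings
#'
#' The number of positions at which two equal-length allele strings differ
#' (the mutational distance on a network edge).
#'
#' @param h1,h2 allele strings over `0`/`1`.
#' @return non-negative integer.
#' @export
hamming_distance <- function(h1, h2) {
  if (nchar(h1) != nchar(h2)) stop("haplotype length mismatch")
  sum(hap_to_bits(h1) != hap_to_bits(h2))
}

# pairwise Hamming matrix from a bit matrix (rows = haplotypes)
#' @noRd
hamming_matrix <- function(B) {
  G <- tcrossprod(B)
  s <- rowSums(B)
  D <- outer(s, s, "+") - 2 * G
  storage.mode(D) <- "integer"
  D
}

# Prim's MST over a dense distance matrix; returns total cost and edges
#' @noRd
mst_dense <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(list(cost = 0L, edges = matrix(integer(0), 0L, 2L)))
  in_tree <- logical(n); in_tree[1L] <- TRUE
  best <- D[1L, ]; parent <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L)
  cost <- 0L
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    edges[k, ] <- c(parent[v], v)
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best
    best[upd] <- D[v, upd]
    parent[upd] <- v
  }
  list(cost = cost, edges = edges)
}

# minimax connection threshold for every pair: the largest edge on the MST
# path (equals the smallest t at which the pair is connected using edges <= t)
#' @noRd
minimax_matrix <- function(D) {
  n <- nrow(D)
  mst <- mst_dense(D)
  adj <- vector("list", n)
  for (e in seq_len(nrow(mst$edges))) {
    a <- mst$edges[e, 1L]; b <- mst$edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  M <- matrix(0L, n, n)
  for (root in seq_len(n)) {
    # DFS from root carrying the running max edge weight
    stack <- root; maxw <- integer(n); visited <- logical(n); visited[root] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          maxw[w] <- max(maxw[v], D[v, w])
          stack <- c(stack, w)
        }
      }
    }
    M[root, ] <- maxw
  }
  M
}

# epsilon-relaxed minimum spanning network: edge uv present iff
# d(u,v) <= minimax(u,v) + epsilon
#' @noRd
msn_edges <- function(D, epsilon = 0L) {
  M <- minimax_matrix(D)
  n <- nrow(D)
  idx <- which(upper.tri(D) & D <= M + epsilon, arr.ind = TRUE)
  data.frame(from = idx[, 1L], to = idx[, 2L],
             weight = D[idx])
}

# pack a bit vector into an integer key (panel length < 31 guaranteed upstream)
#' @noRd
bit_keys <- function(B) {
  as.vector(B %*% 2^(seq_len(ncol(B)) - 1L))
}

#' Median-joining haplotype network
#'
#' Builds a haplotype network in the median-joining style: starting from the
#' minimum spanning network over the observed haplotypes, repeatedly add the
#' unobserved "median vector" (position-wise majority consensus of a node
#' triplet) that most reduces the total network cost (the minimum-spanning
#' tree weight over the node set), until no addition helps; finally drop
#' median nodes whose removal leaves the cost unchanged. Candidate medians
#' are drawn from all node triplets; ties on cost reduction are broken by
#' the lexicographically smallest allele string, making the output
#' deterministic. Only binary allele states are supported.
#'
#' @param haplotypes character vector of distinct allele strings.
#' @param counts observed chromosome counts (parallel to `haplotypes`).
#' @param epsilon non-negative integer relaxation of the spanning network:
#'   an edge is kept when its length is within `epsilon` of the pair's
#'   minimax connection threshold.
#' @param min_count keep only haplotypes observed more than `min_count`
#'   times (e.g. `1` restricts to frequency > 1).
#' @param labels optional named character vector tagging haplotype strings
#'   (e.g. archaic reference names).
#' @param pop_composition optional matrix (rows = haplotype strings, columns
#'   = populations) of per-population chromosome counts.
#' @param prune also remove median nodes lying on no shortest
#'   observed-to-observed path (maximum-parsimony style post-processing).
#' @return a `hap_network`: `nodes` data.frame (`alleles`, `observed_count`,
#'   `median`, `label`), `edges` data.frame (`from`, `to`, `weight` as node
#'   indices and Hamming distance), `cost` (MST weight), `epsilon`, and
#'   `pop_composition`.
#' @export
median_joining <- function(haplotypes, counts = rep(1L, length(haplotypes)),
                           epsilon = 0L, min_count = 0L, labels = NULL,
                           pop_composition = NULL, prune = FALSE) {
  stopifnot(length(haplotypes) >= 1L, length(counts) == length(haplotypes),
            epsilon >= 0L)
  if (anyDuplicated(haplotypes)) {
    agg <- tapply(counts, haplotypes, sum)
    haplotypes <- names(agg); counts <- as.integer(agg)
  }
  bad <- grepl("[^01]", haplotypes)
  if (any(bad)) stop("non-binary allele state in haplotype(s): ",
                     paste(haplotypes[bad], collapse = ", "))
  keep <- counts > min_count
  if (!any(keep)) stop("min_count filter removed every haplotype")
  haplotypes <- haplotypes[keep]; counts <- counts[keep]
  ord <- order(haplotypes)
  haplotypes <- haplotypes[ord]; counts <- counts[ord]

  L <- nchar(haplotypes[1L])
  if (L > 30L) stop("panels longer than 30 loci are not supported")
  B <- do.call(rbind, lapply(haplotypes, hap_to_bits))
  obs_count <- as.integer(counts)
  is_median <- logical(nrow(B))

  # one round of the majority (median) operation over node triplets,
  # returning the bit rows not already present
  median_closure <- function(M) {
    n <- nrow(M)
    if (n < 3L) return(M[0L, , drop = FALSE])
    tri <- utils::combn(n, 3L)
    S <- M[tri[1L, ], , drop = FALSE] + M[tri[2L, ], , drop = FALSE] +
      M[tri[3L, ], , drop = FALSE]
    med <- (S >= 2L) * 1L
    keys <- bit_keys(med)
    new_keys <- setdiff(unique(keys), bit_keys(M))
    med[match(new_keys, keys), , drop = FALSE]
  }

  repeat {
    cost0 <- mst_dense(hamming_matrix(B))$cost
    if (nrow(B) < 3L) break
    # candidate pool: iterated closure (a Steiner point can itself be the
    # median of a triplet involving other medians), capped for tractability
    cand <- median_closure(B)
    if (nrow(cand) == 0L) break
    repeat {
      more <- median_closure(rbind(B, cand))
      if (nrow(more) == 0L || nrow(cand) > 80L) break
      cand <- rbind(cand, more)
      cand <- cand[!duplicated(bit_keys(cand)), , drop = FALSE]
    }
    strs <- apply(cand, 1L, paste, collapse = "")
    ord <- order(strs)
    cand <- cand[ord, , drop = FALSE]; strs <- strs[ord]

    gain_of <- function(idx) {
      cost0 - mst_dense(hamming_matrix(rbind(B, cand[idx, , drop = FALSE])))$cost
    }
    # batch search: the best-gaining set of candidate medians added jointly.
    # Joint addition matters — a Steiner point often pays off only together
    # with another. On compact node sets the search is exhaustive over
    # batches of up to 4 (an optimal Steiner tree on <= 6 terminals needs at
    # most 4 Steiner points); larger networks fall back to single additions.
    singles <- vapply(seq_len(nrow(cand)), function(i) gain_of(i), 0L)
    best_g <- 0L; sel <- NULL
    if (max(singles) > 0L) {
      best_g <- max(singles)
      sel <- which(singles == best_g)[1L]          # cand is string-sorted
    }
    if (nrow(B) <= 12L) {
      pool <- order(-singles, strs)[seq_len(min(18L, nrow(cand)))]
      for (k in 2:4) {
        if (length(pool) < k) break
        combs <- utils::combn(pool, k)
        for (ci in seq_len(ncol(combs))) {
          g <- gain_of(combs[, ci])
          if (g > best_g) { best_g <- g; sel <- combs[, ci] }
        }
      }
    }
    if (is.null(sel)) break
    B <- rbind(B, cand[sel, , drop = FALSE])
    obs_count <- c(obs_count, rep(0L, length(sel)))
    is_median <- c(is_median, rep(TRUE, length(sel)))
  }

  # drop obsolete medians: removal must not increase the network cost
  repeat {
    D <- hamming_matrix(B)
    cost0 <- mst_dense(D)$cost
    med_idx <- which(is_median)
    removed <- FALSE
    for (v in med_idx[order(apply(B[med_idx, , drop = FALSE], 1L, paste, collapse = ""))]) {
      Bv <- B[-v, , drop = FALSE]
      if (nrow(Bv) >= 1L && mst_dense(hamming_matrix(Bv))$cost <= cost0) {
        B <- Bv; obs_count <- obs_count[-v]; is_median <- is_median[-v]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  D <- hamming_matrix(B)
  edges <- msn_edges(D, epsilon)

  if (prune && any(is_median)) {
    # keep only medians on some shortest observed-to-observed path
    repeat {
      n <- nrow(B)
      W <- matrix(Inf, n, n); diag(W) <- 0
      for (e in seq_len(nrow(edges))) {
        W[edges$from[e], edges$to[e]] <- edges$weight[e]
        W[edges$to[e], edges$from[e]] <- edges$weight[e]
      }
      for (k in seq_len(n)) {
        W <- pmin(W, outer(W[, k], W[k, ], "+"))
      }
      obs <- which(!is_median)
      on_path <- !is_median
      for (v in which(is_median)) {
        for (a in obs) {
          hit <- any(abs(W[a, v] + W[v, obs] - W[a, obs]) < 1e-9)
          if (hit) { on_path[v] <- TRUE; break }
        }
      }
      if (all(on_path)) break
      B <- B[on_path, , drop = FALSE]
      obs_count <- obs_count[on_path]; is_median <- is_median[on_path]
      D <- hamming_matrix(B)
      edges <- msn_edges(D, epsilon)
    }
  }

  strings <- apply(B, 1L, paste, collapse = "")
  node_labels <- rep(NA_character_, length(strings))
  if (!is.null(labels)) {
    m <- match(names(labels), strings)
    node_labels[m[!is.na(m)]] <- labels[!is.na(m)]
  }
  pc <- NULL
  if (!is.null(pop_composition)) {
    pc <- pop_composition[match(strings, rownames(pop_composition)), , drop = FALSE]
    rownames(pc) <- strings
  }
  nodes <- data.frame(alleles = strings, observed_count = obs_count,
                      median = is_median, label = node_labels,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 cost = mst_dense(D)$cost, epsilon = as.integer(epsilon),
                 pop_composition = pc),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf("hap_network: %d nodes (%d median vectors), %d edges, cost %d, epsilon %d\n",
              nrow(x$nodes), sum(x$nodes$median), nrow(x$edges), x$cost,
              x$epsilon))
  invisible(x)
}

#' Partition network nodes by core-motif carriage
#'
#' Splits the nodes of a haplotype network into motif carriers and
#' non-carriers (the two main clusters of an introgressed-haplotype
#' network) and reports the minimum Hamming distance across the partition.
#'
#' @param net a `hap_network`.
#' @param motif a [core_motif()].
#' @return list: `carrier` / `non_carrier` allele-string vectors and
#'   `separation` (minimum cross-partition Hamming distance; `NA` when a
#'   side is empty).
#' @export
cluster_partition <- function(net, motif) {
  is_carrier <- carries_core(net$nodes$alleles, motif)
  carrier <- net$nodes$alleles[is_carrier]
  non_carrier <- net$nodes$alleles[!is_carrier]
  sep <- NA_integer_
  if (length(carrier) && length(non_carrier)) {
    sep <- min(vapply(carrier, function(a) {
      min(vapply(non_carrier, function(b) hamming_distance(a, b), 0L))
    }, 0L))
  }
  list(carrier = carrier, non_carrier = non_carrier, separation = sep)
}

#' Write a haplotype network
#'
#' Writes the edge list as TSV and the full graph in GML.
#'
#' @param net a `hap_network`.
#' @param path base output path (suffixes `.edges.tsv`, `.gml` appended).
#' @export
write_network <- function(net, path) {
  el <- data.frame(from = net$nodes$alleles[net$edges$from],
                   to = net$nodes$alleles[net$edges$to],
                   weight = net$edges$weight)
  utils::write.table(el, paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gml <- c("graph [", "  directed 0")
  for (i in seq_len(nrow(net$nodes))) {
    gml <- c(gml, "  node [", sprintf("    id %d", i),
             sprintf('    label "%s"', net$nodes$alleles[i]),
             sprintf("    count %d", net$nodes$observed_count[i]),
             sprintf("    median %d", as.integer(net$nodes$median[i])), "  ]")
  }
  for (e in seq_len(nrow(net$edges))) {
    gml <- c(gml, "  edge [",
             sprintf("    source %d", net$edges$from[e]),
             sprintf("    target %d", net$edges$to[e]),
             sprintf("    weight %d", net$edges$weight[e]), "  ]")
  }
  gml <- c(gml, "]")
  writeLines(gml, paste0(path, ".gml"))
  invisible(path)
}
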