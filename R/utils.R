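# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
hap_to_bits <- function(h) {
  as.integer(strsplit(h, "", fixed = TRUE)[[1]])
}

#' @noRd
bits_to_hap <- function(bits) {
  paste(bits, collapse = "")
}

# numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# derive a child seed from a base seed; keeps results below 2^31
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
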