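# Independent oracles, written naively on purpose: plain double loops and
# explicit index arithmetic, no code shared with the package internals.

# Circular (periodized) analysis: y[k] = sum_m f[m] * x[(2k + L/2 - m) mod n]
naive_dwt_periodic <- function(x, filt) {
  n <- length(x)
  if (n %% 2 == 1) {
    x <- c(x, x[n])
    n <- n + 1
  }
  L <- length(filt)
  out <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    acc <- 0
    for (m in seq_len(L)) {
      pos <- (2 * k + L %/% 2 - m - 1) %% n   # 0-based circular position
      acc <- acc + filt[m] * x[pos + 1]
    }
    out[k] <- acc
  }
  out
}

# Half-point symmetric extension analysis, keeping the even phase of the
# valid part of the linear convolution.
naive_dwt_symmetric <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  ext <- c(rev(x[seq_len(L - 1)]), x, rev(x)[seq_len(L - 1)])
  conv <- numeric(n + L - 1)
  for (i in seq_along(conv)) {
    acc <- 0
    for (m in seq_len(L)) acc <- acc + filt[m] * ext[i + L - m]
    conv[i] <- acc
  }
  conv[seq(2, length(conv), by = 2)]
}

# Brute-force reference for the cumulative-energy selection: keep the
# largest coefficients until the energy of what is left drops below tol^2.
naive_energy_selection <- function(w, tol) {
  ord <- order(abs(w), seq_along(w))   # ascending magnitude, ties by index
  cum <- cumsum(w[ord]^2)
  hit <- which(cum >= tol^2)
  if (length(hit) == 0) return(integer(0))
  sort(ord[hit[1]:length(w)])
}

# 212 packing oracle: route each 12-bit two's-complement pair through an
# explicit bit-string representation.
naive_pack_212_pair <- function(s1, s2) {
  to_bits <- function(v) {
    u <- if (v < 0) v + 4096 else v
    rev(as.integer(intToBits(u))[1:12])   # MSB first
  }
  b1 <- to_bits(s1)
  b2 <- to_bits(s2)
  bits_to_byte <- function(bits) sum(bits * 2^(seq(7, 0)))
  c(bits_to_byte(b1[5:12]),
    bits_to_byte(c(b2[1:4], b1[1:4])),
    bits_to_byte(b2[5:12]))
}

empirical_entropy_bits <- function(x) {
  f <- table(x) / length(x)
  -sum(f * log2(f))
}

# Shared synthetic fixture, small and quiet enough for fast tests.
test_ecg <- function(n_beats = 20, seed = 11, ...) {
  generate_synthetic_ecg(synth_config(n_beats = n_beats, seed = seed, ...))
}
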