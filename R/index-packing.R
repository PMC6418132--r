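#' Re-order a quantized payload by index and delta-code the positions
#'
#' Sorts the surviving coefficient positions in ascending order (carrying
#' magnitudes and signs along), then stores them as first differences:
#' the first element of `delta_indices` is the first (1-based) index, the
#' rest are successive gaps, all `>= 1` because the sorted indices are
#' strictly increasing.
#'
#' @param payload An `ecg_quantized` object with raw (unsorted) indices.
#' @return Object of class `ecg_packed`: `delta_indices`, `magnitudes`,
#'   `signs` (re-ordered), plus `delta` and `n_coeff` carried through.
#' @export
#' @examples
#' p <- structure(list(magnitudes = c(2L, 5L, 1L), signs = c(1L, 0L, 1L),
#'                     indices = c(7L, 3L, 10L), delta = 1, n_coeff = 12L),
#'                class = "ecg_quantized")
#' pack_indices(p)$delta_indices   # 3 4 3
pack_indices <- function(payload) {
  idx <- payload$indices
  if (anyDuplicated(idx)) stop("duplicate coefficient indices")
  ord <- order(idx)
  sorted <- idx[ord]
  structure(
    list(delta_indices = as.integer(c(sorted[1L], diff(sorted))),
         magnitudes = payload$magnitudes[ord],
         signs = payload$signs[ord],
         delta = payload$delta,
         n_coeff = payload$n_coeff),
    class = "ecg_packed")
}

#' Recover sorted indices from their first differences
#'
#' Prefix sum of the delta stream: `idx[1] = d[1]`,
#' `idx[i] = idx[i-1] + d[i]`.
#'
#' @param deltas Integer vector of positive gaps (first element is the
#'   first index itself).
#' @return Strictly increasing integer vector of 1-based indices.
#' @export
#' @examples
#' unpack_indices(c(3, 4, 3))  # 3 7 10
unpack_indices <- function(deltas) {
  if (length(deltas) == 0L) return(integer(0))
  if (any(deltas < 1L)) stop("index gaps must be >= 1")
  cumsum(as.integer(deltas))
}

#' Run-length encode a significance map
#'
#' The baseline position coding the codec is compared against: the
#' positions of nonzero coefficients are expanded into a binary map of
#' length `n_total` and stored as alternating run lengths, starting with
#' the zero-run (possibly of length 0 when the map begins with a 1).
#'
#' @param indices Sorted 1-based positions of nonzero coefficients.
#' @param n_total Length of the full coefficient vector.
#' @return Integer vector of run lengths: zeros-run, ones-run,
#'   zeros-run, ...
#' @export
#' @examples
#' rl_encode_significance(3L, 5L)  # 2 1 2
rl_encode_significance <- function(indices, n_total) {
  if (length(indices) > 0L &&
      (min(indices) < 1L || max(indices) > n_total)) {
    stop("index out of range")
  }
  map <- integer(n_total)
  map[indices] <- 1L
  r <- rle(map)
  runs <- r$lengths
  if (length(runs) > 0L && r$values[1L] == 1L) runs <- c(0L, runs)
  as.integer(runs)
}

#' Decode a run-length significance map back to indices
#'
#' Exact inverse of [rl_encode_significance()].
#'
#' @param runs Alternating run lengths starting with the zero-run.
#' @return List with `indices` (sorted 1-based positions) and `n_total`.
#' @export
rl_decode_significance <- function(runs) {
  runs <- as.integer(runs)
  vals <- rep_len(c(0L, 1L), length(runs))
  map <- rep(vals, runs)
  list(indices = which(map == 1L), n_total = sum(runs))
}
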