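#' Selection of the largest wavelet coefficients by cumulative energy
#'
#' Sorts the coefficient magnitudes in ascending order, accumulates their
#' squared values, and discards the longest low-energy prefix whose total
#' energy stays strictly below `tol^2`: with `t(n)` the cumulative sum of
#' sorted squared magnitudes, `k + 1` is the smallest `n` with
#' `t(n) >= tol^2`, and the coefficients ranked `k + 1, ..., N` are kept.
#' Equal magnitudes are ranked by ascending original index, so the result
#' does not depend on the sorting backend.
#'
#' With `tol = 0` every coefficient is kept.  If even the total energy is
#' below `tol^2` the selection is empty.
#'
#' @param w An `ecg_coeffs` object or numeric vector of wavelet
#'   coefficients.
#' @param tol Non-negative energy threshold (same units as the signal
#'   2-norm).
#' @return Object of class `ecg_selected`: `values` (kept coefficients in
#'   ascending-magnitude order), `indices` (their 1-based positions in the
#'   flat coefficient vector), and `n_coeff` (its total length).
#' @export
#' @examples
#' slwc(c(3, 1, 2), tol = sqrt(2))   # keeps 2 and 3
slwc <- function(w, tol) {
  values <- if (inherits(w, "ecg_coeffs")) w$values else as.numeric(w)
  if (!isTRUE(tol >= 0)) stop("tol must be non-negative")
  ord <- order(abs(values), seq_along(values))  # ties: ascending index
  t_cum <- cumsum(values[ord]^2)
  first <- which(t_cum >= tol^2)[1L]
  keep <- if (is.na(first)) integer(0) else ord[first:length(ord)]
  structure(list(values = values[keep], indices = keep,
                 n_coeff = length(values)),
            class = "ecg_selected")
}

#' Energy threshold from a pre-quantization distortion target
#'
#' For an orthonormal transform, discarding coefficient energy `tol^2`
#' yields a reconstruction whose PRD does not exceed `prd0`; hence
#' `tol = prd0 * ||f|| / 100`.
#'
#' @param signal_norm 2-norm of the raw signal (positive).
#' @param prd0 Pre-quantization PRD target in percent.
#' @return The threshold `tol`.
#' @export
#' @examples
#' tol_from_prd0(200, 0.5)  # 1
tol_from_prd0 <- function(signal_norm, prd0) {
  if (!isTRUE(signal_norm > 0)) stop("signal norm must be positive")
  if (!isTRUE(prd0 >= 0)) stop("prd0 must be non-negative")
  prd0 * signal_norm / 100
}

#' Mid-tread uniform quantization with zero elimination
#'
#' Applies `q = floor(c / delta + 1/2)` to each signed coefficient.
#' Entries quantized to zero are dropped together with their indices;
#' the survivors are split into non-negative magnitudes `|q|` and a sign
#' bit (1 for positive, 0 for negative), stored separately.  Every kept
#' coefficient satisfies `|c - delta * q| <= delta / 2`.
#'
#' @param selected An `ecg_selected` object (or a list with `values`,
#'   `indices`, `n_coeff`).
#' @param delta Positive quantization step.
#' @return Object of class `ecg_quantized`: `magnitudes` (integers
#'   `>= 1`), `signs` (0/1 integers), `indices` (1-based, same order as
#'   the input selection), `delta`, `n_coeff`.
#' @export
#' @examples
#' q <- quantize_coeffs(slwc(c(14.9, -6, 5), tol = 0), delta = 10)
#' q$magnitudes
quantize_coeffs <- function(selected, delta) {
  if (!isTRUE(delta > 0)) stop("delta must be positive")
  q <- floor(selected$values / delta + 0.5)
  keep <- q != 0
  q <- q[keep]
  structure(
    list(magnitudes = as.integer(abs(q)),
         signs = as.integer(q > 0),
         indices = selected$indices[keep],
         delta = delta,
         n_coeff = selected$n_coeff),
    class = "ecg_quantized")
}

#' Recover coefficient values from a quantized payload
#'
#' Inverse of [quantize_coeffs()] up to the quantization error:
#' `value = delta * magnitude * (2 * sign - 1)`.
#'
#' @param payload An `ecg_quantized` object.
#' @return An `ecg_selected` object with the reconstructed values at the
#'   payload's indices.
#' @export
dequantize_coeffs <- function(payload) {
  structure(
    list(values = payload$delta * payload$magnitudes * (2 * payload$signs - 1),
         indices = payload$indices,
         n_coeff = payload$n_coeff),
    class = "ecg_selected")
}
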