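l2 <- function(x) sqrt(sum(x^2))

#' Percentage root-mean-square difference
#'
#' `PRD = 100 * ||f - fr|| / ||f||`, computed on the raw stored samples
#' (including any ADC offset).  The headline distortion measure of the
#' codec.
#'
#' @param f Original signal ([ecg_signal()] or numeric).
#' @param fr Reconstruction, same length.
#' @param baseline_subtract Constant subtracted from both signals before
#'   the norm is taken (0 by default; set to 1024 to reproduce the
#'   baseline-subtracted convention some benchmarks use, which yields far
#'   larger values for the same reconstruction).
#' @return PRD in percent.
#' @export
#' @examples
#' prd(c(3, 4), c(3, 0))  # 80
prd <- function(f, fr, baseline_subtract = 0) {
  f <- as_ecg_samples(f) - baseline_subtract
  fr <- as_ecg_samples(fr) - baseline_subtract
  if (length(f) != length(fr)) stop("signals differ in length")
  nf <- l2(f)
  if (nf == 0) stop("zero-norm reference signal")
  100 * l2(f - fr) / nf
}

#' Baseline-independent (normalized) PRD
#'
#' Same numerator as [prd()] but the denominator removes the signal mean:
#' `PRDN = 100 * ||f - fr|| / ||f - mean(f)||`.  Invariant to adding a
#' constant offset to both signals.
#'
#' @inheritParams prd
#' @return PRDN in percent.
#' @export
prdn <- function(f, fr) {
  f <- as_ecg_samples(f)
  fr <- as_ecg_samples(fr)
  if (length(f) != length(fr)) stop("signals differ in length")
  denom <- l2(f - mean(f))
  if (denom == 0) stop("constant reference signal: PRDN undefined")
  100 * l2(f - fr) / denom
}

#' Compression ratio
#'
#' Uncompressed file size over compressed file size.
#'
#' @param uncompressed_bytes,compressed_bytes Positive sizes in bytes.
#' @return Dimensionless ratio.
#' @export
compression_ratio <- function(uncompressed_bytes, compressed_bytes) {
  if (!isTRUE(uncompressed_bytes > 0) || !isTRUE(compressed_bytes > 0)) {
    stop("sizes must be positive")
  }
  uncompressed_bytes / compressed_bytes
}

#' Quality score: compression ratio per unit distortion
#'
#' @param cr Compression ratio.
#' @param prd PRD in percent (positive).
#' @return `cr / prd`.
#' @export
quality_score <- function(cr, prd) {
  if (!isTRUE(prd > 0)) stop("prd must be positive")
  cr / prd
}

#' Reference size of the uncompressed record
#'
#' The compression ratio needs a convention for the size of the
#' uncompressed file.  The default charges `adc_bits` bits per sample
#' (11 for MIT-BIH records); alternatives are two bytes per sample
#' (int16 container) or the WFDB format-212 on-disk size (1.5 bytes per
#' sample).
#'
#' @param n Number of samples.
#' @param convention `"adc"`, `"int16"` or `"wfdb"`.
#' @param adc_bits Bits per sample for the `"adc"` convention.
#' @return Size in bytes.
#' @export
uncompressed_size <- function(n, convention = c("adc", "int16", "wfdb"),
                              adc_bits = 11L) {
  convention <- match.arg(convention)
  switch(convention,
         adc = ceiling(n * adc_bits / 8),
         int16 = 2 * n,
         wfdb = ceiling(n * 1.5))
}

#' Relative gain in compression ratio
#'
#' `Gain = 100 * (cr1 - cr2) / cr2`, the percentage improvement of
#' approach 1 over approach 2 at matched distortion.
#'
#' @param cr1,cr2 Compression ratios (`cr2 > 0`).
#' @return Gain in percent.
#' @export
#' @examples
#' gain(62.48, 38.46)  # ~62.5
gain <- function(cr1, cr2) {
  if (!isTRUE(cr2 > 0)) stop("reference CR must be positive")
  100 * (cr1 - cr2) / cr2
}

#' Local (segment-wise) PRD
#'
#' Partitions the record into `Q = floor(n / L)` consecutive segments of
#' `L` samples (trailing samples that do not fill a segment are dropped)
#' and computes the PRD of each.  Reports the per-segment values, their
#' mean, the unbiased (`Q - 1` divisor) standard deviation, and the
#' index of the worst segment (ties broken toward the first).
#'
#' @param f,fr Original and reconstructed signals.
#' @param L Segment length in samples (default 2000).
#' @return List with `prds`, `mean`, `std` (`NA` when `Q < 2`),
#'   `worst_segment`, `Q`, `L`.
#' @export
local_prd <- function(f, fr, L = 2000L) {
  f <- as_ecg_samples(f)
  fr <- as_ecg_samples(fr)
  if (length(f) != length(fr)) stop("signals differ in length")
  L <- as.integer(L)
  if (L < 1L) stop("segment length must be >= 1")
  Q <- length(f) %/% L
  if (Q < 1L) stop("record shorter than one segment")
  prds <- vapply(seq_len(Q), function(q) {
    idx <- ((q - 1L) * L + 1L):(q * L)
    prd(f[idx], fr[idx])
  }, numeric(1))
  list(prds = prds,
       mean = mean(prds),
       std = if (Q >= 2L) stats::sd(prds) else NA_real_,
       worst_segment = which.max(prds),   # which.max takes the first maximum
       Q = Q, L = L)
}

#' Full quality report for one record
#'
#' Gathers every evaluation quantity for a record/reconstruction pair in
#' one object: global PRD and PRDN, compression ratio, quality score and
#' segment-wise prd statistics.
#'
#' @param f,fr Original and reconstructed signals.
#' @param compressed_bytes On-disk size of the container.
#' @param uncompressed_bytes Reference size; defaults to the
#'   `adc_bits`-per-sample convention via [uncompressed_size()].
#' @param segment_length Segment length for [local_prd()].
#' @param baseline_subtract Passed to [prd()].
#' @return Object of class `quality_report`.
#' @export
quality_report <- function(f, fr, compressed_bytes,
                           uncompressed_bytes = NULL,
                           segment_length = 2000L,
                           baseline_subtract = 0) {
  samples <- as_ecg_samples(f)
  adc_bits <- if (inherits(f, "ecg_signal")) f$adc_bits else 11L
  if (is.null(uncompressed_bytes)) {
    uncompressed_bytes <- uncompressed_size(length(samples), "adc", adc_bits)
  }
  p <- prd(f, fr, baseline_subtract = baseline_subtract)
  cr <- compression_ratio(uncompressed_bytes, compressed_bytes)
  lp <- local_prd(f, fr, segment_length)
  structure(
    list(record_id = if (inherits(f, "ecg_signal")) f$record_id else "unnamed",
         prd = p, prdn = prdn(f, fr), cr = cr,
         qs = quality_score(cr, p),
         prd_mean = lp$mean, prd_std = lp$std,
         worst_segment = lp$worst_segment, local_prds = lp$prds,
         Q = lp$Q, L = lp$L,
         compressed_bytes = compressed_bytes,
         uncompressed_bytes = uncompressed_bytes),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> record '%s'\n", x$record_id))
  cat(sprintf("  PRD %.2f%%  PRDN %.2f%%  CR %.2f  QS %.2f\n",
              x$prd, x$prdn, x$cr, x$qs))
  cat(sprintf("  local prd over %d x %d-sample segments: mean %.2f, std %.2f, worst segment %d\n",
              x$Q, x$L, x$prd_mean, x$prd_std, x$worst_segment))
  invisible(x)
}

#' One-row data frame view of a quality report
#'
#' Mirrors the per-record benchmark table layout: record, mean and std of
#' the local prd, global PRD, CR, QS, PRDN.
#'
#' @param x A `quality_report`.
#' @param row.names,optional,... Standard `as.data.frame` arguments
#'   (ignored).
#' @return A one-row `data.frame`.
#' @export
as.data.frame.quality_report <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(record = x$record_id, prd_mean = x$prd_mean, prd_std = x$prd_std,
             PRD = x$prd, CR = x$cr, QS = x$qs, PRDN = x$prdn,
             stringsAsFactors = FALSE)
}
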