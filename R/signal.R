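#' Construct an ECG signal object
#'
#' The codec's in-memory representation of a single-channel ECG record:
#' raw ADC integers exactly as stored on disk, together with the sampling
#' rate and ADC metadata.  No rescaling or baseline subtraction is applied
#' at construction; MIT-BIH style records keep their offset (about 1024 ADC
#' units for an 11-bit converter centred on zero volts) because the
#' headline distortion metric (PRD) is defined on the raw stored values.
#'
#' @param samples Integer-valued numeric vector of ADC amplitudes.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param adc_bits ADC resolution in bits per sample.
#' @param baseline ADC offset corresponding to zero input (e.g. 1024).
#' @param record_id Optional record label.
#' @return An object of class `ecg_signal`: a list with fields `samples`,
#'   `fs`, `adc_bits`, `baseline`, `record_id`.
#' @export
#' @examples
#' s <- ecg_signal(c(1020, 1030, 1025), fs = 360)
#' length(s$samples)
ecg_signal <- function(samples, fs = 360, adc_bits = 11, baseline = 1024,
                       record_id = "unnamed") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (anyNA(samples)) stop("signal contains missing values")
  if (!isTRUE(fs > 0)) stop("sampling frequency must be positive")
  if (any(samples != round(samples))) {
    stop("samples must be integer-valued ADC amplitudes")
  }
  # representable either as unsigned [0, 2^b) or two's-complement
  # [-2^(b-1), 2^(b-1)) integers
  b <- as.integer(adc_bits)
  unsigned_ok <- all(samples >= 0 & samples < 2^b)
  signed_ok <- all(samples >= -2^(b - 1) & samples < 2^(b - 1))
  if (!unsigned_ok && !signed_ok) {
    stop(sprintf("samples do not fit in %d bits", b))
  }
  structure(
    list(samples = samples, fs = fs, adc_bits = b, baseline = baseline,
         record_id = as.character(record_id)),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> record '%s': %d samples @ %g Hz, %d-bit ADC (baseline %g)\n",
              x$record_id, length(x$samples), x$fs, x$adc_bits, x$baseline))
  cat(sprintf("  range [%g, %g]\n", min(x$samples), max(x$samples)))
  invisible(x)
}

# Accept either an ecg_signal or a bare numeric vector.
as_ecg_samples <- function(x) {
  if (inherits(x, "ecg_signal")) x$samples else as.numeric(x)
}
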