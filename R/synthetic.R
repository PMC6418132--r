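#' Configuration for the synthetic ECG generator
#'
#' Describes a quasi-periodic ECG-like waveform: each beat is a sum of
#' five Gaussian bumps (P, Q, R, S, T) placed relative to the R peak,
#' beats are spaced by jittered RR intervals, and the analog waveform is
#' overlaid with sinusoidal baseline wander (respiration-like) and white
#' noise before digitization.  Defaults emulate an MIT-BIH style
#' recording: 360 Hz, 11-bit ADC with a 1024 offset, R amplitude around
#' 1.25 mV at 200 ADC units/mV, resting heart rate of 75 bpm.
#'
#' @param n_beats Number of beats.
#' @param mean_rr_s Mean RR interval in seconds.
#' @param rr_jitter_s Standard deviation of the RR interval in seconds
#'   (Gaussian, truncated at 3 sd to keep intervals positive).
#' @param wave_amplitudes Named numeric vector, ADC units, names
#'   `P Q R S T`.
#' @param wave_offsets_s Centres of the five waves relative to the R peak
#'   (seconds).
#' @param wave_widths_s Gaussian standard deviations of the five waves
#'   (seconds; all positive).
#' @param baseline_wander_amp Amplitude of the 0.33 Hz sinusoidal wander,
#'   ADC units.
#' @param noise_sd White-noise standard deviation, ADC units.
#' @param fs Sampling frequency, Hz.
#' @param adc_bits ADC resolution.
#' @param baseline ADC offset added before digitization.
#' @param seed RNG seed; identical configurations give bit-identical
#'   signals.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_beats = 60L,
                         mean_rr_s = 0.8,
                         rr_jitter_s = 0.04,
                         wave_amplitudes = c(P = 30, Q = -40, R = 250, S = -60, T = 70),
                         wave_offsets_s = c(P = -0.2, Q = -0.03, R = 0, S = 0.03, T = 0.3),
                         wave_widths_s = c(P = 0.025, Q = 0.01, R = 0.012, S = 0.01, T = 0.06),
                         baseline_wander_amp = 20,
                         noise_sd = 4,
                         fs = 360,
                         adc_bits = 11L,
                         baseline = 1024,
                         seed = 1L) {
  stopifnot(n_beats >= 1L, mean_rr_s > 0, rr_jitter_s >= 0,
            all(wave_widths_s > 0), fs > 0, baseline_wander_amp >= 0,
            noise_sd >= 0)
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(all(waves %in% names(wave_amplitudes)),
            all(waves %in% names(wave_offsets_s)),
            all(waves %in% names(wave_widths_s)))
  structure(
    list(n_beats = as.integer(n_beats), mean_rr_s = mean_rr_s,
         rr_jitter_s = rr_jitter_s,
         wave_amplitudes = wave_amplitudes[waves],
         wave_offsets_s = wave_offsets_s[waves],
         wave_widths_s = wave_widths_s[waves],
         baseline_wander_amp = baseline_wander_amp, noise_sd = noise_sd,
         fs = fs, adc_bits = as.integer(adc_bits), baseline = baseline,
         seed = as.integer(seed)),
    class = "synth_config")
}

# Run code with a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ECG signal
#'
#' Deterministic given the configuration (including its seed).  Waveform
#' values that would clip outside the ADC range raise an error rather
#' than clipping silently.
#'
#' @param cfg A [synth_config()].
#' @param n_samples Optional exact output length in samples.  The beat
#'   train is generated first; the signal is cropped to `n_samples` if
#'   longer, or an error is raised if too few beats were requested to
#'   cover it.
#' @return An [ecg_signal()].
#' @export
#' @examples
#' s <- generate_synthetic_ecg(synth_config(n_beats = 5, seed = 42))
#' s$fs
generate_synthetic_ecg <- function(cfg, n_samples = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_private_seed(cfg$seed, {
    jit <- stats::rnorm(cfg$n_beats, 0, cfg$rr_jitter_s)
    jit <- pmin(pmax(jit, -3 * cfg$rr_jitter_s), 3 * cfg$rr_jitter_s)
    rr <- pmax(cfg$mean_rr_s + jit, 0.2)
    beat_times <- cumsum(rr)
    # half a beat of lead-in so the first P wave is not truncated
    beat_times <- beat_times - rr[1L] + cfg$mean_rr_s / 2
    total_s <- beat_times[cfg$n_beats] + cfg$mean_rr_s
    n <- ceiling(total_s * cfg$fs)
    t <- (seq_len(n) - 1L) / cfg$fs
    analog <- numeric(n)
    for (b in seq_len(cfg$n_beats)) {
      for (wv in seq_along(cfg$wave_amplitudes)) {
        mu <- beat_times[b] + cfg$wave_offsets_s[wv]
        sd <- cfg$wave_widths_s[wv]
        lo <- max(1L, floor((mu - 5 * sd) * cfg$fs))
        hi <- min(n, ceiling((mu + 5 * sd) * cfg$fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        analog[idx] <- analog[idx] +
          cfg$wave_amplitudes[wv] * exp(-((t[idx] - mu)^2) / (2 * sd^2))
      }
    }
    if (cfg$baseline_wander_amp > 0) {
      analog <- analog + cfg$baseline_wander_amp * sin(2 * pi * 0.33 * t)
    }
    if (cfg$noise_sd > 0) {
      analog <- analog + stats::rnorm(n, 0, cfg$noise_sd)
    }
    digital <- round(analog + cfg$baseline)
    if (any(digital < 0) || any(digital >= 2^cfg$adc_bits)) {
      stop(sprintf("synthetic waveform clips outside the %d-bit ADC range",
                   cfg$adc_bits))
    }
    if (!is.null(n_samples)) {
      if (n < n_samples) {
        stop(sprintf("requested %d samples but only %d generated; increase n_beats",
                     n_samples, n))
      }
      digital <- digital[seq_len(n_samples)]
    }
    ecg_signal(digital, fs = cfg$fs, adc_bits = cfg$adc_bits,
               baseline = cfg$baseline,
               record_id = sprintf("synth%03d", cfg$seed))
  })
}
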