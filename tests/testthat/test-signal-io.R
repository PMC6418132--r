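test_that("212 packing matches a bit-level oracle and round-trips", {
  # hand-picked extremes plus the documented example triple
  pairs <- rbind(c(-1024, 0), c(1023, -1), c(-2048, 2047), c(0, 0))
  for (i in seq_len(nrow(pairs))) {
    expect_identical(
      as.integer(pack_212(pairs[i, ])),
      as.integer(naive_pack_212_pair(pairs[i, 1], pairs[i, 2])))
  }
  expect_identical(unpack_212(pack_212(c(-1024, 0, 1023, 5))),
                   c(-1024L, 0L, 1023L, 5L))

  set.seed(42)
  vals <- matrix(sample(-2048:2047, 2e4, replace = TRUE), ncol = 2)
  packed <- pack_212(as.integer(t(vals)))
  expect_identical(unpack_212(packed), as.integer(t(vals)))

  expect_error(unpack_212(as.raw(c(1, 2, 3, 4))), "multiple of 3")
  expect_error(pack_212(4000), "12-bit")
})

test_that("WFDB records written by the package read back identically", {
  dir <- withr::local_tempdir()
  sig <- ecg_signal(c(-1024, 0, 1023, 512, -7, 3) + 1024, fs = 360,
                    adc_bits = 11, record_id = "fx01")
  hea <- write_wfdb(sig, dir)
  back <- read_wfdb(hea)
  expect_identical(back$samples, sig$samples)
  expect_equal(back$fs, 360)
  expect_equal(back$adc_bits, 11L)
  expect_identical(back$record_id, "fx01")

  two <- ecg_signal(c(1, 2), fs = 250, adc_bits = 12, record_id = "tiny")
  back2 <- read_wfdb(write_wfdb(two, dir))
  expect_identical(back2$samples, c(1, 2))

  expect_error(read_wfdb(file.path(dir, "nope.hea")), "not found")
  expect_error(read_wfdb(hea, channel = 2), "out of range")
})

test_that("vector I/O round-trips in both formats and rejects bad input", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "x.csv")
  writeLines(c("1", "2", "3"), csv)
  s <- read_vector(csv, "csv")
  expect_identical(s$samples, c(1, 2, 3))

  sig <- test_ecg(n_beats = 3)
  p <- file.path(dir, "sig.bin")
  write_vector(sig, p, "binary")
  back <- read_vector(p, "binary")
  expect_identical(back$samples, sig$samples)
  expect_equal(back$fs, sig$fs)

  p2 <- file.path(dir, "sig.csv")
  write_vector(sig, p2, "csv")
  expect_identical(read_vector(p2, "csv")$samples, sig$samples)

  empty <- file.path(dir, "empty.csv")
  file.create(empty)
  expect_error(read_vector(empty, "csv"), "empty")
  bad <- file.path(dir, "bad.csv")
  writeLines("hello", bad)
  expect_error(read_vector(bad, "csv"))
})

test_that("synthetic generator is deterministic and respects morphology", {
  cfg <- synth_config(n_beats = 1, noise_sd = 0, baseline_wander_amp = 0,
                      seed = 9)
  s1 <- generate_synthetic_ecg(cfg)
  s2 <- generate_synthetic_ecg(cfg)
  expect_identical(s1$samples, s2$samples)

  # exactly one excursion above baseline + R/2: the single QRS complex
  thr <- cfg$baseline + cfg$wave_amplitudes[["R"]] / 2
  above <- s1$samples > thr
  n_runs <- sum(diff(c(FALSE, above)) == 1)
  expect_identical(n_runs, 1L)

  # samples always fit the ADC range; a too-hot waveform errors out
  expect_true(all(s1$samples >= 0 & s1$samples < 2^cfg$adc_bits))
  hot <- synth_config(n_beats = 2, wave_amplitudes = c(P = 30, Q = -40,
                      R = 2000, S = -60, T = 70), seed = 1)
  expect_error(generate_synthetic_ecg(hot), "clips")
})

test_that("generated RR intervals track the configured mean", {
  cfg <- synth_config(n_beats = 200, mean_rr_s = 0.8, rr_jitter_s = 0.05,
                      noise_sd = 0, baseline_wander_amp = 0, seed = 21)
  s <- generate_synthetic_ecg(cfg)
  thr <- cfg$baseline + cfg$wave_amplitudes[["R"]] / 2
  # peak-to-peak interval oracle: onsets of threshold crossings
  onsets <- which(diff(c(FALSE, s$samples > thr)) == 1)
  rr <- diff(onsets) / cfg$fs
  se <- stats::sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - cfg$mean_rr_s), 3 * se + 1e-6)
})

test_that("generator fails rather than under-delivering a fixed length", {
  cfg <- synth_config(n_beats = 5, seed = 2)
  expect_error(generate_synthetic_ecg(cfg, n_samples = 10^6), "increase n_beats")
  s <- generate_synthetic_ecg(cfg, n_samples = 1000)
  expect_length(s$samples, 1000)
})
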