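test_that("codec configuration validates its invariants", {
  expect_error(codec_config(method = "a"), "exactly one")
  expect_error(codec_config(method = "a", delta = 35, target_prd = 0.5),
               "exactly one")
  expect_error(codec_config(method = "b", delta = 35, prd0 = 0.4),
               "method \\(a\\)")
  expect_error(codec_config(method = "a", delta = 35), "prd0")
  cfg <- codec_config(method = "a", target_prd = 1)
  expect_identical(cfg$prd0, 0.75)   # default 75% of the target
})

test_that("compress/decompress round trip obeys the quantizer bound", {
  dir <- withr::local_tempdir()
  sig <- test_ecg(n_beats = 30, seed = 13)
  for (method in c("a", "b")) {
    # periodization makes the transform square, so analysis of the
    # reconstruction recovers the quantized coefficients exactly
    cfg <- codec_config(method = method, delta = 20,
                        prd0 = if (method == "a") 0.4 else NULL,
                        spec = transform_spec("cdf97", 4, "periodization"))
    path <- file.path(dir, paste0(method, ".h5"))
    res <- ecg_compress(sig, cfg, path)
    fr <- ecg_decompress(path)
    expect_length(fr$samples, length(sig$samples))
    # in the coefficient domain every kept coefficient is within delta/2
    # and method (b) discards only sub-delta/2 coefficients
    w <- dwt_forward(sig, cfg$spec)
    wr <- dwt_forward(fr$samples, cfg$spec)
    if (method == "b") {
      expect_lte(max(abs(w$values - wr$values)), 20 / 2 + 1e-6)
    }
    # the reported PRD is exactly what the metrics module computes
    expect_identical(res$prd, prd(sig, fr))
    expect_true(is.finite(res$cr) && res$cr > 0)
  }
})

test_that("decompression is deterministic and handles empty payloads", {
  dir <- withr::local_tempdir()
  sig <- test_ecg(n_beats = 10, seed = 19)
  path <- file.path(dir, "d.h5")
  ecg_compress(sig, codec_config(method = "b", delta = 15), path)
  f1 <- ecg_decompress(path)
  f2 <- ecg_decompress(path)
  expect_identical(f1$samples, f2$samples)

  # a container with zero kept coefficients reconstructs the zero signal
  w <- dwt_forward(sig, transform_spec())
  empty <- structure(list(delta_indices = integer(0), magnitudes = integer(0),
                          signs = integer(0), delta = 35,
                          n_coeff = length(w$values)),
                     class = "ecg_packed")
  meta <- list(n_signal = length(sig$samples), spec = w$spec,
               band_lengths = w$band_lengths, input_lengths = w$input_lengths)
  pe <- file.path(dir, "empty.h5")
  write_container(empty, meta, pe)
  expect_identical(max(abs(ecg_decompress(pe)$samples)), 0)
})

test_that("near-lossless limit: tiny delta drives PRD toward zero", {
  dir <- withr::local_tempdir()
  sig <- test_ecg(n_beats = 10, seed = 23)
  res <- ecg_compress(sig, codec_config(method = "b", delta = 0.01),
                      file.path(dir, "nl.h5"))
  expect_lt(res$prd, 0.01)
})

test_that("method (a) with prd0 = 0 equals method (b) byte for byte", {
  dir <- withr::local_tempdir()
  sig <- test_ecg(n_beats = 25, seed = 29)
  pa <- file.path(dir, "a.h5")
  pb <- file.path(dir, "b.h5")
  ecg_compress(sig, codec_config(method = "a", delta = 24, prd0 = 0), pa)
  ecg_compress(sig, codec_config(method = "b", delta = 24), pb)
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))
})

test_that("delta tuning converges to requested distortion", {
  sig <- test_ecg(n_beats = 40, seed = 31)
  cfg <- codec_config(method = "b", delta = 25)
  # fixed-point check: ask the tuner for the PRD a known delta achieves
  dir <- withr::local_tempdir()
  res <- ecg_compress(sig, cfg, file.path(dir, "k.h5"))
  tuned <- tune_delta(sig, codec_config(method = "b", target_prd = res$prd))
  expect_lte(abs(tuned$achieved_prd - res$prd), 0.005)

  # a pure tone is tunable across the whole operating range
  tone <- ecg_signal(round(1024 + 200 * sin(2 * pi * 5 * (1:8192) / 360)),
                     fs = 360, record_id = "tone")
  for (target in c(0.2, 1, 4)) {
    tn <- tune_delta(tone, codec_config(method = "b", target_prd = target))
    expect_lte(tn$iterations, 40L)
    expect_lte(abs(tn$achieved_prd - target), 0.005)
  }

  # unreachable target reports the floor instead of silently failing
  expect_error(
    ecg_compress(sig, codec_config(method = "b", target_prd = 1e-9),
                 file.path(dir, "f.h5")),
    "floor")
})

test_that("larger delta never shrinks quantization error on a fixed set", {
  set.seed(801)
  v <- rnorm(300, sd = 40)
  sel <- structure(list(values = v, indices = seq_along(v), n_coeff = 300L),
                   class = "ecg_selected")
  err_energy <- vapply(c(5, 10, 20, 40), function(delta) {
    q <- quantize_coeffs(sel, delta)
    rec <- numeric(300)
    rec[q$indices] <- q$delta * q$magnitudes * (2 * q$signs - 1)
    sum((v - rec)^2)
  }, numeric(1))
  expect_true(all(diff(err_energy) >= 0))
})

test_that("huffman and baseline-subtraction options flow end to end", {
  dir <- withr::local_tempdir()
  sig <- test_ecg(n_beats = 20, seed = 37)
  ph <- file.path(dir, "h.h5")
  res <- ecg_compress(sig, codec_config(method = "b", delta = 20,
                                        huffman = TRUE), ph)
  fr <- ecg_decompress(ph)
  expect_identical(res$prd, prd(sig, fr))

  cfgb <- codec_config(method = "b", delta = 20, baseline_subtract = 1024)
  resb <- ecg_compress(sig, cfgb, file.path(dir, "bs.h5"))
  # same reconstruction, much larger distortion measure
  expect_gt(resb$prd, res$prd * 2)
})
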