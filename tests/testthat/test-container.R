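packed_fixture <- function(k = 500L, n_coeff = 4096L, delta = 35,
                           seed = 601, max_mag = 200L) {
  set.seed(seed)
  idx <- sort(sample.int(n_coeff, k))
  q <- structure(list(magnitudes = sample.int(max_mag, k, replace = TRUE),
                      signs = sample(0:1, k, replace = TRUE),
                      indices = idx, delta = delta, n_coeff = n_coeff),
                 class = "ecg_quantized")
  pack_indices(q)
}

meta_fixture <- function(n_signal = 4096L) {
  w <- dwt_forward(rep(1024, n_signal), transform_spec())
  list(n_signal = n_signal, spec = w$spec, band_lengths = w$band_lengths,
       input_lengths = w$input_lengths, fs = 360, adc_bits = 11L,
       baseline = 1024, record_id = "fix")
}

test_that("container write/read is lossless for streams and metadata", {
  dir <- withr::local_tempdir()
  p <- packed_fixture()
  meta <- meta_fixture()
  path <- file.path(dir, "c.h5")
  size <- write_container(p, meta, path)
  expect_identical(size, file.size(path))
  back <- read_container(path)
  expect_identical(back$packed$magnitudes, p$magnitudes)
  expect_identical(back$packed$signs, p$signs)
  expect_identical(back$packed$delta_indices, p$delta_indices)
  expect_identical(back$packed$delta, p$delta)
  expect_identical(back$meta$n_signal, meta$n_signal)
  expect_identical(back$meta$band_lengths, unname(as.integer(meta$band_lengths)))
  expect_identical(back$meta$spec$family, "cdf97")
})

test_that("datasets use the narrowest unsigned type that fits", {
  dir <- withr::local_tempdir()
  meta <- meta_fixture()
  small <- packed_fixture(max_mag = 255L)
  big <- small
  big$magnitudes[1] <- 256L
  p1 <- file.path(dir, "u8.h5"); p2 <- file.path(dir, "u16.h5")
  write_container(small, meta, p1)
  write_container(big, meta, p2)
  mag_type_bytes <- function(path) {
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid))
    did <- rhdf5::H5Dopen(fid, "magnitudes")
    on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
    rhdf5::H5Tget_size(rhdf5::H5Dget_type(did))
  }
  expect_identical(mag_type_bytes(p1), 1L)
  expect_identical(mag_type_bytes(p2), 2L)
  # widened values survive the round trip (never truncated)
  expect_identical(read_container(p2)$packed$magnitudes, big$magnitudes)
})

test_that("gzip level is honoured: size non-increasing, constants collapse", {
  dir <- withr::local_tempdir()
  meta <- meta_fixture()
  p <- packed_fixture(k = 2000L)
  p$magnitudes <- rep(17L, 2000L)   # long constant array
  s1 <- write_container(p, meta, file.path(dir, "l1.h5"), gzip_level = 1)
  s9 <- write_container(p, meta, file.path(dir, "l9.h5"), gzip_level = 9)
  expect_lte(s9, s1)
  # the constant magnitude stream must shrink far below its raw size;
  # compare against a container whose magnitudes are incompressible
  set.seed(602)
  q <- packed_fixture(k = 2000L)
  s_rand <- write_container(q, meta, file.path(dir, "rand.h5"))
  expect_lt(s1, s_rand)
})

test_that("huffman-flagged containers decode to the same streams", {
  dir <- withr::local_tempdir()
  p <- packed_fixture()
  meta <- meta_fixture()
  plain <- file.path(dir, "plain.h5")
  huff <- file.path(dir, "huff.h5")
  write_container(p, meta, plain, huffman = FALSE)
  write_container(p, meta, huff, huffman = TRUE)
  a <- read_container(plain)
  b <- read_container(huff)
  expect_identical(a$packed$magnitudes, b$packed$magnitudes)
  expect_identical(a$packed$delta_indices, b$packed$delta_indices)
  expect_identical(a$packed$signs, b$packed$signs)
  expect_true(b$settings$huffman)
})

test_that("layout errors and empty payloads are handled", {
  dir <- withr::local_tempdir()
  p <- packed_fixture()
  meta <- meta_fixture()
  path <- file.path(dir, "x.h5")
  write_container(p, meta, path)
  rhdf5::h5delete(path, "magnitudes")
  expect_error(read_container(path), "missing dataset")
  expect_error(read_container(file.path(dir, "nope.h5")), "not found")

  # zero kept coefficients: container still round-trips and CR stays finite
  empty <- structure(list(delta_indices = integer(0), magnitudes = integer(0),
                          signs = integer(0), delta = 35, n_coeff = 4096L),
                     class = "ecg_packed")
  pe <- file.path(dir, "empty.h5")
  size <- write_container(empty, meta, pe)
  expect_gt(size, 0)
  cr <- compression_ratio(uncompressed_size(650000), size)
  expect_true(is.finite(cr) && cr > 1)
  back <- read_container(pe)
  expect_length(back$packed$magnitudes, 0)
})
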