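#' Read a WFDB format-212 record
#'
#' Parses a WFDB `.hea` header and the associated format-212 signal file
#' (the packing used by the MIT-BIH Arrhythmia database: two 12-bit
#' two's-complement samples per 3 bytes, channels interleaved frame by
#' frame).  Samples are returned exactly as stored -- raw ADC integers,
#' no gain scaling and no baseline subtraction.
#'
#' @param header_path Path to the `.hea` file.
#' @param channel 1-based channel (lead) number; default 1, the first
#'   lead.
#' @return An [ecg_signal()].
#' @export
read_wfdb <- function(header_path, channel = 1L) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record_id <- rec[1L]
  n_sig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(rec[3L]) else 250
  n_samples <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L) stop("malformed header record line")
  if (channel < 1L || channel > n_sig) {
    stop(sprintf("channel %d out of range (record has %d signals)", channel, n_sig))
  }
  sig_lines <- lines[2L:(1L + n_sig)]
  fields <- strsplit(trimws(sig_lines), "\\s+")
  dat_files <- vapply(fields, `[[`, character(1), 1L)
  formats <- vapply(fields, function(f) sub("x.*$", "", f[2L]), character(1))
  if (any(formats != "212")) {
    stop("only WFDB format 212 is supported (found ", paste(unique(formats), collapse = ","), ")")
  }
  if (length(unique(dat_files)) != 1L) {
    stop("multi-file records are not supported")
  }
  adc_res <- if (length(fields[[channel]]) >= 4L) {
    as.integer(fields[[channel]][4L])
  } else NA_integer_
  if (is.na(adc_res)) adc_res <- 12L
  adc_zero <- if (length(fields[[channel]]) >= 5L) {
    as.integer(fields[[channel]][5L])
  } else 0L
  dat_path <- file.path(dirname(header_path), dat_files[1L])
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  raw_bytes <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  samples <- unpack_212(raw_bytes)
  total <- if (!is.na(n_samples)) n_samples * n_sig else length(samples)
  if (length(samples) < total) stop("signal file shorter than header declares")
  samples <- samples[seq_len(total)]
  ch <- samples[seq(channel, total, by = n_sig)]
  ecg_signal(ch, fs = fs, adc_bits = adc_res, baseline = adc_zero,
             record_id = record_id)
}

#' Unpack WFDB format-212 bytes into 12-bit two's-complement samples
#'
#' Each 3-byte group holds two samples: byte 1 is the low 8 bits of the
#' first sample, the low nibble of byte 2 its high 4 bits; the high
#' nibble of byte 2 holds the high 4 bits of the second sample and byte 3
#' its low 8 bits.
#'
#' @param raw_bytes A raw vector whose length is a multiple of 3 (a
#'   trailing partial group is an error).
#' @return Integer vector of samples in `[-2048, 2047]`.
#' @export
unpack_212 <- function(raw_bytes) {
  nb <- length(raw_bytes)
  if (nb %% 3L != 0L) stop("malformed 212 packing: byte count not a multiple of 3")
  b <- as.integer(raw_bytes)
  b1 <- b[seq(1L, nb, 3L)]
  b2 <- b[seq(2L, nb, 3L)]
  b3 <- b[seq(3L, nb, 3L)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 0x0FL), 8L)
  out <- integer(2L * length(b1))
  out[seq(1L, length(out), 2L)] <- s1
  out[seq(2L, length(out), 2L)] <- s2
  ifelse(out > 2047L, out - 4096L, out)
}

#' Pack 12-bit two's-complement samples into WFDB format-212 bytes
#'
#' Inverse of [unpack_212()].  An odd number of samples is padded with a
#' zero sample, as WFDB writers do.
#'
#' @param samples Integer vector in `[-2048, 2047]`.
#' @return Raw vector, 3 bytes per sample pair.
#' @export
pack_212 <- function(samples) {
  s <- as.integer(round(samples))
  if (any(s < -2048L | s > 2047L)) stop("sample out of 12-bit range")
  if (length(s) %% 2L == 1L) s <- c(s, 0L)
  u <- ifelse(s < 0L, s + 4096L, s)
  s1 <- u[seq(1L, length(u), 2L)]
  s2 <- u[seq(2L, length(u), 2L)]
  b <- integer(3L * length(s1))
  b[seq(1L, length(b), 3L)] <- bitwAnd(s1, 0xFFL)
  b[seq(2L, length(b), 3L)] <- bitwOr(bitwAnd(bitwShiftR(s1, 8L), 0x0FL),
                                      bitwShiftL(bitwAnd(bitwShiftR(s2, 8L), 0x0FL), 4L))
  b[seq(3L, length(b), 3L)] <- bitwAnd(s2, 0xFFL)
  as.raw(b)
}

#' Write a single-channel WFDB format-212 record (test fixture helper)
#'
#' @param signal An [ecg_signal()].
#' @param dir Output directory.
#' @param record Record name; files `<record>.hea` and `<record>.dat` are
#'   written.
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(signal, dir, record = signal$record_id) {
  stopifnot(inherits(signal, "ecg_signal"))
  dat <- paste0(record, ".dat")
  hea <- file.path(dir, paste0(record, ".hea"))
  n <- length(signal$samples)
  header <- c(
    sprintf("%s 1 %g %d", record, signal$fs, n),
    sprintf("%s 212 200 %d %d %d 0 0 ECG", dat, signal$adc_bits,
            signal$baseline, as.integer(signal$samples[1L]))
  )
  writeLines(header, hea)
  writeBin(pack_212(signal$samples), file.path(dir, dat))
  invisible(hea)
}

#' Read a plain numeric vector as an ECG signal
#'
#' @param path File path.
#' @param format `"csv"` (one value per line) or `"binary"`
#'   (little-endian int16; metadata is read from a `<path>.json` sidecar
#'   when present).
#' @param fs,adc_bits,baseline,record_id Metadata attached to the
#'   returned signal (overridden by a sidecar for binary files).
#' @return An [ecg_signal()].
#' @export
read_vector <- function(path, format = c("csv", "binary"), fs = 360,
                        adc_bits = 11, baseline = 1024,
                        record_id = tools::file_path_sans_ext(basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    x <- tryCatch(scan(path, what = numeric(), quiet = TRUE),
                  error = function(e) stop("non-numeric content in ", path))
    if (length(x) == 0L) stop("empty file: ", path)
  } else {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$fs)) fs <- meta$fs
      if (!is.null(meta$adc_bits)) adc_bits <- meta$adc_bits
      if (!is.null(meta$baseline)) baseline <- meta$baseline
      if (!is.null(meta$record_id)) record_id <- meta$record_id
    }
    nbytes <- file.info(path)$size
    if (nbytes == 0L) stop("empty file: ", path)
    x <- readBin(path, "integer", n = nbytes %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  }
  ecg_signal(x, fs = fs, adc_bits = adc_bits, baseline = baseline,
             record_id = record_id)
}

#' Write an ECG signal as a plain vector file
#'
#' @param signal An [ecg_signal()] or numeric vector.
#' @param path Output path.
#' @param format `"csv"` or `"binary"` (little-endian int16 plus a
#'   `<path>.json` metadata sidecar).
#' @return Invisibly, `path`.
#' @export
write_vector <- function(signal, path, format = c("csv", "binary")) {
  format <- match.arg(format)
  x <- as_ecg_samples(signal)
  if (format == "csv") {
    writeLines(format(x, scientific = FALSE, trim = TRUE), path)
  } else {
    writeBin(as.integer(x), path, size = 2L, endian = "little")
    if (inherits(signal, "ecg_signal")) {
      jsonlite::write_json(
        list(fs = signal$fs, adc_bits = signal$adc_bits,
             baseline = signal$baseline, record_id = signal$record_id),
        paste0(path, ".json"), auto_unbox = TRUE)
    }
  }
  invisible(path)
}
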