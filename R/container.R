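# Chunked, gzip-compressed HDF5 container for the packed coefficient
# streams.  Uses the rhdf5 low-level API so that object-header time
# tracking can be switched off: containers with identical payloads are
# byte-identical regardless of when they are written.

uint_type_for <- function(max_value) {
  if (max_value <= 255) list(h5 = "H5T_STD_U8LE", bytes = 1L)
  else if (max_value <= 65535) list(h5 = "H5T_STD_U16LE", bytes = 2L)
  else list(h5 = "H5T_STD_U32LE", bytes = 4L)
}

h5_write_uint <- function(fid, name, data, gzip_level, chunk_bytes) {
  ty <- uint_type_for(if (length(data)) max(data) else 0L)
  n <- length(data)
  dcpl <- rhdf5::H5Pcreate("H5P_DATASET_CREATE")
  on.exit(rhdf5::H5Pclose(dcpl), add = TRUE)
  rhdf5::H5Pset_obj_track_times(dcpl, FALSE)
  chunk_len <- max(1L, min(n, chunk_bytes %/% ty$bytes))
  rhdf5::H5Pset_chunk(dcpl, chunk_len)
  rhdf5::H5Pset_deflate(dcpl, gzip_level)
  sid <- rhdf5::H5Screate_simple(n)
  on.exit(rhdf5::H5Sclose(sid), add = TRUE)
  did <- rhdf5::H5Dcreate(fid, name, ty$h5, sid, dcpl = dcpl)
  rhdf5::H5Dwrite(did, as.integer(data))
  rhdf5::H5Dclose(did)
  invisible(NULL)
}

h5_attr <- function(fid, name, value) {
  rhdf5::h5writeAttribute(value, fid, name, asScalar = length(value) == 1L)
}

write_huffman_streams <- function(fid, prefix, symbols, gzip_level, chunk_bytes) {
  enc <- huffman_encode(symbols)
  h5_write_uint(fid, paste0(prefix, "_bits"), as.integer(enc$bits),
                gzip_level, chunk_bytes)
  # the canonical code table is small; attributes avoid per-dataset overhead
  h5_attr(fid, paste0(prefix, "_symbols"), as.integer(enc$symbols))
  h5_attr(fid, paste0(prefix, "_lengths"), as.integer(enc$lengths))
  h5_attr(fid, paste0(prefix, "_nbits"), as.integer(enc$nbits))
  h5_attr(fid, paste0(prefix, "_n"), as.integer(enc$n))
  invisible(NULL)
}

read_huffman_streams <- function(path, prefix, attrs) {
  stream <- list(
    bits = as.raw(c(rhdf5::h5read(path, paste0(prefix, "_bits")))),
    symbols = as.integer(attrs[[paste0(prefix, "_symbols")]]),
    lengths = as.integer(attrs[[paste0(prefix, "_lengths")]]),
    nbits = as.integer(attrs[[paste0(prefix, "_nbits")]]),
    n = as.integer(attrs[[paste0(prefix, "_n")]]))
  huffman_decode(stream)
}

#' Write packed coefficient streams to an HDF5 container
#'
#' Stores the quantized magnitudes, packed sign bits (8 per byte) and
#' delta-coded indices as chunked, gzip-compressed datasets in the
#' narrowest unsigned integer type that fits each array, together with
#' the metadata the decoder needs (signal length, quantization step,
#' transform description and band bookkeeping).  With `huffman = TRUE`
#' the magnitude and index streams pass through the canonical Huffman
#' stage first and the code tables are stored alongside the bits.
#'
#' @param packed An `ecg_packed` object from [pack_indices()].
#' @param meta List with `n_signal`, `spec`, `band_lengths`,
#'   `input_lengths` and optionally `fs`, `adc_bits`, `baseline`,
#'   `record_id` (as produced by the codec).
#' @param path Output file path (overwritten).
#' @param gzip_level DEFLATE level 0--9 applied per chunk.
#' @param chunk_bytes Approximate chunk size in bytes.
#' @param huffman Apply the entropy stage to magnitudes and index gaps.
#' @return Invisibly, the on-disk file size in bytes.
#' @export
write_container <- function(packed, meta, path, gzip_level = 4L,
                            chunk_bytes = 65536L, huffman = FALSE) {
  stopifnot(inherits(packed, "ecg_packed"))
  if (file.exists(path) && !file.remove(path)) stop("cannot overwrite ", path)
  fid <- rhdf5::H5Fcreate(path)
  on.exit(try(rhdf5::H5Fclose(fid), silent = TRUE), add = TRUE)
  k <- length(packed$magnitudes)
  gzip_level <- as.integer(gzip_level)
  chunk_bytes <- as.integer(chunk_bytes)

  h5_attr(fid, "layout_version", "1")
  h5_attr(fid, "n_signal", as.integer(meta$n_signal))
  h5_attr(fid, "n_coeff", as.integer(packed$n_coeff))
  h5_attr(fid, "n_kept", as.integer(k))
  h5_attr(fid, "delta", as.numeric(packed$delta))
  h5_attr(fid, "family", meta$spec$family)
  h5_attr(fid, "level", as.integer(meta$spec$level))
  h5_attr(fid, "extension_mode", meta$spec$mode)
  h5_attr(fid, "band_lengths", as.integer(meta$band_lengths))
  h5_attr(fid, "input_lengths", as.integer(meta$input_lengths))
  h5_attr(fid, "huffman", as.integer(huffman))
  h5_attr(fid, "gzip_level", gzip_level)
  h5_attr(fid, "chunk_bytes", chunk_bytes)
  h5_attr(fid, "fs", as.numeric(meta$fs %||% 360))
  h5_attr(fid, "adc_bits", as.integer(meta$adc_bits %||% 11L))
  h5_attr(fid, "baseline", as.numeric(meta$baseline %||% 1024))
  h5_attr(fid, "record_id", as.character(meta$record_id %||% "unnamed"))

  if (k > 0L) {
    sign_bits <- c(packed$signs, integer((-k) %% 8L))
    sign_bytes <- as.integer(packBits(as.integer(sign_bits), type = "raw"))
    h5_write_uint(fid, "signs", sign_bytes, gzip_level, chunk_bytes)
    if (huffman) {
      write_huffman_streams(fid, "magnitudes", packed$magnitudes,
                            gzip_level, chunk_bytes)
      write_huffman_streams(fid, "delta_indices", packed$delta_indices,
                            gzip_level, chunk_bytes)
    } else {
      h5_write_uint(fid, "magnitudes", packed$magnitudes, gzip_level, chunk_bytes)
      h5_write_uint(fid, "delta_indices", packed$delta_indices,
                    gzip_level, chunk_bytes)
    }
  }
  rhdf5::H5Fclose(fid)
  on.exit(NULL)
  invisible(file.size(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an HDF5 container back into packed streams
#'
#' Exact inverse of [write_container()]; Huffman-coded streams are
#' decoded transparently.
#'
#' @param path Container path.
#' @return List with `packed` (an `ecg_packed`), `meta` (signal and
#'   transform metadata) and `settings` (huffman flag, gzip level, chunk
#'   bytes).
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  attrs <- rhdf5::h5readAttributes(path, "/")
  needed <- c("layout_version", "n_signal", "n_coeff", "n_kept", "delta",
              "family", "level", "extension_mode", "band_lengths",
              "input_lengths", "huffman")
  missing <- setdiff(needed, names(attrs))
  if (length(missing)) {
    stop("container layout error: missing attribute(s) ",
         paste(missing, collapse = ", "))
  }
  if (as.character(attrs$layout_version) != "1") {
    stop("unknown container layout version: ", attrs$layout_version)
  }
  k <- as.integer(attrs$n_kept)
  huffman <- as.integer(attrs$huffman) == 1L
  if (k > 0L) {
    contents <- rhdf5::h5ls(path)$name
    want <- if (huffman) {
      c("signs", "magnitudes_bits", "delta_indices_bits")
    } else c("signs", "magnitudes", "delta_indices")
    miss <- setdiff(want, contents)
    if (length(miss)) {
      stop("container layout error: missing dataset(s) ",
           paste(miss, collapse = ", "))
    }
    sign_bytes <- as.raw(c(rhdf5::h5read(path, "signs")))
    signs <- as.integer(rawToBits(sign_bytes))[seq_len(k)]
    if (huffman) {
      magnitudes <- read_huffman_streams(path, "magnitudes", attrs)
      delta_indices <- read_huffman_streams(path, "delta_indices", attrs)
    } else {
      magnitudes <- as.integer(c(rhdf5::h5read(path, "magnitudes")))
      delta_indices <- as.integer(c(rhdf5::h5read(path, "delta_indices")))
    }
  } else {
    signs <- integer(0)
    magnitudes <- integer(0)
    delta_indices <- integer(0)
  }
  spec <- transform_spec(as.character(attrs$family),
                         as.integer(attrs$level),
                         as.character(attrs$extension_mode))
  packed <- structure(
    list(delta_indices = delta_indices, magnitudes = magnitudes,
         signs = signs, delta = as.numeric(attrs$delta),
         n_coeff = as.integer(attrs$n_coeff)),
    class = "ecg_packed")
  list(
    packed = packed,
    meta = list(
      n_signal = as.integer(attrs$n_signal),
      spec = spec,
      band_lengths = as.integer(attrs$band_lengths),
      input_lengths = as.integer(attrs$input_lengths),
      fs = as.numeric(attrs$fs %||% 360),
      adc_bits = as.integer(attrs$adc_bits %||% 11L),
      baseline = as.numeric(attrs$baseline %||% 1024),
      record_id = as.character(attrs$record_id %||% "unnamed")),
    settings = list(huffman = huffman,
                    gzip_level = as.integer(attrs$gzip_level %||% 4L),
                    chunk_bytes = as.integer(attrs$chunk_bytes %||% 65536L)))
}
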