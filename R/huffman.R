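# Canonical Huffman coding of non-negative integer symbol streams.
# Used as the optional entropy stage in front of the container: codes are
# rebuilt from the (symbol, code length) table alone, so only that table
# and the packed bits need to be stored.

# Huffman code lengths via the two-queue method (O(k log k)).
huffman_code_lengths <- function(syms, freqs) {
  k <- length(syms)
  if (k == 1L) return(1L)  # degenerate alphabet: one 1-bit code
  ord <- order(freqs, syms)
  # node arrays: weights and parents; leaves first (sorted), merged after
  n_nodes <- 2L * k - 1L
  weight <- numeric(n_nodes)
  parent <- integer(n_nodes)
  weight[seq_len(k)] <- freqs[ord]
  leaf_head <- 1L     # next unconsumed leaf
  merge_head <- k + 1L  # next unconsumed merged node
  merge_tail <- k     # last created merged node
  pop_min <- function() {
    use_leaf <-
      if (leaf_head <= k && merge_head <= merge_tail) {
        weight[leaf_head] <= weight[merge_head]
      } else leaf_head <= k
    if (use_leaf) { i <- leaf_head; leaf_head <<- leaf_head + 1L }
    else { i <- merge_head; merge_head <<- merge_head + 1L }
    i
  }
  for (node in (k + 1L):n_nodes) {
    i <- pop_min(); j <- pop_min()
    weight[node] <- weight[i] + weight[j]
    parent[i] <- node; parent[j] <- node
    merge_tail <- node
  }
  depth <- integer(n_nodes)
  for (node in (n_nodes - 1L):1L) depth[node] <- depth[parent[node]] + 1L
  lengths <- integer(k)
  lengths[ord] <- depth[seq_len(k)]
  lengths
}

# Canonical code values for symbols sorted by (length, symbol).
canonical_codes <- function(lengths_sorted) {
  k <- length(lengths_sorted)
  codes <- numeric(k)
  code <- 0
  for (i in seq_len(k)) {
    if (i > 1L) code <- (code + 1) * 2^(lengths_sorted[i] - lengths_sorted[i - 1L])
    codes[i] <- code
  }
  codes
}

#' Huffman-encode an integer symbol stream
#'
#' Builds a canonical Huffman code from the empirical symbol frequencies
#' and packs the codewords into a raw bitstream.  A single-symbol
#' alphabet receives a 1-bit code.  The code is fully described by the
#' `(symbols, lengths)` table, which is what the container stores.
#'
#' @param symbols Non-empty vector of non-negative integers.
#' @return Object of class `huffman_stream`: `bits` (raw vector), `nbits`
#'   (number of meaningful bits), `symbols` and `lengths` (canonical
#'   table, sorted by code length then symbol), `n` (symbol count).
#' @export
#' @examples
#' enc <- huffman_encode(c(0, 0, 0, 1))
#' enc$nbits  # 4
huffman_encode <- function(symbols) {
  if (length(symbols) == 0L) stop("empty symbol stream")
  symbols <- as.integer(symbols)
  if (any(symbols < 0L)) stop("symbols must be non-negative")
  tab <- table(symbols)
  syms <- as.integer(names(tab))
  freqs <- as.numeric(tab)
  lens <- huffman_code_lengths(syms, freqs)
  ord <- order(lens, syms)
  syms_c <- syms[ord]
  lens_c <- lens[ord]
  codes <- canonical_codes(lens_c)
  # per-symbol bit patterns (MSB first), then concatenate along the stream
  bit_list <- lapply(seq_along(syms_c), function(i) {
    l <- lens_c[i]
    as.integer(floor(codes[i] / 2^((l - 1L):0L)) %% 2)
  })
  stream_bits <- unlist(bit_list[match(symbols, syms_c)], use.names = FALSE)
  nbits <- length(stream_bits)
  pad <- (-nbits) %% 8L
  if (pad) stream_bits <- c(stream_bits, integer(pad))
  structure(
    list(bits = packBits(as.integer(stream_bits), type = "raw"),
         nbits = nbits, symbols = syms_c, lengths = lens_c,
         n = length(symbols)),
    class = "huffman_stream")
}

#' Decode a canonical Huffman bitstream
#'
#' Exact inverse of [huffman_encode()].
#'
#' @param stream A `huffman_stream` (or a list with the same fields).
#' @return Integer vector of the original symbols.
#' @export
huffman_decode <- function(stream) {
  syms <- as.integer(stream$symbols)
  lens <- as.integer(stream$lengths)
  n <- stream$n
  if (n == 0L) return(integer(0))
  codes <- canonical_codes(lens)
  max_len <- max(lens)
  # per-length decoding tables
  first_code <- rep(NA_real_, max_len)
  first_pos <- integer(max_len)
  count <- integer(max_len)
  for (l in unique(lens)) {
    sel <- which(lens == l)
    first_code[l] <- codes[sel[1L]]
    first_pos[l] <- sel[1L]
    count[l] <- length(sel)
  }
  bits <- as.integer(rawToBits(stream$bits))[seq_len(stream$nbits)]
  out <- integer(n)
  oi <- 1L
  code <- 0
  l <- 0L
  for (b in bits) {
    code <- code * 2 + b
    l <- l + 1L
    if (l <= max_len && count[l] > 0L) {
      off <- code - first_code[l]
      if (off >= 0 && off < count[l]) {
        out[oi] <- syms[first_pos[l] + off]
        oi <- oi + 1L
        if (oi > n) break
        code <- 0
        l <- 0L
      }
    }
    if (l > max_len) stop("corrupt Huffman stream: no codeword matches")
  }
  if (oi <= n) stop("corrupt Huffman stream: bitstream exhausted early")
  out
}
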