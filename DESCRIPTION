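Package: ecgzip
Title: Lossy Compression of ECG Signals by Wavelet Thresholding and
    Chunked-Gzip HDF5 Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A transform codec for single-channel electrocardiogram (ECG)
    records. The signal is decomposed with a multilevel discrete wavelet
    transform (CDF 9/7 by default, with db5, sym4 and coif4 alternatives),
    the largest coefficients are selected by a cumulative-energy rule, the
    survivors are quantized with a mid-tread uniform quantizer, their signs
    and delta-coded positions are stored as narrow integer streams in a
    chunked, gzip-compressed HDF5 container, and the decoder inverts every
    step.  Includes a WFDB format-212 reader for MIT-BIH style records, a
    synthetic ECG generator for offline testing, an optional canonical
    Huffman entropy stage, a run-length significance-map baseline, a full
    distortion/compression metric suite (PRD, PRDN, CR, QS, local prd), a
    benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rhdf5,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
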