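---
title: "Lossy ECG compression by wavelet thresholding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossy ECG compression by wavelet thresholding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The codec in one paragraph

`ecgzip` compresses a single-channel ECG record `f` of `N` samples in three
steps. First, a multilevel discrete wavelet transform turns `f` into a flat
coefficient vector `w` (approximation band first, then detail bands coarsest
to finest). Second, the coefficients are thinned and discretized: optionally
the largest coefficients are selected by a cumulative-energy rule
(method (a)), then every surviving coefficient is quantized by a mid-tread
uniform quantizer `q = floor(c / delta + 1/2)` and entries mapped to zero are
dropped (method (b) is exactly this pipeline with the selection switched
off). Third, the survivors are re-ordered by position, their positions are
stored as first differences of the sorted index list, magnitudes, sign bits
(packed 8 per byte) and index gaps are written as narrow unsigned integer
datasets in a chunked HDF5 file with per-chunk DEFLATE (gzip) compression.
The decoder reads the streams, rebuilds the positions by prefix sum, forms
`delta * magnitude * (2 * sign - 1)` at each position of a zero coefficient
vector, and inverts the transform.

The design bet is that for ECG at moderate distortion the gzip layer of the
container is entropy coding enough: the index-gap stream is dominated by the
value 1 (nonzero coefficients cluster in the low bands) and compresses
extremely well, so no dedicated entropy coder is needed in the loop. An
optional canonical Huffman stage is provided to test precisely that claim.

## Distortion and compression measures

For a reconstruction `fr`, the primary distortion measure is the percentage
root-mean-square difference on the *raw stored samples*,

    PRD = 100 * ||f - fr|| / ||f||,

which therefore depends on the ADC offset (about 1024 for 11-bit MIT-BIH
records). `PRDN` uses the mean-removed denominator `||f - mean(f)||` and is
offset-independent; a `baseline_subtract` option reproduces the convention
of benchmarks that subtract 1024 before computing PRD (the same
reconstruction then scores an order of magnitude worse — the two conventions
must never be mixed when comparing methods). Compression is reported as
`CR = uncompressed bytes / compressed bytes` and `QS = CR / PRD`. Local
quality uses segments of `L = 2000` samples (`Q = floor(N / L)` segments,
trailing remainder dropped): per-segment prd, its mean, its unbiased
(`Q - 1` divisor) standard deviation, and the worst segment
`argmax prd(q)` (ties to the first). Database summaries are unweighted
means over records — including the quality score, which is averaged
per record rather than recomputed from mean CR and mean PRD.

The uncompressed size in CR needs a convention; none is universal. The
default charges `adc_bits` bits per sample (11 bits for MIT-BIH), which best
matches how these records are usually costed; `int16` (2 bytes/sample) and
`wfdb` (1.5 bytes/sample, the format-212 disk size) are available, and the
choice is recorded in the run manifest because it rescales every CR by a
constant.

## The wavelet engine

Four families are built in: `db5`, `sym4`, `coif4` (orthonormal) and
`cdf97`, the biorthogonal 9/7-tap Cohen–Daubechies–Feauveau pair used by
JPEG2000. `cdf97` at level 4 is the default: across families and levels it
gives the best compression on ECG-like signals, but the margin is small —
the family is not where the codec's performance comes from.

Two boundary policies are implemented, matching the common conventions for
finite signals:

* `symmetric` (default): half-point reflection at the edges. The
  coefficient count slightly exceeds `N` (by about the filter length per
  level); positions are stored explicitly, so the surplus only costs a few
  stream elements.
* `periodization`: circular extension, exactly `N` coefficients, and exact
  energy conservation for the orthonormal families (Parseval). This is the
  mode to use when reasoning about energy budgets; odd-length inputs are
  padded by repeating the last sample, and the pad is cropped on inversion.

Perfect reconstruction holds in both modes for every family at working
precision (the test grid asserts `1e-8` relative; observed errors are at
`1e-12` and below). Because indices are stored explicitly, the flat
coefficient ordering (approximation first, details coarsest to finest) is a
free choice; any fixed ordering round-trips.

## Coefficient selection and quantization

The selection rule sorts `|w|` ascending, forms cumulative energies
`t(n)`, finds the smallest `n` with `t(n) >= tol^2`, and keeps the
coefficients from that rank up. Ties between equal magnitudes break by
ascending original index, making the output independent of the sort
implementation. The threshold comes from a pre-quantization distortion
budget `PRD_0`: `tol = PRD_0 * ||f|| / 100`, exact for orthonormal
transforms and an excellent approximation for `cdf97`. When a target PRD
is given without an explicit `PRD_0`, the default is
`PRD_0 = 0.75 * target`, the middle of the 70–80% band that works well in
practice: a much smaller `PRD_0` makes the selection inert (the quantizer
then does all the thinning and methods (a) and (b) coincide); a `PRD_0`
too close to the target forces a tiny `delta` and hurts compression.

The quantizer is applied to *signed* coefficient values exactly as the
formula reads. The alternative — quantizing magnitudes — differs at exact
half-step ties (`c = -delta/2` maps to 0 under the signed rule and to 1
under the magnitude rule); the signed reading is adopted and the sign bit
is derived from the quantized value, so a coefficient eliminated by the
quantizer never leaves a stray sign behind.

`delta` can be tuned to a target PRD by bisection over
`[1e-3, 1] * max(|f|)`, measuring the achieved PRD through the full
quantize–dequantize–inverse loop (no file I/O inside the search). The
stopping tolerance of 0.005 percent points resolves distortion figures
printed to two decimals; 40 iterations bound the search. PRD is monotone in
`delta` up to quantization granularity, so bisection converges in
practice within 10–15 iterations; if the target lies below the floor
reachable at the smallest step, the tuner reports that floor instead of
thrashing.

## Storage

The container is genuine HDF5: any standard reader can open it. Datasets
use the narrowest unsigned type that fits their maximum (widening, never
truncating), are chunked (64 KiB by default) and DEFLATE-compressed
(level 4 by default; the level and chunk size are recorded as attributes
since they shift CR by a few percent). Object-header time tracking is
disabled so identical payloads produce byte-identical files — this is what
makes the method (a)/(b) equivalence testable at the file level, and it is
also why the container stores only decode-relevant metadata (transform
descriptor, `N`, `delta`, stream dtypes) rather than which method produced
it; the method and its parameters live in the run manifest.

Two alternative position codings exist for comparison experiments: a
run-length coding of the binary significance map (alternating run lengths
starting with the zero run), and the canonical Huffman stage, applied to
the magnitude and index-gap streams with the code table stored as
attributes. On the synthetic corpus the Huffman stage *loses* to plain
gzip: the per-symbol Huffman stream reaches the iid entropy bound, but
DEFLATE additionally exploits serial correlation between symbols (runs of
gap = 1, repeated magnitudes), which a memoryless code cannot see. On real
records with different symbol statistics the stage can pay off at low PRD;
the flag is there to measure, not to presume.

## The synthetic generator, and what tests on it do not show

Offline tests and the acceptance protocols use a synthetic generator: each
beat is five Gaussian bumps (P, Q, R, S, T) with configurable amplitudes,
offsets and widths; RR intervals are Gaussian-jittered (truncated at 3 sd);
a 0.33 Hz sinusoid emulates respiration-driven baseline wander; white noise
is added; and the waveform is digitized at 360 Hz to 11 bits with a 1024
offset — the MIT-BIH recording format. Defaults (R amplitude 250 ADC units
= 1.25 mV at 200 units/mV, RR 0.8 s, wander 20 units, noise sd 4 units)
were chosen once as representative of a clean adult resting ECG.

The generator is deliberately simple. It produces no arrhythmia, no
electrode artifacts, no muscle noise bursts, and its spectral content is
smoother than real ECG. Since the codec is morphology-agnostic (it makes no
use of QRS structure), passing tests on synthetic data validate the
*pipeline* — reconstruction bounds, bijective codings, metric definitions,
tuner convergence — but the *absolute* compression ratios on synthetic
records run somewhat higher than on the MIT-BIH database at matched PRD
(cleaner signals concentrate energy in fewer coefficients). Database-level
figures must therefore be produced with `bench_wfdb_dir()` on the actual
records, with one global `delta` across all records (the per-database
protocol: mean PRD is reported for a fixed step, not tuned per record).
The WFDB reader takes the first lead by default and the bench harness
records the channel used, since published per-record figures do not always
state the lead.

## Numerical choices and degenerate inputs

* Selection with `tol = 0` keeps everything; `tol^2` above the total energy
  yields an empty selection, which flows through the whole pipeline (a
  valid container with zero kept coefficients decodes to the zero signal).
* An all-constant signal has undefined PRDN; the metric errors rather than
  returning infinity.
* Problem sizes in the tests: transform grids up to 4096 samples,
  end-to-end checks on 650000-sample records (the standard half-hour
  length), 10^3 random selection instances and 10^4 random coding
  instances; the full suite runs in about half a minute.
* Acceptance protocols use an 8-record synthetic corpus of 650000-sample
  records — large enough for stable means, small enough to run in under a
  minute.

## Known limitations

* Only WFDB format 212 is parsed (the MIT-BIH packing); other WFDB formats
  need conversion first.
* The quantizer uses one global `delta` across bands; per-band steps are
  out of scope (uniform quantization across bands is part of the design's
  simplicity and works well for ECG).
* No diagnostic-quality metrics (QRS detectability, WDD); PRD-family
  metrics only.
* The Huffman bitstream decoder is a plain R loop; decoding multi-hundred-
  kilobyte entropy-coded containers is seconds, not milliseconds.
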