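#' Analysis/synthesis filter banks for the supported wavelet families
#'
#' Returns the four FIR filters of a two-channel perfect-reconstruction
#' filter bank: decomposition low/high pass (`dec_lo`, `dec_hi`) and
#' reconstruction low/high pass (`rec_lo`, `rec_hi`).  `db5`, `sym4` and
#' `coif4` are orthonormal; `cdf97` is the biorthogonal 9/7-tap
#' Cohen--Daubechies--Feauveau pair (the JPEG2000 lossy filter, also known
#' as bior4.4), padded with zeros to an even 10-tap length so that all
#' families share the same indexing convention.
#'
#' The numeric values are the standard published coefficients at full
#' double precision.
#'
#' @param family One of `"db5"`, `"sym4"`, `"coif4"`, `"cdf97"`.
#' @return A list with components `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric vectors of equal even length) and `family`.
#' @export
#' @examples
#' fb <- wavelet_filters("cdf97")
#' length(fb$dec_lo)
wavelet_filters <- function(family = c("cdf97", "db5", "sym4", "coif4")) {
  family <- match.arg(family)
  fb <- .wavelet_filter_table[[family]]
  c(fb, list(family = family))
}

.wavelet_filter_table <- list(
  db5 = list(
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
               0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
               0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
               0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
               0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
               -0.07757149384004572, -0.006241490212798274, 0.012580751999081999,
               0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
               0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
               0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
               0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.006241490212798274,
               -0.07757149384004572, -0.032244869584638375, 0.24229488706638203,
               0.13842814590132074, -0.7243085284377729, 0.6038292697971896,
               -0.16010239797419293)
  ),
  sym4 = list(
    dec_lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
               0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
               -0.012603967262037833, 0.0322231006040427),
    dec_hi = c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
               0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
               0.02963552764599851, -0.07576571478927333),
    rec_lo = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
               0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
               -0.02963552764599851, -0.07576571478927333),
    rec_hi = c(-0.07576571478927333, 0.02963552764599851, 0.49761866763201545,
               -0.8037387518059161, 0.29785779560527736, 0.09921954357684722,
               -0.012603967262037833, -0.0322231006040427)
  ),
  coif4 = list(
    dec_lo = c(-1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05,
               6.233885431278719e-05, -0.0002599743371222568, -0.0005890202246332165,
               0.0012665610789256603, 0.0037514346971460866, -0.0056582838001308835,
               -0.015211728187697211, 0.02508225333794961, 0.03933442260558915,
               -0.09622042453595264, -0.06662747236681717, 0.43438603311435653,
               0.7822389344242826, 0.41530842700068227, -0.05607731960356926,
               -0.08126671024919373, 0.02668230466960483, 0.01606894713157503,
               -0.007346167936268051, -0.001629492425226786, 0.000892313902537003),
    dec_hi = c(-0.000892313902537003, -0.001629492425226786, 0.007346167936268051,
               0.01606894713157503, -0.02668230466960483, -0.08126671024919373,
               0.05607731960356926, 0.41530842700068227, -0.7822389344242826,
               0.43438603311435653, 0.06662747236681717, -0.09622042453595264,
               -0.03933442260558915, 0.02508225333794961, 0.015211728187697211,
               -0.0056582838001308835, -0.0037514346971460866, 0.0012665610789256603,
               0.0005890202246332165, -0.0002599743371222568, -6.233885431278719e-05,
               3.1229861599195265e-05, 3.259647940030751e-06, -1.7849909144933469e-06),
    rec_lo = c(0.000892313902537003, -0.001629492425226786, -0.007346167936268051,
               0.01606894713157503, 0.02668230466960483, -0.08126671024919373,
               -0.05607731960356926, 0.41530842700068227, 0.7822389344242826,
               0.43438603311435653, -0.06662747236681717, -0.09622042453595264,
               0.03933442260558915, 0.02508225333794961, -0.015211728187697211,
               -0.0056582838001308835, 0.0037514346971460866, 0.0012665610789256603,
               -0.0005890202246332165, -0.0002599743371222568, 6.233885431278719e-05,
               3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
    rec_hi = c(-1.7849909144933469e-06, 3.259647940030751e-06, 3.1229861599195265e-05,
               -6.233885431278719e-05, -0.0002599743371222568, 0.0005890202246332165,
               0.0012665610789256603, -0.0037514346971460866, -0.0056582838001308835,
               0.015211728187697211, 0.02508225333794961, -0.03933442260558915,
               -0.09622042453595264, 0.06662747236681717, 0.43438603311435653,
               -0.7822389344242826, 0.41530842700068227, 0.05607731960356926,
               -0.08126671024919373, -0.02668230466960483, 0.01606894713157503,
               0.007346167936268051, -0.001629492425226786, -0.000892313902537003)
  ),
  cdf97 = list(
    dec_lo = c(0.0, 0.03782845550726404, -0.023849465019556843, -0.11062440441843718,
               0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
               -0.11062440441843718, -0.023849465019556843, 0.03782845550726404),
    dec_hi = c(0.0, -0.06453888262869706, 0.04068941760916406, 0.41809227322161724,
               -0.7884856164055829, 0.41809227322161724, 0.04068941760916406,
               -0.06453888262869706, 0.0, 0.0),
    rec_lo = c(0.0, -0.06453888262869706, -0.04068941760916406, 0.41809227322161724,
               0.7884856164055829, 0.41809227322161724, -0.04068941760916406,
               -0.06453888262869706, 0.0, 0.0),
    rec_hi = c(0.0, -0.03782845550726404, -0.023849465019556843, 0.11062440441843718,
               0.37740285561283066, -0.8526986790088938, 0.37740285561283066,
               0.11062440441843718, -0.023849465019556843, -0.03782845550726404)
  )
)
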