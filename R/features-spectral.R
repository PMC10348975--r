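#' Relative band power from a PSD
#'
#' Ratio of the discrete PSD sum over a frequency band to the sum over the
#' full analysis range (0-45 Hz by default, the upper cut-off of the band-pass
#' filter). Grid sums are used, not trapezoidal integration; a bin is in-band
#' when its center frequency lies in `[f1, f2]` inclusive.
#'
#' @param psd A tibble as returned by [welch_psd()] (`freq`, `power`).
#' @param f1,f2 Band limits in Hz (theta = 4-8, beta = 12-30).
#' @param f_l,f_h Denominator limits in Hz (defaults 0 and 45).
#'
#' @return Fraction in \[0, 1\]; `NaN` when the total in-range power is zero
#'   (degenerate segment), with a warning.
#' @export
#'
#' @examples
#' psd <- welch_psd(sin(2 * pi * 6 * seq(0, 3, length.out = 1500)), fs = 500)
#' relative_power(psd, 4, 8)    # theta: close to 1 for a 6 Hz tone
relative_power <- function(psd, f1, f2, f_l = 0, f_h = 45) {
  stopifnot(f_l <= f1, f1 < f2, f2 <= f_h)
  total <- sum(psd$power[psd$freq >= f_l & psd$freq <= f_h])
  if (!is.finite(total) || total <= 0) {
    warning("zero total power in [f_l, f_h]; relative power undefined")
    return(NaN)
  }
  band <- sum(psd$power[psd$freq >= f1 & psd$freq <= f2])
  band / total
}

#' Normalized spectral edge frequency
#'
#' The smallest grid frequency below which a fraction `r` of the total PSD
#' power (0 to fs/2) lies, normalized by the 45 Hz analysis limit so the
#' result is comparable across sampling rates. SEF95 (`r = 0.95`) above the
#' alpha band is taken as a marker of higher consciousness levels. The
#' first-bin-crossing convention is used (no interpolation between bins).
#'
#' @param psd A tibble as returned by [welch_psd()].
#' @param r Power fraction in (0, 1); default 0.95.
#' @param f_norm Normalization frequency in Hz (default 45, the filter's
#'   upper cut-off).
#'
#' @return Normalized edge frequency (edge / `f_norm`); `NaN` with a warning
#'   when the total power is zero.
#' @export
#'
#' @examples
#' psd <- welch_psd(rnorm(1500), fs = 500)
#' sef(psd)            # SEF95, normalized by 45 Hz
#' sef(psd, r = 0.5)   # median frequency
sef <- function(psd, r = 0.95, f_norm = 45) {
  stopifnot(r > 0, r < 1)
  total <- sum(psd$power)
  if (!is.finite(total) || total <= 0) {
    warning("zero total power; SEF undefined")
    return(NaN)
  }
  idx <- which(cumsum(psd$power) >= r * total)[1]
  psd$freq[idx] / f_norm
}
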