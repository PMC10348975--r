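# Welch spectral estimation with the pipeline's fixed scheme:
# Hamming taper, sub-windows of 1/8 the segment length, 50% overlap.
# Implemented directly on stats::fft; the same windowed FFT segments are
# reused for auto- and cross-spectra (coherency), so the plan is factored out.

# Hamming taper (periodic form, as used by spectral estimators).
.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / n)

# Sub-window plan for a segment of n samples.
.welch_plan <- function(n, fs) {
  L <- n %/% 8L
  if (L < 2) stop("segment too short for Welch estimation (need >= 16 samples)")
  hop <- max(1L, L %/% 2L)
  n_seg <- (n - L) %/% hop + 1L
  starts <- (seq_len(n_seg) - 1L) * hop
  w <- .hamming(L)
  nfreq <- L %/% 2L + 1L
  list(L = L, hop = hop, starts = starts, w = w, nfreq = nfreq,
       freqs = (seq_len(nfreq) - 1L) * fs / L,
       scale = 1 / (fs * sum(w^2)))
}

# Windowed FFT segments of one channel: complex nfreq x n_seg matrix.
.welch_fft <- function(x, plan) {
  segs <- vapply(plan$starts,
                 function(s) x[(s + 1):(s + plan$L)] * plan$w,
                 numeric(plan$L))
  f <- stats::mvfft(segs)
  f[seq_len(plan$nfreq), , drop = FALSE]
}

# One-sided auto-spectrum from the segment FFT matrix.
.welch_auto <- function(f, plan) {
  p <- rowMeans(Re(f * Conj(f))) * plan$scale
  # double all bins except DC (and Nyquist when L is even) for one-sided PSD
  two <- rep(2, plan$nfreq)
  two[1] <- 1
  if (plan$L %% 2L == 0L) two[plan$nfreq] <- 1
  p * two
}

# Complex cross-spectrum (one-sided scaling shared with .welch_auto cancels
# in coherency, so plain segment-averaged products suffice).
.welch_cross <- function(fx, fy) rowMeans(fx * Conj(fy))

#' Welch power spectral density of one signal segment
#'
#' Estimates the PSD with a Hamming window of 1/8 the segment length and 50%
#' overlap between sub-windows (Welch's method). This fixed scheme is the one
#' used for all spectral features and for coherency.
#'
#' @param x Numeric vector, one channel of one analysis window.
#' @param fs Sampling rate in Hz.
#'
#' @return A tibble with columns `freq` (Hz, 0 to fs/2 on the sub-window FFT
#'   grid) and `power` (one-sided PSD, amplitude^2 per Hz, nonnegative).
#' @export
#'
#' @examples
#' x <- sin(2 * pi * 6 * seq(0, 3, length.out = 1500))
#' psd <- welch_psd(x, fs = 500)
#' psd$freq[which.max(psd$power)]  # near 6 Hz
welch_psd <- function(x, fs) {
  stopifnot(is.numeric(x), length(x) >= 16, fs > 0)
  plan <- .welch_plan(length(x), fs)
  f <- .welch_fft(x, plan)
  tibble::tibble(freq = plan$freqs, power = pmax(.welch_auto(f, plan), 0))
}
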