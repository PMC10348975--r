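# Connectivity features: theta-band imaginary coherency (linear coupling,
# insensitive to zero-lag volume conduction) and theta-tuned weighted symbolic
# mutual information (linear + nonlinear coupling between ordinal patterns).

#' Imaginary part of coherency between two channels, band-averaged
#'
#' Coherency is the normalized cross-spectrum
#' `S_xy(f) / sqrt(S_xx(f) S_yy(f))`; only its imaginary part is kept, which
#' suppresses instantaneous (volume-conducted) coupling. Auto- and
#' cross-spectra use the same Welch scheme as [welch_psd()]. The scalar
#' returned is the mean of `|Im(coherency)|` over the bins whose center lies
#' inside the band (theta, 4-8 Hz, by default); magnitudes are averaged so
#' that lead/lag asymmetries across bins do not cancel.
#'
#' @param x,y Numeric vectors of equal length (two channels, one window).
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric band limits in Hz (default `c(4, 8)`).
#'
#' @return Scalar in \[0, 1\]; `NaN` with a warning when either channel has
#'   zero in-band power.
#' @export
#'
#' @examples
#' # quadrature theta-band pair: coherent with ~90 degree lag across the band
#' n <- 4000
#' f <- stats::fft(stats::rnorm(n))
#' fr <- (seq_len(n) - 1) * 250 / n; fr <- pmin(fr, 250 - fr)
#' f[fr < 4 | fr > 8] <- 0
#' x <- Re(stats::fft(f, inverse = TRUE) / n)
#' h <- rep(0, n); h[1] <- 1; h[2:(n/2)] <- 2; h[n/2 + 1] <- 1
#' y <- Im(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)  # Hilbert of x
#' icoh_pair(x, y, fs = 250)  # near 1
icoh_pair <- function(x, y, fs, band = c(4, 8)) {
  stopifnot(length(x) == length(y), length(band) == 2, band[2] < fs / 2)
  plan <- .welch_plan(length(x), fs)
  fx <- .welch_fft(x, plan)
  fy <- .welch_fft(y, plan)
  sxx <- rowMeans(Re(fx * Conj(fx)))
  syy <- rowMeans(Re(fy * Conj(fy)))
  sxy <- .welch_cross(fx, fy)
  in_band <- plan$freqs >= band[1] & plan$freqs <= band[2]
  if (!any(in_band)) stop("no Welch frequency bin falls inside the band")
  denom <- sqrt(sxx[in_band] * syy[in_band])
  if (any(denom <= 0)) {
    warning("zero-power channel in band; iCOH undefined")
    return(NaN)
  }
  mean(abs(Im(sxy[in_band] / denom)))
}

# The 6 ordinal patterns for k = 3, as rank triplets, and the index of each
# pattern's sign-opposite (ranks mapped r -> 4 - r).
.k3_patterns <- rbind(
  c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
)
.k3_opposite <- apply(4 - .k3_patterns, 1, function(p) {
  which(apply(.k3_patterns, 1, identical, as.numeric(p)))
})

#' Ordinal-pattern symbolization of a signal
#'
#' Maps a window to the sequence of ordinal (rank) patterns of `k` samples
#' separated by `tau_samples`. With `k = 3` and `tau` = 16 ms (8 samples at
#' 500 Hz) the patterns are tuned to theta-band EEG dynamics. Ties are broken
#' by temporal order: the earlier sample ranks lower.
#'
#' @param x Numeric vector, length > `(k - 1) * tau_samples`.
#' @param k Motif length; only `k = 3` (alphabet of 6 patterns) is supported.
#' @param tau_samples Separation between motif elements in samples (default 8).
#'
#' @return Integer vector of symbols in `1:6` (indices into the rank-pattern
#'   alphabet), length `length(x) - (k - 1) * tau_samples`, with attributes
#'   `k` and `tau_samples`.
#' @export
#'
#' @examples
#' symbolize(c(1, 3, 2), tau_samples = 1)  # single symbol: pattern (1, 3, 2)
symbolize <- function(x, k = 3, tau_samples = 8) {
  if (k != 3) stop("only k = 3 is supported")
  tau_samples <- as.integer(tau_samples)
  n <- length(x)
  if (n <= (k - 1) * tau_samples) stop("window too short to symbolize")
  m <- n - (k - 1) * tau_samples
  v1 <- x[seq_len(m)]
  v2 <- x[seq_len(m) + tau_samples]
  v3 <- x[seq_len(m) + 2L * tau_samples]
  # ranks with earlier-sample-ranks-lower tie-breaking
  r1 <- 1L + (v2 < v1) + (v3 < v1)
  r2 <- 1L + (v1 <= v2) + (v3 < v2)
  r3 <- 1L + (v1 <= v3) + (v2 <= v3)
  # encode rank triplet -> index in .k3_patterns (lexicographic)
  code <- (r1 - 1L) * 9L + (r2 - 1L) * 3L + (r3 - 1L)
  lut <- integer(27)
  lut[(.k3_patterns[, 1] - 1) * 9 + (.k3_patterns[, 2] - 1) * 3 +
        (.k3_patterns[, 3] - 1) + 1] <- seq_len(6)
  sym <- lut[code + 1L]
  structure(sym, k = k, tau_samples = tau_samples)
}

#' Weighted symbolic mutual information between two symbol sequences
#'
#' Mutual information between the empirical joint distribution of ordinal
#' patterns, normalized by `log(k!)` and weighted so that identical and
#' sign-opposite pattern pairs contribute zero (discounting common-source /
#' volume-conduction coupling). Independent signals score near 0; a
#' deterministic non-trivial pattern correspondence scores 1. The estimate is
#' floored at 0 (sampling noise can push the weighted sum microscopically
#' negative).
#'
#' @param sx,sy Equal-length symbol sequences from [symbolize()] with the
#'   same `k` and `tau_samples`.
#' @return Scalar in \[0, 1\].
#' @export
#'
#' @examples
#' x <- rnorm(5000); y <- rnorm(5000)
#' wsmi_pair(symbolize(x), symbolize(y))  # independent: near 0
wsmi_pair <- function(sx, sy) {
  if (length(sx) != length(sy)) stop("symbol sequences must have equal length")
  if (!identical(attr(sx, "tau_samples"), attr(sy, "tau_samples"))) {
    stop("symbol sequences must share the same tau")
  }
  n <- length(sx)
  if (n < 6) warning("fewer symbols than alphabet size; wSMI estimate unstable")
  joint <- matrix(tabulate(sx + 6L * (sy - 1L), nbins = 36L), nrow = 6) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  w <- matrix(1, 6, 6)
  diag(w) <- 0
  w[cbind(seq_len(6), .k3_opposite)] <- 0
  terms <- joint * log(joint / outer(px, py))
  terms[joint == 0] <- 0
  max(sum(w * terms) / log(factorial(3)), 0)
}

#' Average pairwise connectivity over all channel pairs
#'
#' Arithmetic mean over unordered channel pairs, excluding `NaN` pairs
#' (degenerate channels), mirroring the across-channel averaging used for the
#' univariate features.
#'
#' @param values Numeric vector of per-pair connectivity values.
#' @return Scalar mean; `NaN` with a warning when every pair is `NaN`.
#' @export
aggregate_pairs <- function(values) {
  stopifnot(length(values) >= 1)
  ok <- is.finite(values)
  if (!any(ok)) {
    warning("all channel pairs undefined; aggregate is NaN")
    return(NaN)
  }
  mean(values[ok])
}

# tau in samples for a given sampling rate: round(16 ms * fs), warning when
# the rounding error exceeds 10% of the requested lag.
.wsmi_tau_samples <- function(fs, tau_s = 0.016) {
  exact <- tau_s * fs
  tau <- max(1L, as.integer(round(exact)))
  if (abs(tau - exact) / exact > 0.1) {
    warning(sprintf(
      "wSMI lag rounded from %.2f to %d samples (> 10%% rounding error at fs = %g Hz)",
      exact, tau, fs))
  }
  tau
}
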