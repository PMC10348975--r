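# Complexity features: Poincare ellipsoid radius ratio and Hilbert-binarized
# Lempel-Ziv complexity.

#' Poincare ellipsoid radius ratio (SD1/SD2)
#'
#' The Poincare plot draws `x(t)` against `x(t + tau)`. SD1 is the standard
#' deviation of the points around the short axis (perpendicular to the line of
#' identity) and SD2 around the long axis. Their ratio ERR = SD1/SD2
#' approaches 1 for random signals (round cloud) and 0 for linear/deterministic
#' ones (elongated cloud); larger values indicate more complex EEG and higher
#' consciousness levels.
#'
#' SD1 = (sqrt(2)/2) * SD(x(t) - x(t+tau)) and
#' SD2 = sqrt(2 * SD(x(t))^2 - SD1^2), with SD taken over t = 1..n-tau so the
#' closed form matches the geometric definition on the plotted pairs.
#'
#' @param x Numeric vector (one channel of one window), length >= `tau` + 2.
#' @param tau Delay in samples (default 1).
#'
#' @return ERR in \[0, Inf); `NaN` with a warning when SD2 = 0 (degenerate,
#'   e.g. a perfectly anti-periodic or constant signal).
#' @export
#'
#' @examples
#' poincare_err(rnorm(1e4))          # ~ 1: randomness
#' poincare_err(seq_len(100))        # 0: constant first differences
poincare_err <- function(x, tau = 1) {
  n <- length(x)
  stopifnot(tau >= 1, n >= tau + 2)
  x1 <- x[seq_len(n - tau)]
  x2 <- x[(tau + 1):n]
  sd1sq <- 0.5 * stats::var(x1 - x2)
  sd2sq <- 2 * stats::var(x1) - sd1sq
  if (!is.finite(sd2sq) || sd2sq <= .Machine$double.eps * max(stats::var(x1), 1)) {
    warning("SD2 = 0; ERR undefined for this segment")
    return(NaN)
  }
  sqrt(max(sd1sq, 0) / sd2sq)
}

# Hilbert transform via the analytic-signal FFT construction: returns the
# imaginary part x_h of the analytic signal x + i*x_h.
.hilbert <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(f * h, inverse = TRUE) / n)
}

#' Binarize a signal by its Hilbert transform magnitude
#'
#' Transforms the window to its analytic signal and emits bit 1 where the
#' absolute Hilbert transform exceeds its own mean, 0 otherwise (ties go to
#' 0). The bit sequence feeds the Lempel-Ziv complexity. The threshold scales
#' with the signal, so binarization is amplitude-invariant.
#'
#' @param x Numeric vector, length >= 4.
#' @return Integer vector of 0/1 bits, same length as `x`.
#' @export
#'
#' @examples
#' bits <- hilbert_binarize(sin(2 * pi * 5 * seq(0, 2, by = 1e-3)))
#' mean(bits)  # fraction of 1s: 2*acos(2/pi)/pi for a pure tone
hilbert_binarize <- function(x) {
  stopifnot(length(x) >= 4)
  a <- abs(.hilbert(x))
  as.integer(a > mean(a))
}

#' Lempel-Ziv complexity of a binary sequence
#'
#' Counts the number of distinct phrases found as the sequence is scanned
#' left to right under exhaustive LZ76 parsing (Kaspar-Schuster scheme), the
#' standard complexity estimator in the EEG literature. Optionally normalized
#' by `n / log2(n)`, the asymptotic complexity of a random binary sequence,
#' so random signals score near 1. An LZ78 dictionary parse is available for
#' comparison.
#'
#' @param bits Integer/numeric vector of 0s and 1s (nonempty).
#' @param normalize Return `c(n) * log2(n) / n` instead of the raw phrase
#'   count (default `TRUE`).
#' @param scheme `"lz76"` (default) or `"lz78"`.
#'
#' @return Complexity (normalized value, or phrase count when
#'   `normalize = FALSE`).
#' @export
#'
#' @examples
#' lzc(c(0,0,0,1,1,0,1,0,0,1,0,0,0,1,0,1), normalize = FALSE)  # 6
#' lzc(rep(0, 10), normalize = FALSE)                          # 2
lzc <- function(bits, normalize = TRUE, scheme = c("lz76", "lz78")) {
  scheme <- match.arg(scheme)
  stopifnot(length(bits) >= 1, all(bits %in% c(0, 1)))
  b <- as.integer(bits)
  n <- length(b)
  c_n <- if (scheme == "lz76") lz76_count(b) else .lz78_count(b)
  if (!normalize) return(c_n)
  if (n < 2) return(c_n)  # log2(1) = 0: normalization undefined, return count
  c_n * log2(n) / n
}

# LZ78 dictionary parse: phrases are (longest known phrase) + next symbol.
.lz78_count <- function(b) {
  dict <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  cur <- ""
  for (s in b) {
    cur <- paste0(cur, s)
    if (!exists(cur, envir = dict, inherits = FALSE)) {
      assign(cur, TRUE, envir = dict)
      count <- count + 1L
      cur <- ""
    }
  }
  if (nzchar(cur)) count <- count + 1L  # trailing incomplete phrase
  count
}
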