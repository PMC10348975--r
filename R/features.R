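#' Extract the seven consciousness-related features per sliding window
#'
#' For every 3-s window (1-s hop by default) computes, per channel and then
#' averaged across channels: theta (4-8 Hz) and beta (12-30 Hz) relative
#' power, normalized SEF95, Poincare ellipsoid radius ratio, normalized
#' Lempel-Ziv complexity of the Hilbert-binarized signal; and, averaged over
#' all unordered channel pairs: theta-band imaginary coherency and
#' theta-tuned weighted symbolic mutual information (`k = 3`, lag 16 ms).
#' The recording is assumed already band-pass filtered (0.5-45 Hz); wSMI is
#' computed on that broadband signal, its theta selectivity coming from the
#' lag alone.
#'
#' @param rec An [eeg_recording()] (typically output of [bandpass_filter()]).
#' @param window_s,hop_s Segmentation grid in seconds (defaults 3 and 1).
#' @param theta,beta Band limits in Hz for the relative powers.
#' @param f_total Upper limit of the total-power range for relative power and
#'   SEF normalization (default 45 Hz, the filter cut-off).
#' @param wsmi_tau_s wSMI element separation in seconds (default 0.016).
#'
#' @return A tibble with one row per window: `window`, `start_time_s`, and
#'   feature columns `theta_rp`, `beta_rp`, `sef95`, `err`, `lzc`,
#'   `icoh_theta`, `wsmi_theta`. Degenerate windows yield `NaN` features.
#' @export
#'
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 3000), nrow = 4), fs = 250)
#' feats <- extract_features(bandpass_filter(rec))
extract_features <- function(rec, window_s = 3, hop_s = 1,
                             theta = c(4, 8), beta = c(12, 30),
                             f_total = 45, wsmi_tau_s = 0.016) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  wins <- segment_windows(rec, window_s, hop_s)
  nch <- nrow(rec$data)
  pairs <- if (nch >= 2) utils::combn(nch, 2) else NULL
  tau <- .wsmi_tau_samples(fs, wsmi_tau_s)
  win_len <- round(window_s * fs)
  plan <- .welch_plan(win_len, fs)
  theta_bins <- plan$freqs >= theta[1] & plan$freqs <= theta[2]
  if (!any(theta_bins)) stop("no Welch bin falls in the theta band")

  one_window <- function(i) {
    idx <- (wins$start_sample[i] + 1):wins$end_sample[i]
    seg <- rec$data[, idx, drop = FALSE]
    ffts <- vector("list", nch)
    autos <- matrix(NA_real_, plan$nfreq, nch)
    syms <- vector("list", nch)
    th_rp <- bt_rp <- s95 <- err <- lz <- numeric(nch)
    for (ch in seq_len(nch)) {
      x <- seg[ch, ]
      f <- .welch_fft(x, plan)
      ffts[[ch]] <- f
      auto <- .welch_auto(f, plan)
      autos[, ch] <- rowMeans(Re(f * Conj(f)))  # unscaled, for coherency
      psd <- tibble::tibble(freq = plan$freqs, power = pmax(auto, 0))
      total <- sum(psd$power[psd$freq <= f_total])
      if (total <= 0) {
        th_rp[ch] <- bt_rp[ch] <- s95[ch] <- NaN
      } else {
        th_rp[ch] <- sum(psd$power[psd$freq >= theta[1] & psd$freq <= theta[2]]) / total
        bt_rp[ch] <- sum(psd$power[psd$freq >= beta[1] & psd$freq <= beta[2]]) / total
        s95[ch] <- psd$freq[which(cumsum(psd$power) >= 0.95 * sum(psd$power))[1]] / f_total
      }
      err[ch] <- suppressWarnings(poincare_err(x))
      lz[ch] <- lzc(hilbert_binarize(x))
      syms[[ch]] <- symbolize(x, tau_samples = tau)
    }
    ic <- ws <- NaN
    if (!is.null(pairs)) {
      icv <- wsv <- numeric(ncol(pairs))
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1, p]; b <- pairs[2, p]
        denom <- sqrt(autos[theta_bins, a] * autos[theta_bins, b])
        icv[p] <- if (any(denom <= 0)) NaN else {
          sxy <- .welch_cross(ffts[[a]], ffts[[b]])
          mean(abs(Im(sxy[theta_bins] / denom)))
        }
        wsv[p] <- wsmi_pair(syms[[a]], syms[[b]])
      }
      ic <- suppressWarnings(aggregate_pairs(icv))
      ws <- suppressWarnings(aggregate_pairs(wsv))
    }
    c(mean(th_rp), mean(bt_rp), mean(s95), mean(err), mean(lz), ic, ws)
  }

  vals <- vapply(seq_len(nrow(wins)), one_window, numeric(7))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(t(vals)), .feature_names))
  dplyr::bind_cols(wins[, c("window", "start_time_s")], out)
}
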