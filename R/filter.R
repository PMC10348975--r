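#' Band-pass filter a recording
#'
#' Per-channel Butterworth band-pass, by default third order from 0.5 to
#' 45 Hz, the front end of the analysis pipeline. The filter is applied
#' zero-phase (forward-backward) by default so that features stay aligned in
#' time with external scoring; a causal single-pass mode is available. No
#' artifact rejection is performed.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz (defaults 0.5 and 45). `high` must be
#'   below the Nyquist frequency.
#' @param order Butterworth order (default 3).
#' @param zero_phase Apply forward-backward (`TRUE`, default) or causal
#'   single-pass filtering.
#'
#' @return A filtered [eeg_recording()] of the same shape.
#' @export
#'
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), nrow = 1), fs = 200)
#' filtered <- bandpass_filter(rec)
bandpass_filter <- function(rec, low = 0.5, high = 45, order = 3,
                            zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (high >= nyq) stop("`high` must be below the Nyquist frequency (fs/2)")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (ncol(rec$data) <= 3 * order) stop("signal too short to filter")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt1 <- function(x) {
    if (zero_phase) signal::filtfilt(bf$b, bf$a, x)
    else as.numeric(signal::filter(bf$b, bf$a, x))
  }
  out <- t(apply(rec$data, 1, filt1))
  eeg_recording(out, rec$fs, rec$channel_labels, rec$start_time)
}
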