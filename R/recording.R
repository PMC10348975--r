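#' Construct an EEG recording object
#'
#' Light-weight carrier for a multichannel EEG recording: a channels-by-samples
#' amplitude matrix (microvolts) with its sampling rate and channel labels.
#'
#' @param data Numeric matrix, channels x samples. A plain vector is treated as
#'   a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel names (10-20-system
#'   names for clinical data); defaults to `"ch1"`, `"ch2"`, ...
#' @param start_time Optional start timestamp (`POSIXct` or numeric seconds).
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs`, `channel_labels`, `start_time`.
#' @export
#'
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1000), nrow = 2), fs = 100)
#' rec
eeg_recording <- function(data, fs, channel_labels = NULL, start_time = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length must equal the number of channels (rows)")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

#' Restrict a recording to a set of channels
#'
#' Returns the recording restricted to the requested channels, in the order
#' requested. Used to keep only the channels common to all recording montages.
#'
#' @param rec An [eeg_recording()].
#' @param wanted Character vector of channel labels; must all be present.
#' @return An [eeg_recording()] with the selected channels.
#' @export
select_channels <- function(rec, wanted) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(wanted, rec$channel_labels)
  if (length(missing) > 0) {
    stop("channel(s) not present in recording: ", paste(missing, collapse = ", "))
  }
  idx <- match(wanted, rec$channel_labels)
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs,
                channel_labels = wanted, start_time = rec$start_time)
}

#' Sliding-window segmentation
#'
#' Cuts a recording into fixed-length windows sliding by a fixed hop
#' (defaults: 3-s windows sliding one second at a time). A trailing partial
#' window is dropped, never padded: every feature is defined on fixed-length
#' segments.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (default 3).
#' @param hop_s Hop between consecutive window starts in seconds (default 1).
#'
#' @return A tibble with one row per window: `window` (1-based index),
#'   `start_sample` (0-based), `end_sample` (half-open), `start_time_s`.
#'   Attributes `window_s`, `hop_s`, `fs` record the segmentation grid.
#' @export
#'
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 5000), nrow = 2), fs = 500)
#' segment_windows(rec)  # 8 windows: floor((10 - 3)/1) + 1
segment_windows <- function(rec, window_s = 3, hop_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0, hop_s > 0)
  n <- ncol(rec$data)
  win <- round(window_s * rec$fs)
  hop <- round(hop_s * rec$fs)
  if (n < win) stop("recording shorter than one window")
  n_windows <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_windows) - 1L) * hop
  out <- tibble::tibble(
    window = seq_len(n_windows),
    start_sample = starts,
    end_sample = starts + win,
    start_time_s = starts / rec$fs
  )
  attr(out, "window_s") <- window_s
  attr(out, "hop_s") <- hop_s
  attr(out, "fs") <- rec$fs
  out
}
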