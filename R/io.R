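# Plain-text I/O. Recordings travel as CSV matrices (rows = samples,
# columns = channels, header = channel labels); the sampling rate is not
# stored in the file and must be supplied on read.

#' Write / read an EEG recording as a CSV matrix
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns an [eeg_recording()].
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- tibble::as_tibble(t(rec$data))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs Sampling rate in Hz of the stored recording.
#' @export
read_recording_csv <- function(path, fs) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  eeg_recording(t(as.matrix(df)), fs, channel_labels = names(df))
}

#' Write / read eyes scoring as CSV
#'
#' Columns: `epoch_start_s`, `epoch_end_s`, `label` (`O`, `C`, `O/C`, or
#' empty for unavailable scoring).
#'
#' @param eyes Eyes-scoring tibble.
#' @param path File path.
#' @export
write_eyes_csv <- function(eyes, path) {
  readr::write_csv(eyes, path, na = "")
  invisible(path)
}

#' @rdname write_eyes_csv
#' @export
read_eyes_csv <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    epoch_start_s = readr::col_double(),
                    epoch_end_s = readr::col_double(),
                    label = readr::col_character()))
}

#' Write the consciousness trace as CSV
#'
#' Columns: `window`, `time_s`, `p_fcm`, `p_gmm`, `p_conscious`.
#'
#' @param trace Trace tibble (e.g. `fit$trace`).
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' Write a model report as JSON
#'
#' Summarizes a fit: per-method centroids, conscious-cluster indices,
#' iteration counts, final objectives, and GMM mixing proportions.
#'
#' @param fit A `consciousness_fit`.
#' @param path File path.
#' @export
write_report_json <- function(fit, path) {
  stopifnot(inherits(fit, "consciousness_fit"))
  rep1 <- function(cl) {
    list(centroids = unname(apply(cl$centroids, 1, as.list)),
         feature_names = cl$feature_names,
         conscious_index = cl$conscious_index,
         iterations = length(cl$objective),
         final_objective = cl$objective[length(cl$objective)],
         proportions = if (!is.null(cl$proportions)) cl$proportions)
  }
  jsonlite::write_json(
    list(fcm = rep1(fit$fcm), gmm = rep1(fit$gmm),
         n_windows = nrow(fit$trace), n_clustered = length(fit$rows_used)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
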