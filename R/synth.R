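# Synthetic EEG generator: multichannel recordings driven by a known
# conscious/unconscious state schedule, emulating the statistical structure
# the estimation method assumes, so the full pipeline can be exercised
# without restricted clinical data. Conscious segments have elevated theta
# and beta relative power, SEF95 above the alpha band, a larger broadband
# (random) component, and stronger theta-band inter-channel coupling.

#' Parameters for the synthetic EEG generator
#'
#' Each state is a sum of unit-variance band-limited noise components
#' (delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30 Hz) weighted per state,
#' plus a broadband (0.5-45 Hz) noise component, plus a shared theta-band
#' source added to every channel with a channel-specific sample delay
#' (1-10 samples) and weighted by the coupling strength. The delays give the
#' shared component a nonzero imaginary coherency (pure zero-lag sharing
#' would look like volume conduction and carry none). Default state
#' parameters realize the conscious-state hypotheses with clear separation:
#' conscious states have higher theta and beta weight, more broadband noise,
#' SEF95 above the alpha band, and stronger theta coupling.
#'
#' @param n_channels Number of channels (default 6).
#' @param fs Sampling rate in Hz (default 500); must exceed 90 Hz so the
#'   45 Hz analysis band is representable.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param conscious,unconscious Per-state parameter lists with elements
#'   `band_weights` (named delta/theta/alpha/beta amplitude weights, >= 0),
#'   `broadband` (amplitude weight of the broadband component, in \[0, 1\]),
#'   `coupling` (theta-coupling strength, in \[0, 1\]).
#' @param eyes_epoch_s Eyes-scoring epoch length in seconds (default 300,
#'   i.e. 5-min epochs).
#' @param eyes_noise_rate Fraction of eyes epochs replaced by `NA` (default 0).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 6, fs = 500, seed = 1,
                         conscious = list(
                           band_weights = c(delta = 0.5, theta = 0.8,
                                            alpha = 0.4, beta = 0.6),
                           broadband = 0.4, coupling = 0.6),
                         unconscious = list(
                           band_weights = c(delta = 1.0, theta = 0.3,
                                            alpha = 0.5, beta = 0.15),
                           broadband = 0.1, coupling = 0.1),
                         eyes_epoch_s = 300, eyes_noise_rate = 0) {
  if (fs <= 2 * 45) stop("fs must exceed 90 Hz (2 x 45 Hz analysis band)")
  for (st in list(conscious, unconscious)) {
    stopifnot(all(st$band_weights >= 0),
              st$broadband >= 0, st$broadband <= 1,
              st$coupling >= 0, st$coupling <= 1)
  }
  structure(
    list(n_channels = n_channels, fs = fs, seed = seed,
         conscious = conscious, unconscious = unconscious,
         eyes_epoch_s = eyes_epoch_s, eyes_noise_rate = eyes_noise_rate),
    class = "synth_config"
  )
}

.check_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("duration_s", "state") %in% names(schedule)))
  if (nrow(schedule) == 0 || any(schedule$duration_s <= 0)) {
    stop("schedule must have at least one entry with positive duration")
  }
  if (!all(schedule$state %in% c("conscious", "unconscious"))) {
    stop("schedule states must be 'conscious' or 'unconscious'")
  }
  invisible(schedule)
}

# Unit-variance band-limited Gaussian noise by FFT shaping: white noise with
# all frequency bins outside [f1, f2] zeroed. Exact band limits, no filter
# transients.
.band_noise <- function(n, fs, f1, f2) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # fold to two-sided magnitude frequency
  f[freqs < f1 | freqs > f2] <- 0
  y <- Re(stats::fft(f, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band noise (band too narrow for n)")
  y / s
}

#' Generate a synthetic multichannel EEG recording
#'
#' Produces `total_duration * fs` samples per channel following the state
#' schedule, with instantaneous state transitions (crisp ground truth), and
#' the per-sample true state labels.
#'
#' @param schedule Data frame with columns `duration_s` (> 0, seconds) and
#'   `state` (`"conscious"` / `"unconscious"`), in temporal order.
#' @param config A [synth_config()].
#'
#' @return A list with `recording` (an [eeg_recording()]) and `labels`
#'   (tibble: `time_s`, `state` per sample).
#' @export
#'
#' @examples
#' sched <- tibble::tibble(duration_s = c(30, 30),
#'                         state = c("conscious", "unconscious"))
#' out <- generate_recording(sched, synth_config(n_channels = 4, fs = 200))
#' out$recording
generate_recording <- function(schedule, config) {
  .check_schedule(schedule)
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  per_run <- round(schedule$duration_s * fs)
  n <- sum(per_run)
  state <- rep(schedule$state, times = per_run)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 12), beta = c(12, 30))
  # per-sample weights for each component
  wt <- function(field, band = NULL) {
    pick <- function(st) {
      prm <- config[[st]]
      if (is.null(band)) prm[[field]] else prm$band_weights[[band]]
    }
    ifelse(state == "conscious", pick("conscious"), pick("unconscious"))
  }
  data <- withr::with_seed(config$seed, {
    shared_theta <- .band_noise(n, fs, 4, 8)
    delays <- if (config$n_channels <= 10) {
      sample(1:10, config$n_channels)
    } else {
      sample(1:10, config$n_channels, replace = TRUE)
    }
    coup <- wt("coupling")
    mat <- matrix(NA_real_, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      sig <- numeric(n)
      for (b in names(bands)) {
        sig <- sig + wt("band_weights", b) * .band_noise(n, fs, bands[[b]][1], bands[[b]][2])
      }
      sig <- sig + wt("broadband") * .band_noise(n, fs, 0.5, 45)
      # circularly delayed shared theta source: nonzero-lag coupling
      d <- delays[ch]
      sig <- sig + coup * shared_theta[((seq_len(n) - 1 - d) %% n) + 1]
      mat[ch, ] <- sig
    }
    mat
  })
  rec <- eeg_recording(data, fs,
                       channel_labels = paste0("ch", seq_len(config$n_channels)))
  labels <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, state = state)
  list(recording = rec, labels = labels)
}

#' Generate eyes scoring aligned with a state schedule
#'
#' Tiles the recording into scoring epochs (default 5 min) and labels each
#' `O` (eyes open) when it is majority-conscious, `C` (eyes closed) when
#' majority-unconscious, and `O/C` when exactly mixed. A seeded fraction
#' `eyes_noise_rate` of epochs is replaced by `NA` (scoring unavailable).
#'
#' @inheritParams generate_recording
#' @return A tibble with `epoch_start_s`, `epoch_end_s`, `label`.
#' @export
#'
#' @examples
#' sched <- tibble::tibble(duration_s = c(600, 600),
#'                         state = c("conscious", "unconscious"))
#' generate_eyes_scoring(sched, synth_config())  # O, O, C, C
generate_eyes_scoring <- function(schedule, config) {
  .check_schedule(schedule)
  stopifnot(inherits(config, "synth_config"))
  total <- sum(schedule$duration_s)
  ep <- config$eyes_epoch_s
  n_epochs <- ceiling(total / ep - 1e-9)
  starts <- (seq_len(n_epochs) - 1) * ep
  ends <- pmin(starts + ep, total)
  # conscious-time overlap of [s, e) with the schedule's conscious runs
  run_end <- cumsum(schedule$duration_s)
  run_start <- run_end - schedule$duration_s
  conscious_overlap <- function(s, e) {
    sum(pmax(0, pmin(e, run_end[schedule$state == "conscious"]) -
               pmax(s, run_start[schedule$state == "conscious"])))
  }
  frac <- mapply(conscious_overlap, starts, ends) / (ends - starts)
  label <- ifelse(frac > 0.5, "O", ifelse(frac < 0.5, "C", "O/C"))
  if (config$eyes_noise_rate > 0) {
    label <- withr::with_seed(config$seed + 1L, {
      drop <- stats::runif(length(label)) < config$eyes_noise_rate
      replace(label, drop, NA_character_)
    })
  }
  tibble::tibble(epoch_start_s = starts, epoch_end_s = ends, label = label)
}
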