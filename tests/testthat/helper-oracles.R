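# Independent oracles and small fixtures, deliberately implemented without
# reusing the package's own code paths.

# Brute-force LZ76 exhaustive parsing: each phrase is the shortest prefix of
# the remainder that is not a substring of everything before its last
# character (string search, no pointer tricks).
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  count <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    while (l + k - 1L <= n) {
      w <- substr(s, l, l + k - 1L)
      prefix <- substr(s, 1L, l + k - 2L)
      if (grepl(w, prefix, fixed = TRUE)) k <- k + 1L else break
    }
    count <- count + 1L
    l <- l + k
  }
  count
}

# Plain fixed-point FCM iteration (m = 2), no restarts, no vectorized
# shortcuts: the textbook update equations written out directly.
fcm_oracle <- function(x, u0, m = 2, iters = 500) {
  x <- as.matrix(x)
  u <- u0
  for (it in seq_len(iters)) {
    um <- u^m
    centers <- matrix(NA_real_, ncol(u), ncol(x))
    for (j in seq_len(ncol(u))) {
      centers[j, ] <- colSums(um[, j] * x) / sum(um[, j])
    }
    for (i in seq_len(nrow(x))) {
      d <- sqrt(colSums((t(centers) - x[i, ])^2))
      if (any(d == 0)) {
        u[i, ] <- as.numeric(d == 0) / sum(d == 0)
      } else {
        for (j in seq_len(ncol(u))) {
          u[i, j] <- 1 / sum((d[j] / d)^(2 / (m - 1)))
        }
      }
    }
  }
  list(memberships = u, centroids = centers)
}

# Poincare SD1/SD2 measured geometrically on the plotted pairs:
# project (x_t, x_{t+tau}) onto the axes rotated 45 degrees.
poincare_oracle <- function(x, tau = 1) {
  n <- length(x)
  p1 <- x[seq_len(n - tau)]
  p2 <- x[(tau + 1):n]
  sd1 <- sd((p1 - p2) / sqrt(2))
  sd2 <- sd((p1 + p2) / sqrt(2))
  sd1 / sd2
}

# Direct periodogram (no Welch averaging) for peak-location checks.
periodogram_peak <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs <= fs / 2
  freqs[keep][which.max(p[keep])]
}

# Tiny synthetic recording for structural tests (fast: low fs, short).
tiny_recording <- function(seed = 1, fs = 200, dur = c(30, 30), n_channels = 4) {
  sched <- tibble::tibble(duration_s = dur,
                          state = c("conscious", "unconscious")[seq_along(dur) %% 2 + 1])
  sched$state <- rep(c("conscious", "unconscious"), length.out = nrow(sched))
  cfg <- synth_config(n_channels = n_channels, fs = fs, seed = seed)
  list(schedule = sched, config = cfg,
       out = generate_recording(sched, cfg))
}
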