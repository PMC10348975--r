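test_that("generated recordings have the scheduled length and are seed-reproducible", {
  sched <- tibble::tibble(duration_s = c(600, 600),
                          state = c("conscious", "unconscious"))
  cfg <- synth_config(n_channels = 6, fs = 500, seed = 1)
  # length check only needs the schedule arithmetic, use a cheap config too
  small <- synth_config(n_channels = 2, fs = 100, seed = 1)
  out <- generate_recording(sched, small)
  expect_equal(ncol(out$recording$data), 600 * 100 * 2)
  expect_equal(nrow(out$recording$data), 2)
  expect_equal(nrow(out$labels), 120000)

  sched2 <- tibble::tibble(duration_s = c(20, 20),
                           state = c("conscious", "unconscious"))
  a <- generate_recording(sched2, cfg)
  b <- generate_recording(sched2, cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$labels, b$labels)
  c <- generate_recording(sched2, synth_config(n_channels = 6, fs = 500, seed = 2))
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("generator rejects invalid schedules and too-low sampling rates", {
  cfg <- synth_config(fs = 200)
  expect_error(generate_recording(tibble::tibble(duration_s = numeric(0),
                                                 state = character(0)), cfg),
               "positive duration")
  expect_error(generate_recording(tibble::tibble(duration_s = 0, state = "conscious"),
                                  cfg), "positive duration")
  expect_error(synth_config(fs = 80), "90 Hz")
  expect_error(generate_recording(tibble::tibble(duration_s = 10, state = "awake"),
                                  cfg), "conscious")
})

test_that("conscious halves show higher theta relative power than unconscious halves", {
  tr <- tiny_recording(seed = 3, fs = 200, dur = c(30, 30))
  fe <- extract_features(bandpass_filter(tr$out$recording))
  cons <- fe$start_time_s + 3 <= 30
  unc <- fe$start_time_s >= 30
  expect_gt(mean(fe$theta_rp[cons]), mean(fe$theta_rp[unc]))
  expect_gt(mean(fe$beta_rp[cons]), mean(fe$beta_rp[unc]))
  expect_gt(mean(fe$sef95[cons]), mean(fe$sef95[unc]))
  expect_gt(mean(fe$lzc[cons]), mean(fe$lzc[unc]))
  expect_gt(mean(fe$err[cons]), mean(fe$err[unc]))
})

test_that("wSMI and iCOH increase with theta-coupling strength (expectation over seeds)", {
  sched <- tibble::tibble(duration_s = 40, state = "conscious")
  mean_conn <- function(coupling) {
    ws <- ic <- numeric(0)
    for (sd in 1:3) {
      cfg <- synth_config(n_channels = 4, fs = 500, seed = sd,
                          conscious = list(
                            band_weights = c(delta = 0.5, theta = 0.8,
                                             alpha = 0.4, beta = 0.6),
                            broadband = 0.4, coupling = coupling))
      fe <- extract_features(bandpass_filter(
        generate_recording(sched, cfg)$recording))
      ws <- c(ws, mean(fe$wsmi_theta))
      ic <- c(ic, mean(fe$icoh_theta))
    }
    c(wsmi = mean(ws), icoh = mean(ic))
  }
  lo <- mean_conn(0.1)
  hi <- mean_conn(1.0)
  expect_gt(hi["wsmi"], lo["wsmi"])
  expect_gt(hi["icoh"], lo["icoh"])
})

test_that("eyes scoring follows the majority rule, mixed rule, and noise contract", {
  sched <- tibble::tibble(duration_s = c(600, 600),
                          state = c("conscious", "unconscious"))
  cfg <- synth_config(fs = 100, eyes_epoch_s = 300, eyes_noise_rate = 0)
  eyes <- generate_eyes_scoring(sched, cfg)
  expect_equal(eyes$label, c("O", "O", "C", "C"))
  expect_equal(eyes$epoch_start_s, c(0, 300, 600, 900))
  expect_equal(eyes$epoch_end_s, c(300, 600, 900, 1200))

  # epoch straddling a state change 50/50 -> O/C; majority epochs keep O/C out
  sched2 <- tibble::tibble(duration_s = c(150, 450),
                           state = c("conscious", "unconscious"))
  eyes2 <- generate_eyes_scoring(sched2, cfg)
  expect_equal(eyes2$label, c("O/C", "C"))
  sched3 <- tibble::tibble(duration_s = c(200, 400),
                           state = c("conscious", "unconscious"))
  expect_equal(generate_eyes_scoring(sched3, cfg)$label, c("O", "C"))

  # full noise -> all NA; reproducible under the seed
  cfg_na <- synth_config(fs = 100, eyes_epoch_s = 300, eyes_noise_rate = 1)
  eyes_na <- generate_eyes_scoring(sched, cfg_na)
  expect_true(all(is.na(eyes_na$label)))
  expect_identical(generate_eyes_scoring(sched, cfg_na), eyes_na)
})

test_that("eyes epochs tile the recording including a trailing partial epoch", {
  sched <- tibble::tibble(duration_s = c(500, 250),
                          state = c("conscious", "unconscious"))
  eyes <- generate_eyes_scoring(sched, synth_config(fs = 100, eyes_epoch_s = 300))
  expect_equal(eyes$epoch_start_s, c(0, 300, 600))
  expect_equal(eyes$epoch_end_s, c(300, 600, 750))
  # epoch 2: 300-500 conscious (200 s) vs 500-600 unconscious -> majority O
  expect_equal(eyes$label, c("O", "O", "C"))
})
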