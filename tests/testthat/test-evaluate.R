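# A small fitted object built from synthetic features, reused across tests.
fit_fixture <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      set.seed(61)
      fm <- tibble::tibble(
        window = 1:60, start_time_s = seq(0, 590, by = 10),
        theta_rp = c(rnorm(30, 0.2, 0.03), rnorm(30, 0.6, 0.03)),
        beta_rp = c(rnorm(30, 0.1, 0.02), rnorm(30, 0.4, 0.02)),
        sef95 = c(rnorm(30, 0.3, 0.03), rnorm(30, 0.7, 0.03)),
        err = c(rnorm(30, 0.2, 0.03), rnorm(30, 0.8, 0.03)),
        lzc = c(rnorm(30, 0.3, 0.03), rnorm(30, 0.9, 0.03)),
        icoh_theta = c(rnorm(30, 0.1, 0.02), rnorm(30, 0.3, 0.02)),
        wsmi_theta = c(rnorm(30, 0.05, 0.01), rnorm(30, 0.2, 0.02))
      )
      value <<- estimate_consciousness(fm, seed = 3)
    }
    value
  }
})

test_that("Spearman contributions hit the monotone and null limits", {
  fit <- fit_fixture()
  contrib <- spearman_contributions(fit)
  expect_setequal(unique(contrib$method), c("fcm", "gmm", "ensemble"))
  expect_true(all(abs(contrib$rho) <= 1, na.rm = TRUE))

  # feature equal to the trace -> rho = 1; its negation -> rho = -1
  tr <- fit$trace$p_conscious
  fit2 <- fit
  fit2$features$theta_rp <- tr
  fit2$features$beta_rp <- -tr
  contrib2 <- spearman_contributions(fit2)
  expect_equal(contrib2$rho[contrib2$feature == "theta_rp" &
                              contrib2$method == "ensemble"], 1)
  expect_equal(contrib2$rho[contrib2$feature == "beta_rp" &
                              contrib2$method == "ensemble"], -1)

  # independent noise vs trace: |rho| small at n = 1000
  set.seed(62)
  y <- runif(1000)
  x <- rnorm(1000)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_lt(abs(unname(ct$estimate)), 0.1)

  # constant trace -> NaN + not significant
  fit3 <- fit
  fit3$trace$p_fcm <- rep(0.5, nrow(fit3$trace))
  contrib3 <- spearman_contributions(fit3)
  expect_true(all(is.nan(contrib3$rho[contrib3$method == "fcm"])))
})

test_that("inter-cluster distance is Euclidean and monotone in coordinates", {
  expect_equal(intercluster_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(intercluster_distance(rep(1, 7), rep(1, 7)), 0)
  set.seed(63)
  c1 <- runif(7)
  c2 <- runif(7)
  expect_lte(intercluster_distance(c1, c2, dims = c(2, 5)),
             intercluster_distance(c1, c2))
})

test_that("accuracy sweep follows the confusion arithmetic and exclusion rules", {
  # constructed trace: 6 epochs of 10 s, one sample per second
  trace <- tibble::tibble(time_s = 0:59,
                          p_conscious = rep(c(1, 1, 1, 0, 0, 1), each = 10))
  eyes <- tibble::tibble(epoch_start_s = seq(0, 50, 10),
                         epoch_end_s = seq(10, 60, 10),
                         label = c("O", "O", "O", "C", "C", "C"))
  acc <- accuracy_vs_eyes(trace, eyes, thresholds = 0.5)
  # TP = 3, TN = 2, FP = 1, FN = 0 -> 5/6
  expect_equal(acc$tp, 3)
  expect_equal(acc$tn, 2)
  expect_equal(acc$fp, 1)
  expect_equal(acc$fn, 0)
  expect_equal(acc$accuracy, 5 / 6)
  expect_equal(acc$tp + acc$tn + acc$fp + acc$fn, 6)

  # constant-1 trace, all-O scoring: accuracy 1 at every threshold
  tr1 <- tibble::tibble(time_s = 0:59, p_conscious = 1)
  all_o <- tibble::tibble(epoch_start_s = c(0, 30), epoch_end_s = c(30, 60),
                          label = c("O", "O"))
  acc1 <- accuracy_vs_eyes(tr1, all_o)
  expect_equal(acc1$accuracy, rep(1, 5))

  # O/C and NA epochs are excluded; all-NA errors
  mixed <- tibble::tibble(epoch_start_s = c(0, 20, 40),
                          epoch_end_s = c(20, 40, 60),
                          label = c("O", "O/C", NA))
  accm <- accuracy_vs_eyes(tr1, mixed, thresholds = 0.5)
  expect_equal(accm$tp + accm$tn + accm$fp + accm$fn, 1)
  expect_error(accuracy_vs_eyes(tr1, tibble::tibble(
    epoch_start_s = 0, epoch_end_s = 60, label = NA_character_)), "no evaluable")
})

test_that("flipping all eyes labels maps accuracy to its complement", {
  set.seed(64)
  trace <- tibble::tibble(time_s = 0:99, p_conscious = runif(100))
  eyes <- tibble::tibble(epoch_start_s = seq(0, 90, 10),
                         epoch_end_s = seq(10, 100, 10),
                         label = sample(c("O", "C"), 10, replace = TRUE))
  flipped <- eyes
  flipped$label <- ifelse(eyes$label == "O", "C", "O")
  a <- accuracy_vs_eyes(trace, eyes)
  b <- accuracy_vs_eyes(trace, flipped)
  expect_equal(a$accuracy + b$accuracy, rep(1, 5))
})

test_that("samples at the threshold count as conscious (inclusive rule)", {
  trace <- tibble::tibble(time_s = 0:9, p_conscious = rep(0.5, 10))
  eyes <- tibble::tibble(epoch_start_s = 0, epoch_end_s = 10, label = "O")
  acc <- accuracy_vs_eyes(trace, eyes, thresholds = 0.5)
  expect_equal(acc$accuracy, 1)
})

test_that("evaluate_consciousness bundles contributions, distances, accuracy", {
  fit <- fit_fixture()
  eyes <- tibble::tibble(epoch_start_s = c(0, 300), epoch_end_s = c(300, 600),
                         label = c("C", "O"))
  rpt <- evaluate_consciousness(fit, eyes = eyes)
  expect_s3_class(rpt$contributions, "tbl_df")
  expect_equal(nrow(rpt$contributions), 21)  # 7 features x 3 methods
  # distances: per method, "all" plus the 21 feature pairs
  expect_equal(nrow(rpt$distances), 2 * (1 + choose(7, 2)))
  expect_true(all(rpt$distances$distance >= 0))
  pair_rows <- rpt$distances[rpt$distances$dims != "all", ]
  all_rows <- rpt$distances[rpt$distances$dims == "all", ]
  for (m in c("fcm", "gmm")) {
    expect_true(all(pair_rows$distance[pair_rows$method == m] <=
                      all_rows$distance[all_rows$method == m]))
  }
  expect_equal(nrow(rpt$accuracy), 5)
  # the fixture's two halves separate cleanly: high accuracy at 0.5
  expect_gte(rpt$accuracy$accuracy[rpt$accuracy$threshold == 0.5], 0.9)
})
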