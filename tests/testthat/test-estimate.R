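test_that("min-max normalization maps columns to [0,1] and respects NaN/constant rules", {
  fm <- tibble::tibble(theta_rp = c(2, 4, 6))
  expect_equal(normalize_features(fm)$theta_rp, c(0, 0.5, 1))
  fm01 <- tibble::tibble(beta_rp = c(0, 0.25, 1))
  expect_equal(normalize_features(fm01)$beta_rp, c(0, 0.25, 1))

  with_nan <- tibble::tibble(lzc = c(0, 5, NaN, 10))
  out <- normalize_features(with_nan)
  expect_equal(out$lzc, c(0, 0.5, NaN, 1))

  expect_warning(cst <- normalize_features(tibble::tibble(err = c(3, 3, 3))),
                 "constant")
  expect_equal(cst$err, c(0.5, 0.5, 0.5))
})

test_that("FCM separates two blobs and matches the fixed-point oracle", {
  x <- matrix(c(0, 0.01, 0.02, 1, 1.01, 1.02), ncol = 1)
  fit <- fcm(x, N = 2, seed = 1)
  cen <- sort(fit$centroids[, 1])
  expect_lt(abs(cen[1] - 0.01), 0.05)
  expect_lt(abs(cen[2] - 1.01), 0.05)
  own <- apply(fit$memberships, 1, max)
  expect_true(all(own > 0.95))

  # oracle: plain fixed-point iteration from the same initialization
  set.seed(5)
  u0 <- matrix(runif(12), ncol = 2)
  u0 <- u0 / rowSums(u0)
  fit2 <- fcm(x, N = 2, init = u0, eps = 1e-13, max_iter = 5000)
  orc <- fcm_oracle(x, u0)
  expect_lt(max(abs(sort(fit2$centroids[, 1]) - sort(orc$centroids[, 1]))), 1e-6)

  # independent library cross-check on the centroids
  if (requireNamespace("e1071", quietly = TRUE)) {
    cm <- e1071::cmeans(x, centers = 2, m = 2)
    expect_equal(sort(fit$centroids[, 1]), sort(unname(cm$centers[, 1])),
                 tolerance = 1e-3)
  }
})

test_that("FCM memberships are row-stochastic and the objective never increases", {
  set.seed(51)
  x <- matrix(rnorm(200), ncol = 2)
  fit <- fcm(x, N = 2, seed = 3)
  expect_equal(rowSums(fit$memberships), rep(1, 100), tolerance = 1e-12)
  expect_true(all(diff(fit$objective) <= 1e-9))

  # a data point exactly at a centroid gets membership exactly 1: start from
  # an assignment whose first centroid coincides with the first point
  x2 <- matrix(c(0, 1, 1.02), ncol = 1)
  u0 <- rbind(c(1, 0), c(0, 1), c(0, 1))
  fit2 <- fcm(x2, N = 2, init = u0)
  expect_equal(unname(fit2$memberships[1, ]), c(1, 0))
})

test_that("FCM approaches the hard nearest-centroid partition as m -> 1", {
  set.seed(52)
  x <- rbind(matrix(rnorm(100, 0, 0.3), ncol = 2),
             matrix(rnorm(100, 4, 0.3), ncol = 2))
  fit <- fcm(x, N = 2, m = 1.05, seed = 2)
  km <- kmeans(x, centers = fit$centroids)
  hard <- apply(fit$memberships, 1, which.max)
  # same partition up to label swap, and memberships nearly 0/1
  agree <- mean(hard == km$cluster)
  expect_true(agree > 0.98 || agree < 0.02)
  expect_gt(mean(apply(fit$memberships, 1, max)), 0.99)
})

test_that("GMM-EM recovers simulated mixture parameters", {
  set.seed(53)
  x <- matrix(c(rnorm(500, 0, 1), rnorm(500, 5, 1)), ncol = 1)
  fit <- gmm_em(x, K = 2, seed = 1)
  mu <- sort(fit$centroids[, 1])
  expect_lt(abs(mu[1] - 0), 0.2)
  expect_lt(abs(mu[2] - 5), 0.2)
  expect_lt(max(abs(fit$proportions - 0.5)), 0.05)
  expect_equal(rowSums(fit$memberships), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(diff(fit$objective) >= -1e-8))  # EM monotone likelihood

  # independent library cross-check on the recovered means
  if (requireNamespace("mclust", quietly = TRUE)) {
    withr::local_package("mclust")
    mc <- mclust::Mclust(x[, 1], G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(mu, sort(as.numeric(mc$parameters$mean)), tolerance = 0.05)
  }
})

test_that("GMM degenerate cases: K = 1 and coincident-looking data", {
  set.seed(54)
  x <- matrix(rnorm(50), ncol = 1)
  fit <- gmm_em(x, K = 1, seed = 1)
  expect_equal(fit$memberships[, 1], rep(1, 50))
  expect_equal(fit$centroids[1, 1], mean(x), tolerance = 1e-8)
  expect_error(gmm_em(matrix(rep(1, 10), ncol = 1), K = 2), "distinct")
  expect_error(fcm(matrix(rep(1, 10), ncol = 1), N = 2), "distinct")
})

test_that("conscious-cluster labeling uses majority, then SEF95, then centroid mean", {
  mk <- function(c1, c2, names = NULL) {
    structure(list(centroids = rbind(c1, c2), method = "fcm",
                   feature_names = names), class = "cluster_result")
  }
  fn <- c("theta_rp", "beta_rp", "sef95", "err", "lzc", "icoh_theta", "wsmi_theta")
  expect_equal(label_conscious_cluster(mk(rep(0.8, 7), rep(0.2, 7), fn)), 1L)
  expect_equal(label_conscious_cluster(mk(rep(0.2, 7), rep(0.8, 7), fn)), 2L)

  # 4 vs 3 coordinate majority
  a <- c(0.9, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1)
  b <- c(0.1, 0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  expect_equal(label_conscious_cluster(mk(a, b, fn)), 1L)

  # 3-3 split with one equal coordinate: higher SEF95 wins
  a2 <- c(0.9, 0.9, 0.9, 0.5, 0.1, 0.1, 0.1)
  b2 <- c(0.1, 0.1, 0.2, 0.5, 0.9, 0.9, 0.9)
  expect_equal(label_conscious_cluster(mk(a2, b2, fn)), 1L)
  b3 <- c(0.1, 0.1, 0.95, 0.5, 0.9, 0.9, 0.9)
  expect_equal(label_conscious_cluster(mk(a2, b3, fn)), 2L)
})

test_that("ensemble average is the plain two-trace mean", {
  expect_equal(ensemble_average(0.2, 0.8), 0.5)
  expect_equal(ensemble_average(1, 1), 1)
  p <- runif(10)
  expect_equal(ensemble_average(p, p), p)
  expect_error(ensemble_average(1:3 / 3, 1:4 / 4), "equal length")
})

test_that("estimate_consciousness produces a [0,1] trace and excludes NaN windows", {
  set.seed(55)
  fm <- tibble::tibble(
    window = 1:40, start_time_s = 0:39,
    theta_rp = c(rnorm(20, 0.2, 0.02), rnorm(20, 0.6, 0.02)),
    beta_rp = c(rnorm(20, 0.1, 0.02), rnorm(20, 0.4, 0.02)),
    sef95 = c(rnorm(20, 0.3, 0.02), rnorm(20, 0.7, 0.02)),
    err = c(rnorm(20, 0.2, 0.02), rnorm(20, 0.8, 0.02)),
    lzc = c(rnorm(20, 0.3, 0.02), rnorm(20, 0.9, 0.02)),
    icoh_theta = c(rnorm(20, 0.1, 0.02), rnorm(20, 0.3, 0.02)),
    wsmi_theta = c(rnorm(20, 0.05, 0.01), rnorm(20, 0.2, 0.02))
  )
  fm$lzc[7] <- NaN
  fit <- suppressMessages(estimate_consciousness(fm, seed = 2))
  tr <- tidy(fit)
  expect_true(is.na(tr$p_conscious[7]))
  ok <- !is.na(tr$p_conscious)
  expect_true(all(tr$p_conscious[ok] >= 0 & tr$p_conscious[ok] <= 1))
  # second half was built uniformly higher -> higher estimated consciousness
  expect_gt(mean(tr$p_conscious[21:40]), mean(tr$p_conscious[ok & tr$window <= 20]))
  g <- glance(fit)
  expect_equal(g$n_clustered, 39)
  expect_equal(g$n_windows, 40)
})
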