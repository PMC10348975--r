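# Soft clustering of the feature matrix into conscious / unconscious clusters
# and the ensemble-averaged consciousness trace.

#' Min-max normalize feature columns to \[0, 1\]
#'
#' Each feature column is scaled to span \[0, 1\] over the recording's finite
#' rows. Rows with non-finite entries are ignored by the min/max and left as
#' they are (they are excluded from clustering later). A constant column
#' carries no contrast and is set to 0.5 with a warning.
#'
#' @param features A tibble from [extract_features()] (or any data frame with
#'   numeric feature columns plus optional `window` / `start_time_s` columns,
#'   which are passed through).
#' @return The same tibble with feature columns normalized.
#' @export
#'
#' @examples
#' normalize_features(tibble::tibble(theta_rp = c(2, 4, 6)))
normalize_features <- function(features) {
  meta <- intersect(c("window", "start_time_s"), names(features))
  cols <- setdiff(names(features), meta)
  out <- features
  for (cl in cols) {
    v <- out[[cl]]
    fin <- is.finite(v)
    if (sum(fin) < 2) {
      warning("column `", cl, "` has fewer than 2 finite values; set to 0.5")
      v[fin] <- 0.5
    } else {
      rng <- range(v[fin])
      if (diff(rng) == 0) {
        warning("constant feature column `", cl, "` set to 0.5")
        v[fin] <- 0.5
      } else {
        v[fin] <- (v[fin] - rng[1]) / diff(rng)
      }
    }
    out[[cl]] <- v
  }
  out
}

# Squared Euclidean distances between rows of x (n x p) and centroids (N x p).
.sqdist <- function(x, centers) {
  n <- nrow(x)
  d <- matrix(0, n, nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d[, j] <- rowSums(sweep(x, 2, centers[j, ], "-")^2)
  }
  d
}

# One FCM run from a given membership matrix; returns memberships, centroids
# and the objective trace. Alternates the centroid and membership updates
# until the objective improves by less than eps.
.fcm_run <- function(x, u, m, max_iter, eps) {
  obj <- numeric(0)
  j_prev <- Inf
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    d2 <- .sqdist(x, centers)
    zero <- d2 <= .Machine$double.eps
    u_new <- 1 / (d2^(1 / (m - 1)) * rowSums((1 / d2)^(1 / (m - 1))))
    if (any(zero)) {
      # a point coincident with a centroid belongs fully to that cluster
      rows <- which(rowSums(zero) > 0)
      u_new[rows, ] <- 0
      u_new[rows, ] <- zero[rows, , drop = FALSE] / rowSums(zero[rows, , drop = FALSE])
    }
    u <- u_new
    j <- sum(u^m * d2)
    obj <- c(obj, j)
    if (is.finite(j_prev) && abs(j_prev - j) < eps) break
    j_prev <- j
  }
  list(memberships = u, centroids = centers, objective = obj)
}

#' Fuzzy c-means clustering
#'
#' Soft K-means with fuzzifier `m`: memberships are initialized at random
#' (seeded, row-normalized), then centroid and membership updates alternate
#' until the objective `J_m` (fuzzified within-cluster sum of squared
#' distances) improves by less than `eps` or `max_iter` is reached. Defaults
#' follow the study settings: `m = 2`, 1000 iterations, `eps = 1e-5`. The
#' best of `restarts` seeded starts (lowest final `J_m`) is returned. A data
#' point coincident with a centroid receives membership 1 to that cluster.
#'
#' @param data Numeric matrix or data frame of normalized features
#'   (rows = observations). Non-finite rows must be removed beforehand.
#' @param N Number of clusters (default 2: conscious / unconscious).
#' @param m Fuzzifier, > 1 (default 2).
#' @param max_iter Maximum iterations (default 1000).
#' @param eps Minimum absolute improvement of `J_m` between consecutive
#'   iterations (default 1e-5).
#' @param seed Integer seed for the random membership initialization.
#' @param restarts Number of seeded restarts (default 5).
#' @param init Optional n x N membership matrix to start from (deterministic
#'   initialization; overrides `restarts`).
#'
#' @return A `cluster_result` list: `memberships` (n x N, rows sum to 1),
#'   `centroids` (N x p), `objective` (per-iteration `J_m`, nonincreasing),
#'   `method = "fcm"`, `m`, and `feature_names`.
#' @export
#'
#' @examples
#' x <- matrix(c(0, 0.01, 0.02, 1, 1.01, 1.02), ncol = 1)
#' fit <- fcm(x, seed = 1)
#' sort(fit$centroids[, 1])  # near 0.01 and 1.01
fcm <- function(data, N = 2, m = 2, max_iter = 1000, eps = 1e-5, seed = 1,
                restarts = 5, init = NULL) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("`data` must be finite; drop NaN rows first")
  if (m <= 1) stop("fuzzifier `m` must be > 1")
  if (nrow(unique(x)) < N) stop("need at least N distinct data rows")
  runs <- if (is.null(init)) {
    withr::with_seed(seed, lapply(seq_len(restarts), function(r) {
      u0 <- matrix(stats::runif(nrow(x) * N), ncol = N)
      .fcm_run(x, u0 / rowSums(u0), m, max_iter, eps)
    }))
  } else {
    stopifnot(nrow(init) == nrow(x), ncol(init) == N)
    list(.fcm_run(x, init / rowSums(init), m, max_iter, eps))
  }
  best <- runs[[which.min(vapply(runs, function(r) r$objective[length(r$objective)],
                                 numeric(1)))]]
  structure(
    list(memberships = best$memberships, centroids = best$centroids,
         objective = best$objective, method = "fcm", m = m,
         feature_names = colnames(data)),
    class = "cluster_result"
  )
}

# log multivariate normal density with covariance given by its Cholesky factor
.dmvnorm_log <- function(x, mean, chol_sigma) {
  p <- ncol(x)
  z <- forwardsolve(t(chol_sigma), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) - 0.5 * p * log(2 * pi)
}

# k-means++-style seeding of K centers
.kmeanspp <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (K > 1) {
    for (k in 2:K) {
      d2 <- apply(.sqdist(x, centers[seq_len(k - 1), , drop = FALSE]), 1, min)
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- x[sample.int(n, 1, prob = prob), ]
    }
  }
  centers
}

# One EM run from given initial centers.
.gmm_run <- function(x, centers, K, max_iter, tol, ridge) {
  n <- nrow(x); p <- ncol(x)
  resp <- if (K == 1) {
    matrix(1, n, 1)
  } else {
    km <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 10))
    outer(km$cluster, seq_len(K), "==") * 1
  }
  resp <- resp + 1e-10
  resp <- resp / rowSums(resp)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  pi_g <- mu <- sigma <- NULL
  for (it in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    pi_g <- nk / n
    mu <- t(resp) %*% x / nk
    sigma <- vector("list", K)
    logd <- matrix(NA_real_, n, K)
    for (g in seq_len(K)) {
      xc <- sweep(x, 2, mu[g, ], "-")
      s <- crossprod(xc * resp[, g], xc) / nk[g]
      diag(s) <- diag(s) + ridge
      sigma[[g]] <- s
      logd[, g] <- .dmvnorm_log(x, mu[g, ], chol(s))
    }
    # E step (log-sum-exp)
    lw <- sweep(logd, 2, log(pi_g), "+")
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    resp <- exp(lw - lse)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  list(memberships = resp, centroids = mu, proportions = pi_g,
       covariances = sigma, objective = ll_trace,
       converged = length(ll_trace) < max_iter)
}

#' Gaussian mixture model fitted by expectation-maximization
#'
#' Fits a full-covariance `K`-component Gaussian mixture by EM; the E step
#' computes posterior membership probabilities and the M step re-estimates
#' proportions, means and covariances with those posteriors as weights.
#' Posteriors are the soft memberships. Convergence is declared when the
#' log-likelihood improves by less than `tol` (default 1e-5, max 1000
#' iterations, matching the FCM settings). Covariances carry a small diagonal
#' ridge for numerical stability; each of `n_init` seeded k-means++-style
#' starts is run and the best final log-likelihood kept.
#'
#' @param data Numeric matrix or data frame of normalized features.
#' @param K Number of mixture components (default 2).
#' @param max_iter,tol EM stopping rule (defaults 1000 and 1e-5).
#' @param seed Integer seed for the initializations.
#' @param n_init Number of seeded starts (default 5).
#' @param ridge Diagonal ridge added to each covariance (default 1e-6).
#'
#' @return A `cluster_result` list: `memberships` (posteriors, rows sum
#'   to 1), `centroids` (component means), `proportions`, `covariances`,
#'   `objective` (per-iteration log-likelihood, nondecreasing),
#'   `method = "gmm"`.
#' @export
#'
#' @examples
#' x <- matrix(c(rnorm(200), rnorm(200, 5)), ncol = 1)
#' fit <- gmm_em(x, seed = 1)
#' sort(fit$centroids[, 1])  # near 0 and 5
gmm_em <- function(data, K = 2, max_iter = 1000, tol = 1e-5, seed = 1,
                   n_init = 5, ridge = 1e-6) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("`data` must be finite; drop NaN rows first")
  if (nrow(unique(x)) < K) stop("need at least K distinct data rows")
  runs <- withr::with_seed(seed, lapply(seq_len(n_init), function(r) {
    .gmm_run(x, .kmeanspp(x, K), K, max_iter, tol, ridge)
  }))
  best <- runs[[which.max(vapply(runs, function(r) r$objective[length(r$objective)],
                                 numeric(1)))]]
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best iterate")
  }
  structure(
    list(memberships = best$memberships, centroids = best$centroids,
         proportions = best$proportions, covariances = best$covariances,
         objective = best$objective, method = "gmm",
         feature_names = colnames(data)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> method = %s, %d observations, %d cluster(s)\n",
              x$method, nrow(x$memberships), ncol(x$memberships)))
  cat(sprintf("final objective: %.6g after %d iteration(s)\n",
              x$objective[length(x$objective)], length(x$objective)))
  invisible(x)
}

#' Identify the conscious cluster from its centroid
#'
#' Conscious states are hypothesized to show higher values of every feature
#' (theta/beta power, SEF95, complexity, theta connectivity), so the cluster
#' whose centroid is higher in the majority of feature coordinates is labeled
#' conscious. Ties are broken by the higher SEF95 coordinate, then by the
#' higher centroid mean.
#'
#' @param result A `cluster_result` from [fcm()] or [gmm_em()] fitted on
#'   normalized features (2 clusters).
#' @return Integer index (1 or 2) of the conscious cluster.
#' @export
label_conscious_cluster <- function(result) {
  cen <- result$centroids
  stopifnot(nrow(cen) == 2)
  wins1 <- sum(cen[1, ] > cen[2, ])
  wins2 <- sum(cen[2, ] > cen[1, ])
  if (wins1 != wins2) return(if (wins1 > wins2) 1L else 2L)
  sef_col <- if (!is.null(result$feature_names)) {
    match("sef95", result$feature_names)
  } else NA_integer_
  if (!is.na(sef_col) && cen[1, sef_col] != cen[2, sef_col]) {
    return(if (cen[1, sef_col] > cen[2, sef_col]) 1L else 2L)
  }
  if (mean(cen[1, ]) >= mean(cen[2, ])) 1L else 2L
}

#' Ensemble-average two conscious-membership traces
#'
#' Per-sample arithmetic mean of the conscious-cluster membership traces from
#' the two clustering methods; the ensemble output is the estimated
#' consciousness level in \[0, 1\] (0 unconscious, 1 conscious).
#'
#' @param p_fcm,p_gmm Equal-length numeric vectors in \[0, 1\].
#' @return Numeric vector, the per-sample mean.
#' @export
ensemble_average <- function(p_fcm, p_gmm) {
  if (length(p_fcm) != length(p_gmm)) stop("traces must have equal length")
  (p_fcm + p_gmm) / 2
}

#' Estimate the consciousness-level trace from a feature matrix
#'
#' Full estimation stage: min-max normalization, 2-cluster FCM and GMM-EM on
#' the finite rows, per-method conscious-cluster labeling, and the
#' ensemble-averaged trace. Windows with non-finite features get `NA` trace
#' values.
#'
#' @param features Tibble from [extract_features()].
#' @param m,max_iter,eps FCM/GMM settings (defaults 2, 1000, 1e-5).
#' @param seed Integer seed for both clusterers' initializations.
#' @param restarts Seeded restarts per clusterer (default 5).
#'
#' @return A `consciousness_fit` object: `trace` tibble (`window`, `time_s`,
#'   `p_fcm`, `p_gmm`, `p_conscious`), fitted `fcm` and `gmm`
#'   `cluster_result`s with `conscious_index`es, the normalized feature
#'   tibble, and the indices of rows used.
#' @export
#'
#' @examples
#' \donttest{
#' sched <- tibble::tibble(duration_s = c(60, 60),
#'                         state = c("conscious", "unconscious"))
#' cfg <- synth_config(n_channels = 4, fs = 200, seed = 1)
#' rec <- generate_recording(sched, cfg)
#' fit <- rec$recording |>
#'   bandpass_filter() |>
#'   extract_features() |>
#'   estimate_consciousness(seed = 1)
#' fit
#' }
estimate_consciousness <- function(features, m = 2, max_iter = 1000,
                                   eps = 1e-5, seed = 1, restarts = 5) {
  norm <- normalize_features(features)
  fcols <- setdiff(names(norm), c("window", "start_time_s"))
  x <- as.matrix(norm[, fcols])
  ok <- which(apply(x, 1, function(r) all(is.finite(r))))
  if (length(ok) < 2) stop("fewer than 2 windows with finite features")
  if (length(ok) < nrow(x)) {
    message(nrow(x) - length(ok), " window(s) with non-finite features excluded from clustering")
  }
  xf <- x[ok, , drop = FALSE]
  fit_f <- fcm(xf, N = 2, m = m, max_iter = max_iter, eps = eps,
               seed = seed, restarts = restarts)
  fit_g <- gmm_em(xf, K = 2, max_iter = max_iter, tol = eps,
                  seed = seed, n_init = restarts)
  fit_f$conscious_index <- label_conscious_cluster(fit_f)
  fit_g$conscious_index <- label_conscious_cluster(fit_g)
  p_f <- p_g <- rep(NA_real_, nrow(x))
  p_f[ok] <- fit_f$memberships[, fit_f$conscious_index]
  p_g[ok] <- fit_g$memberships[, fit_g$conscious_index]
  trace <- tibble::tibble(
    window = features$window,
    time_s = features$start_time_s,
    p_fcm = p_f,
    p_gmm = p_g,
    p_conscious = ensemble_average(p_f, p_g)
  )
  structure(
    list(trace = trace, fcm = fit_f, gmm = fit_g,
         features = norm, rows_used = ok),
    class = "consciousness_fit"
  )
}

#' @export
print.consciousness_fit <- function(x, ...) {
  cat(sprintf("<consciousness_fit> %d windows (%d clustered)\n",
              nrow(x$trace), length(x$rows_used)))
  cat(sprintf("FCM conscious cluster: %d | GMM conscious cluster: %d\n",
              x$fcm$conscious_index, x$gmm$conscious_index))
  cat(sprintf("mean consciousness level: %.3f\n",
              mean(x$trace$p_conscious, na.rm = TRUE)))
  invisible(x)
}
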