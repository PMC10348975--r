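# Evaluation of a fitted consciousness trace: feature contributions
# (Spearman), cluster separation (centroid-linkage Euclidean distance), and
# agreement with eyes-open/closed scoring (thresholded accuracy sweep).

#' Spearman feature contributions to the estimated consciousness level
#'
#' Spearman correlation (and p-value) between each feature and the per-method
#' and ensemble traces: how much each EEG signature drives the final
#' estimate. Correlations with `p > 0.05` are flagged as not significant.
#'
#' @param fit A `consciousness_fit` from [estimate_consciousness()].
#' @return A tibble with columns `feature`, `method` (`fcm`, `gmm`,
#'   `ensemble`), `rho`, `p_value`, `significant`.
#' @export
spearman_contributions <- function(fit) {
  stopifnot(inherits(fit, "consciousness_fit"))
  fcols <- setdiff(names(fit$features), c("window", "start_time_s"))
  traces <- list(fcm = fit$trace$p_fcm, gmm = fit$trace$p_gmm,
                 ensemble = fit$trace$p_conscious)
  purrr::map_dfr(fcols, function(fc) {
    purrr::map_dfr(names(traces), function(mth) {
      x <- fit$features[[fc]]
      y <- traces[[mth]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
        return(tibble::tibble(feature = fc, method = mth, rho = NaN,
                              p_value = NaN, significant = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      tibble::tibble(feature = fc, method = mth,
                     rho = unname(ct$estimate), p_value = ct$p.value,
                     significant = ct$p.value <= 0.05)
    })
  })
}

#' Euclidean distance between two cluster centroids
#'
#' Centroid-linkage separation between the conscious and unconscious
#' clusters, computed on the normalized features, over all feature
#' coordinates or any subset (e.g. a feature pair). Small distances signal
#' poorly separated clusters and unreliable consciousness estimates.
#'
#' @param c1,c2 Numeric centroid vectors of equal length.
#' @param dims Indices or names of the coordinates to use (default all).
#' @return Nonnegative distance.
#' @export
#'
#' @examples
#' intercluster_distance(c(0, 0), c(3, 4))  # 5
intercluster_distance <- function(c1, c2, dims = NULL) {
  stopifnot(length(c1) == length(c2))
  if (!is.null(dims)) {
    c1 <- c1[dims]
    c2 <- c2[dims]
  }
  sqrt(sum((c1 - c2)^2))
}

#' Accuracy of the consciousness trace against eyes scoring
#'
#' Binarizes the trace at each threshold (values at or above the threshold
#' become 1 = conscious), aggregates samples to one prediction per scoring
#' epoch by majority, and compares with the eyes labels (O = 1, C = 0).
#' Epochs labeled `O/C` or `NA` are excluded. Accuracy is
#' `(TP + TN) / (TP + TN + FP + FN)` per threshold; thresholds default to
#' 0.3-0.7 in steps of 0.1 because 0.5 need not be the conscious/unconscious
#' boundary.
#'
#' @param trace Tibble with `time_s` and `p_conscious` columns (e.g.
#'   `fit$trace`).
#' @param eyes Tibble with `epoch_start_s`, `epoch_end_s`, `label` columns
#'   (labels in `O`, `C`, `O/C`, `NA`), e.g. from [generate_eyes_scoring()]
#'   or [read_eyes_csv()].
#' @param thresholds Numeric thresholds (default `seq(0.3, 0.7, 0.1)`).
#' @param per_sample Compare per trace sample instead of per epoch (default
#'   `FALSE`: epoch-majority aggregation).
#'
#' @return A tibble with one row per threshold: `threshold`, `tp`, `tn`,
#'   `fp`, `fn`, `accuracy`.
#' @export
accuracy_vs_eyes <- function(trace, eyes, thresholds = seq(0.3, 0.7, by = 0.1),
                             per_sample = FALSE) {
  stopifnot(all(c("time_s", "p_conscious") %in% names(trace)),
            all(c("epoch_start_s", "epoch_end_s", "label") %in% names(eyes)))
  ev <- eyes[!is.na(eyes$label) & eyes$label %in% c("O", "C"), , drop = FALSE]
  if (nrow(ev) == 0) stop("no evaluable epochs (all O/C or NA)")
  truth_epoch <- as.integer(ev$label == "O")
  purrr::map_dfr(thresholds, function(th) {
    bin <- as.integer(trace$p_conscious >= th)
    pred <- truth <- integer(0)
    for (e in seq_len(nrow(ev))) {
      in_ep <- trace$time_s >= ev$epoch_start_s[e] &
        trace$time_s < ev$epoch_end_s[e] & !is.na(bin)
      if (!any(in_ep)) next
      if (per_sample) {
        pred <- c(pred, bin[in_ep])
        truth <- c(truth, rep(truth_epoch[e], sum(in_ep)))
      } else {
        pred <- c(pred, as.integer(mean(bin[in_ep]) >= 0.5))
        truth <- c(truth, truth_epoch[e])
      }
    }
    if (length(pred) == 0) stop("no trace samples fall inside evaluable epochs")
    tp <- sum(pred == 1 & truth == 1)
    tn <- sum(pred == 0 & truth == 0)
    fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    tibble::tibble(threshold = th, tp = tp, tn = tn, fp = fp, fn = fn,
                   accuracy = (tp + tn) / (tp + tn + fp + fn))
  })
}

#' Full evaluation report for a fitted trace
#'
#' Bundles the Spearman feature contributions, the per-method inter-cluster
#' centroid distances (overall and per feature pair), and, when eyes scoring
#' is supplied, the thresholded accuracy sweep.
#'
#' @param fit A `consciousness_fit`.
#' @param eyes Optional eyes-scoring tibble (see [accuracy_vs_eyes()]).
#' @param thresholds Thresholds for the accuracy sweep.
#' @return A list of class `consciousness_report` with elements
#'   `contributions`, `distances` (tibble: `method`, `dims`, `distance`),
#'   and `accuracy` (or `NULL`).
#' @export
evaluate_consciousness <- function(fit, eyes = NULL,
                                   thresholds = seq(0.3, 0.7, by = 0.1)) {
  stopifnot(inherits(fit, "consciousness_fit"))
  dist_rows <- purrr::map_dfr(list(fit$fcm, fit$gmm), function(cl) {
    fn <- cl$feature_names
    pairs <- utils::combn(length(fn), 2)
    per_pair <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      d <- pairs[, i]
      tibble::tibble(method = cl$method,
                     dims = paste(fn[d], collapse = "+"),
                     distance = intercluster_distance(cl$centroids[1, ],
                                                      cl$centroids[2, ], d))
    })
    dplyr::bind_rows(
      tibble::tibble(method = cl$method, dims = "all",
                     distance = intercluster_distance(cl$centroids[1, ],
                                                      cl$centroids[2, ])),
      per_pair
    )
  })
  structure(
    list(contributions = spearman_contributions(fit),
         distances = dist_rows,
         accuracy = if (!is.null(eyes)) {
           tryCatch(accuracy_vs_eyes(fit$trace, eyes, thresholds),
                    error = function(e) {
                      warning("accuracy not computed: ", conditionMessage(e))
                      NULL
                    })
         }),
    class = "consciousness_report"
  )
}

#' @export
print.consciousness_report <- function(x, ...) {
  cat("<consciousness_report>\n")
  cat("Feature contributions (Spearman rho, ensemble):\n")
  ens <- x$contributions[x$contributions$method == "ensemble", ]
  for (i in seq_len(nrow(ens))) {
    cat(sprintf("  %-11s %+.4f%s\n", ens$feature[i], ens$rho[i],
                if (isTRUE(ens$significant[i])) "" else " (n.s.)"))
  }
  ov <- x$distances[x$distances$dims == "all", ]
  cat(sprintf("Inter-cluster distance (all features): FCM %.4f, GMM %.4f\n",
              ov$distance[ov$method == "fcm"], ov$distance[ov$method == "gmm"]))
  if (!is.null(x$accuracy)) {
    cat("Accuracy vs eyes scoring:\n")
    for (i in seq_len(nrow(x$accuracy))) {
      cat(sprintf("  threshold %.1f: %.2f%%\n", x$accuracy$threshold[i],
                  100 * x$accuracy$accuracy[i]))
    }
  }
  invisible(x)
}
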