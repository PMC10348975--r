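# broom-style accessors for fitted objects.

#' Tidy a consciousness fit into its trace
#'
#' @param x A `consciousness_fit`.
#' @param ... Unused.
#' @return The trace tibble: `window`, `time_s`, `p_fcm`, `p_gmm`,
#'   `p_conscious`.
#' @export
tidy.consciousness_fit <- function(x, ...) x$trace

#' One-row summary of a consciousness fit
#'
#' @param x A `consciousness_fit`.
#' @param ... Unused.
#' @return A one-row tibble: window counts, per-method conscious-cluster
#'   index, iterations, final objectives, overall inter-cluster distances,
#'   and the mean estimated consciousness level.
#' @export
glance.consciousness_fit <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$trace),
    n_clustered = length(x$rows_used),
    fcm_conscious_cluster = x$fcm$conscious_index,
    gmm_conscious_cluster = x$gmm$conscious_index,
    fcm_iterations = length(x$fcm$objective),
    gmm_iterations = length(x$gmm$objective),
    fcm_objective = x$fcm$objective[length(x$fcm$objective)],
    gmm_loglik = x$gmm$objective[length(x$gmm$objective)],
    fcm_intercluster_distance = intercluster_distance(
      x$fcm$centroids[1, ], x$fcm$centroids[2, ]),
    gmm_intercluster_distance = intercluster_distance(
      x$gmm$centroids[1, ], x$gmm$centroids[2, ]),
    mean_p_conscious = mean(x$trace$p_conscious, na.rm = TRUE)
  )
}

#' Tidy a cluster result
#'
#' @param x A `cluster_result` from [fcm()] or [gmm_em()].
#' @param ... Unused.
#' @return A tibble with one row per observation: `row`, membership columns
#'   `p_cluster1`, `p_cluster2`, ...
#' @export
tidy.cluster_result <- function(x, ...) {
  u <- x$memberships
  out <- tibble::as_tibble(u, .name_repair = ~ paste0("p_cluster", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(row = seq_len(nrow(u))), out)
}

#' One-row summary of a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A one-row tibble: method, observation/cluster counts, iterations,
#'   final objective.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_obs = nrow(x$memberships),
    n_clusters = ncol(x$memberships),
    iterations = length(x$objective),
    objective = x$objective[length(x$objective)]
  )
}
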