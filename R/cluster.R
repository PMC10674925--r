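#' K-means clustering of adherence trajectories
#'
#' Lloyd's algorithm with squared Euclidean distance on the window-level CMA
#' vectors, in the style of k-means for longitudinal data: `n_starts`
#' independent k-means++ initializations, iteration until the assignments
#' stabilize (or `max_iter`), empty clusters re-seeded from the point farthest
#' from its centroid, and the start with the lowest within-cluster sum of
#' squares returned. Dimensions are left unstandardized: all windows share
#' the `[0, 1]` CMA scale.
#'
#' @param trajectories A [cma_trajectories()] tibble (or any data frame with
#'   `patient_id` and `w1 ... w<n>` columns).
#' @param k Number of clusters (>= 2).
#' @param n_starts Independent initializations (default 20).
#' @param max_iter Maximum Lloyd iterations per start.
#' @param seed Integer seed for the initializations.
#' @return A `traj_clusters` object: list with `k`, `centroids` (k x windows
#'   matrix), `assignments` (tibble `patient_id`, `cluster`), `wss`,
#'   `wss_trace` (per-iteration totals of the winning start), `ch_score`, and
#'   `labels` (filled by [label_clusters()]).
#' @export
kmeans_longitudinal <- function(trajectories, k, n_starts = 20,
                                max_iter = 100, seed = NULL) {
  x <- trajectory_matrix(trajectories)
  if (any(!is.finite(x))) stop("trajectories contain non-finite values")
  if (k < 2) stop("k must be at least 2")
  if (nrow(unique(x)) < k) {
    stop("fewer distinct trajectories (", nrow(unique(x)), ") than k = ", k)
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- lloyd_once(x, k, max_iter)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  centroids <- best$centroids
  rownames(centroids) <- NULL
  out <- structure(list(
    k = k,
    centroids = centroids,
    assignments = tibble::tibble(patient_id = trajectories$patient_id,
                                 cluster = best$cluster),
    wss = best$wss,
    wss_trace = best$trace,
    ch_score = NA_real_,
    labels = NULL
  ), class = "traj_clusters")
  out$ch_score <- calinski_harabasz(trajectories, out)
  out
}

trajectory_matrix <- function(trajectories) {
  wcols <- grep("^w[0-9]+$", names(trajectories), value = TRUE)
  wcols <- wcols[order(as.integer(sub("^w", "", wcols)))]
  as.matrix(trajectories[wcols])
}

# squared distances from every row of x to every centroid
dist2 <- function(x, centers) {
  d <- -2 * x %*% t(centers)
  d <- sweep(d, 2, rowSums(centers^2), `+`)
  d + rowSums(x^2)
}

kpp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

lloyd_once <- function(x, k, max_iter) {
  centers <- kpp_init(x, k)
  assign_prev <- rep(0L, nrow(x))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d <- dist2(x, centers)
    cl <- max.col(-d, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    for (j in which(tabulate(cl, k) == 0)) {
      far <- which.max(d[cbind(seq_len(nrow(x)), cl)])
      cl[far] <- j
      d[far, ] <- Inf  # cannot be stolen again this iteration
    }
    for (j in seq_len(k)) centers[j, ] <- colMeans(x[cl == j, , drop = FALSE])
    trace <- c(trace, sum((x - centers[cl, , drop = FALSE])^2))
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
  }
  list(centroids = centers, cluster = cl,
       wss = trace[length(trace)], trace = trace)
}

#' Calinski-Harabasz criterion of a clustering
#'
#' The between/within variance ratio
#' `CH = (B / (k - 1)) / (W / (n - k))`, where `B` is the weighted scatter of
#' the centroids around the grand mean and `W` the within-cluster sum of
#' squares. A perfectly tight clustering (`W = 0`) scores `+Inf`.
#'
#' @param trajectories The clustered data (see [kmeans_longitudinal()]).
#' @param model A `traj_clusters` object.
#' @return A nonnegative number (possibly `Inf`).
#' @export
calinski_harabasz <- function(trajectories, model) {
  x <- trajectory_matrix(trajectories)
  cl <- model$assignments$cluster
  k <- model$k
  n <- nrow(x)
  if (k <= 1 || n <= k) stop("Calinski-Harabasz requires 1 < k < n")
  grand <- colMeans(x)
  ng <- tabulate(cl, k)
  b <- sum(ng * rowSums(sweep(model$centroids, 2, grand)^2))
  w <- sum((x - model$centroids[cl, , drop = FALSE])^2)
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Select the number of trajectory groups
#'
#' Fits [kmeans_longitudinal()] for each candidate `k` and returns the model
#' maximizing the Calinski-Harabasz criterion, ties broken toward smaller
#' `k`. The per-`k` scores are kept in the result (`ch_by_k`).
#'
#' @inheritParams kmeans_longitudinal
#' @param k_range Candidate cluster counts (default 2 to 6).
#' @return The winning `traj_clusters` model, labeled by [label_clusters()],
#'   with an extra `ch_by_k` tibble.
#' @export
select_k <- function(trajectories, k_range = 2:6, n_starts = 20,
                     max_iter = 100, seed = NULL) {
  if (!length(k_range)) stop("k_range is empty")
  n_distinct <- nrow(unique(trajectory_matrix(trajectories)))
  ks <- sort(k_range[k_range <= n_distinct & k_range < nrow(trajectories)])
  if (!length(ks)) {
    stop("no feasible k in k_range: only ", n_distinct,
         " distinct trajectories")
  }
  if (!is.null(seed)) set.seed(seed)
  fits <- purrr::map(ks, ~kmeans_longitudinal(trajectories, .x,
                                              n_starts = n_starts,
                                              max_iter = max_iter))
  scores <- purrr::map_dbl(fits, "ch_score")
  best <- fits[[which.max(scores)]]  # which.max takes the first (smallest k)
  best$ch_by_k <- tibble::tibble(k = ks, ch = scores)
  label_clusters(best)
}

#' Label clusters semantically from their centroids
#'
#' Deterministic rules on the centroid shapes: a cluster whose centroid
#' averages at least 0.7 over windows 1-4 but at most 0.35 over windows 9-12
#' is `partial_drop_off` (high early adherence, drop later). The remaining
#' clusters are ranked by overall centroid mean: top is `high`, bottom `low`,
#' the middle one `moderate`; surplus middle clusters are labeled `other`.
#' With a single non-drop-off cluster it is `high` when its mean is at least
#' 0.5 and `low` otherwise.
#'
#' @param model A `traj_clusters` object.
#' @return The model with `labels` (character vector indexed by cluster) set
#'   and a `label` column added to the assignments.
#' @export
label_clusters <- function(model) {
  cm <- rowMeans(model$centroids)
  nw <- ncol(model$centroids)
  early <- rowMeans(model$centroids[, 1:4, drop = FALSE])
  late <- rowMeans(model$centroids[, (nw - 3):nw, drop = FALSE])
  labels <- rep(NA_character_, model$k)
  labels[early >= 0.7 & late <= 0.35] <- "partial_drop_off"
  rest <- which(is.na(labels))
  if (length(rest) == 1) {
    labels[rest] <- if (cm[rest] >= 0.5) "high" else "low"
  } else if (length(rest) >= 2) {
    ord <- rest[order(cm[rest], decreasing = TRUE)]
    labels[ord[1]] <- "high"
    labels[ord[length(ord)]] <- "low"
    mid <- ord[-c(1, length(ord))]
    if (length(mid)) {
      # the median-ranked middle cluster is "moderate" (rank-based, so ties
      # in centroid means cannot flip the labeling)
      keep <- mid[ceiling(length(mid) / 2)]
      labels[keep] <- "moderate"
      labels[setdiff(mid, keep)] <- "other"
    }
  }
  model$labels <- labels
  model$assignments$label <- labels[model$assignments$cluster]
  model
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat("Trajectory clustering: k =", x$k,
      "| CH =", format(x$ch_score, digits = 6),
      "| WSS =", format(x$wss, digits = 6), "\n")
  if (!is.null(x$labels)) {
    tab <- table(x$assignments$label)
    cat("Groups:", paste0(names(tab), " (", as.integer(tab), ")",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy per-cluster summary of a trajectory clustering
#'
#' @param x A `traj_clusters` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: label, size, share and centroid
#'   mean.
#' @export
tidy.traj_clusters <- function(x, ...) {
  n_total <- nrow(x$assignments)
  sizes <- tabulate(x$assignments$cluster, x$k)
  tibble::tibble(
    cluster = seq_len(x$k),
    label = if (is.null(x$labels)) NA_character_ else x$labels,
    n = sizes,
    share = sizes / n_total,
    centroid_mean = rowMeans(x$centroids)
  )
}

#' One-row model summary of a trajectory clustering
#'
#' @inheritParams tidy.traj_clusters
#' @return A tibble with `k`, `n`, `wss`, `ch_score`.
#' @export
glance.traj_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignments), wss = x$wss,
                 ch_score = x$ch_score)
}

#' Plot clustered adherence trajectories
#'
#' Spaghetti plot of individual window-level CMA trajectories faceted by
#' cluster label, with the centroid overlaid.
#'
#' @param object A `traj_clusters` object.
#' @param trajectories The [cma_trajectories()] tibble the model was fitted
#'   on.
#' @param max_lines Individual trajectories drawn per cluster (sampled when
#'   larger, to keep the figure readable).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traj_clusters <- function(object, trajectories, max_lines = 100,
                                   ...) {
  panels <- if (is.null(object$labels)) as.character(seq_len(object$k)) else
    object$labels
  long <- trajectories |>
    dplyr::inner_join(object$assignments, by = "patient_id") |>
    tidyr::pivot_longer(dplyr::matches("^w[0-9]+$"), names_to = "window",
                        values_to = "cma") |>
    dplyr::mutate(window = as.integer(sub("^w", "", .data$window)),
                  panel = panels[.data$cluster])
  long <- long |>
    dplyr::group_by(.data$panel) |>
    dplyr::filter(.data$patient_id %in%
                    sample(unique(.data$patient_id),
                           min(max_lines, dplyr::n_distinct(.data$patient_id)))) |>
    dplyr::ungroup()
  cen <- tibble::as_tibble(object$centroids, .name_repair = ~paste0("w", seq_along(.x))) |>
    dplyr::mutate(cluster = dplyr::row_number(),
                  panel = panels[.data$cluster]) |>
    tidyr::pivot_longer(dplyr::matches("^w[0-9]+$"), names_to = "window",
                        values_to = "cma") |>
    dplyr::mutate(window = as.integer(sub("^w", "", .data$window)))
  ggplot2::ggplot(long, ggplot2::aes(.data$window, .data$cma)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.15, linewidth = 0.3) +
    ggplot2::geom_line(data = cen, colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_x_continuous(breaks = seq(2, 12, 2)) +
    ggplot2::labs(x = "30-day window", y = "CMA9") +
    ggplot2::theme_minimal()
}
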