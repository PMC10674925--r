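traj1d <- function(x) tibble::tibble(patient_id = seq_along(x), w1 = x)

manual_model <- function(x, cl, k) {
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(x[cl == j, , drop = FALSE])
  }))
  structure(list(k = k, centroids = centroids,
                 assignments = tibble::tibble(patient_id = seq_len(nrow(x)),
                                              cluster = cl)),
            class = "traj_clusters")
}

test_that("Calinski-Harabasz matches the hand-computed 1-D fixture", {
  tr <- traj1d(c(0, 2, 10, 12))
  model <- manual_model(matrix(c(0, 2, 10, 12)), c(1L, 1L, 2L, 2L), 2)
  # B = 2*(1-6)^2 + 2*(11-6)^2 = 100, W = 4, CH = (100/1)/(4/2) = 50
  expect_equal(calinski_harabasz(tr, model), 50)
})

test_that("zero within-cluster scatter scores +Inf", {
  tr <- traj1d(c(0, 0, 10, 10))
  model <- manual_model(matrix(c(0, 0, 10, 10)), c(1L, 1L, 2L, 2L), 2)
  expect_equal(calinski_harabasz(tr, model), Inf)
})

test_that("CH agrees with the scatter decomposition of stats::kmeans", {
  set.seed(14)
  tr <- tibble::tibble(patient_id = 1:80)
  for (w in paste0("w", 1:12)) tr[[w]] <- runif(80)
  fit <- kmeans_longitudinal(tr, k = 3, n_starts = 10, seed = 2)
  x <- as.matrix(tr[paste0("w", 1:12)])
  km <- suppressWarnings(stats::kmeans(x, centers = fit$centroids,
                                       iter.max = 1, algorithm = "Lloyd"))
  ch_ref <- (km$betweenss / 2) / (km$tot.withinss / (80 - 3))
  expect_equal(fit$ch_score, ch_ref, tolerance = 1e-6)
  expect_gt(fit$ch_score, 0)
  expect_true(is.finite(fit$ch_score))
})

test_that("CH input contracts are enforced", {
  tr <- traj1d(c(0, 2, 10, 12))
  expect_error(calinski_harabasz(tr, manual_model(matrix(c(0, 2, 10, 12)),
                                                  rep(1L, 4), 1)))
})

test_that("two separated bundles are recovered perfectly", {
  tr <- tibble::tibble(patient_id = 1:100)
  for (w in paste0("w", 1:12)) tr[[w]] <- rep(c(0.9, 0.1), each = 50)
  fit <- kmeans_longitudinal(tr, k = 2, n_starts = 5, seed = 1)
  expect_true(same_partition(fit$assignments$cluster,
                             rep(1:2, each = 50)))
  expect_equal(fit$wss, 0)
  expect_equal(fit$ch_score, Inf)
  sel <- select_k(tr, k_range = 2:4, n_starts = 5, seed = 1)
  expect_equal(sel$k, 2)
})

test_that("degenerate inputs error", {
  tr <- tibble::tibble(patient_id = 1:10)
  for (w in paste0("w", 1:12)) tr[[w]] <- 0.5
  expect_error(kmeans_longitudinal(tr, k = 2), "distinct")
  expect_error(select_k(tr, k_range = integer(0)), "empty")
  tr$w1[1] <- NaN
  expect_error(kmeans_longitudinal(tr, k = 2), "finite")
})

test_that("fixed seed and input give identical assignments", {
  set.seed(99)
  tr <- tibble::tibble(patient_id = 1:60)
  for (w in paste0("w", 1:12)) tr[[w]] <- runif(60)
  f1 <- kmeans_longitudinal(tr, k = 3, n_starts = 5, seed = 21)
  f2 <- kmeans_longitudinal(tr, k = 3, n_starts = 5, seed = 21)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$centroids, f2$centroids)
})

test_that("clustering is invariant to input row order up to relabeling", {
  set.seed(6)
  co <- generate_cohort(generator_config(300, seed = 17))
  tr <- cma_trajectories(co$events, cohort = co$patients)
  f1 <- select_k(tr, k_range = 2:5, n_starts = 10, seed = 3)
  perm <- sample(nrow(tr))
  f2 <- select_k(tr[perm, ], k_range = 2:5, n_starts = 10, seed = 3)
  expect_equal(f1$k, f2$k)
  cl2 <- f2$assignments$cluster[order(perm)]
  expect_true(same_partition(f1$assignments$cluster, cl2))
})

test_that("within-cluster sum of squares is non-increasing over iterations", {
  set.seed(23)
  for (i in 1:10) {
    tr <- tibble::tibble(patient_id = 1:120)
    for (w in paste0("w", 1:12)) tr[[w]] <- runif(120)
    fit <- kmeans_longitudinal(tr, k = 4, n_starts = 3, seed = i)
    expect_true(all(diff(fit$wss_trace) <= 1e-9))
  }
})

test_that("my k-means matches stats::kmeans quality on shared data", {
  set.seed(33)
  tr <- tibble::tibble(patient_id = 1:200)
  for (w in paste0("w", 1:12)) tr[[w]] <- runif(200)
  fit <- kmeans_longitudinal(tr, k = 4, n_starts = 20, seed = 5)
  km <- stats::kmeans(as.matrix(tr[paste0("w", 1:12)]), 4, nstart = 20)
  expect_lt(fit$wss, km$tot.withinss * 1.02)
})

test_that("centroid labeling follows the shape rules", {
  flat <- function(v) matrix(v, 1, 12)
  m <- structure(list(
    k = 4,
    centroids = rbind(flat(0.95), c(rep(0.85, 4), rep(0.5, 4), rep(0.1, 4)),
                      flat(0.5), flat(0.15)),
    assignments = tibble::tibble(patient_id = 1:4, cluster = 1:4)),
    class = "traj_clusters")
  lab <- label_clusters(m)
  expect_equal(lab$labels, c("high", "partial_drop_off", "moderate", "low"))
  expect_equal(lab$assignments$label,
               c("high", "partial_drop_off", "moderate", "low"))
  # no drop-off shape: plain ranking
  m$centroids <- rbind(flat(0.9), flat(0.5), flat(0.15), flat(0.99))
  lab2 <- label_clusters(m)
  expect_equal(lab2$labels, c("moderate", "other", "low", "high"))
  # two clusters only: high and low by mean
  m$k <- 2
  m$centroids <- rbind(flat(0.8), flat(0.2))
  m$assignments <- tibble::tibble(patient_id = 1:2, cluster = 1:2)
  lab3 <- label_clusters(m)
  expect_equal(lab3$labels, c("high", "low"))
})

test_that("tidy and glance summarize the clustering", {
  tr <- tibble::tibble(patient_id = 1:100)
  for (w in paste0("w", 1:12)) tr[[w]] <- rep(c(0.9, 0.1), each = 50)
  fit <- label_clusters(kmeans_longitudinal(tr, k = 2, n_starts = 3,
                                            seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$n), 100)
  expect_equal(sum(td$share), 1)
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$n, 100)
})
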