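toy_1d <- matrix(c(0, 1, 10, 11), 4, 1,
                 dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
toy_labels <- c(1, 1, 2, 2)

test_that("PCA projection is exact for data lying in a 2D subspace", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(100 * 2), 100, 2)))
  z <- matrix(rnorm(40 * 2, sd = 3), 40, 2)
  x <- z %*% t(basis) + matrix(rnorm(100, sd = 0.5), 40, 100, byrow = TRUE)
  rownames(x) <- sprintf("w%02d", 1:40)
  proj <- pca_project(x, 2)
  expect_equal(sum(proj$explained_variance_ratio), 1.0, tolerance = 1e-8)
  expect_equal(as.matrix(dist(proj$coords)), as.matrix(dist(x)),
               tolerance = 1e-8)
})

test_that("duplicating every point leaves the components unchanged", {
  set.seed(2)
  x <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(sprintf("w%02d", 1:20)))
  dup <- rbind(x, x)
  rownames(dup) <- sprintf("w%02d", 1:40)
  p1 <- pca_project(x, 2)
  p2 <- pca_project(dup, 2)
  expect_equal(unname(p2$coords[1:20, ]), unname(p1$coords),
               tolerance = 1e-8)
})

test_that("projection matches an independent covariance eigendecomposition", {
  set.seed(3)
  x <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(sprintf("w%02d", 1:50)))
  proj <- pca_project(x, 2)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(cov(xc), symmetric = TRUE)
  ref <- xc %*% eig$vectors[, 1:2]
  for (j in 1:2) {
    agree <- max(abs(proj$coords[, j] - ref[, j]))
    flipped <- max(abs(proj$coords[, j] + ref[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
  expect_equal(proj$explained_variance_ratio,
               eig$values[1:2] / sum(eig$values), tolerance = 1e-8)
})

test_that("projection errors when there are too few points", {
  x <- matrix(rnorm(4), 2, 2, dimnames = list(c("a", "b")))
  expect_error(pca_project(x, 2), class = "obsclust_input_error")
})

test_that("k-means degenerate cases behave as expected", {
  sol1 <- kmeans_cluster(toy_1d, k = 1, seed = 1)
  expect_equal(as.numeric(sol1$centers), mean(toy_1d))
  expect_equal(sol1$inertia, sum((toy_1d - mean(toy_1d))^2))

  soln <- kmeans_cluster(toy_1d, k = 4, seed = 1)
  expect_equal(soln$inertia, 0)
  expect_equal(sort(unique(soln$labels)), 1:4)

  expect_error(kmeans_cluster(toy_1d, k = 5, seed = 1),
               class = "obsclust_param_error")
})

test_that("k-means separates two planted blobs exactly and deterministically", {
  blobs <- make_blobs(2, per = 6, sep = 10, sd = 0.4, seed = 4)
  sol <- kmeans_cluster(blobs$x, k = 2, seed = 9)
  expect_equal(ari(blobs$labels, sol$labels), 1.0)
  sol2 <- kmeans_cluster(blobs$x, k = 2, seed = 9)
  expect_identical(sol$labels, sol2$labels)
})

test_that("silhouette matches the hand-computed 1D toy value", {
  # per-point scores 9.5/10.5, 8.5/9.5, 8.5/9.5, 9.5/10.5
  expect_equal(silhouette_score(toy_1d, toy_labels),
               (2 * 9.5 / 10.5 + 2 * 8.5 / 9.5) / 4, tolerance = 1e-12)
  expect_equal(silhouette_score(toy_1d, toy_labels), 0.8997, tolerance = 1e-4)
})

test_that("coincident clusters (a = b) score zero silhouette", {
  x <- matrix(0, 4, 1, dimnames = list(sprintf("p%d", 1:4)))
  expect_equal(silhouette_score(x, c(1, 1, 2, 2)), 0)
})

test_that("singleton clusters contribute zero and one cluster is an error", {
  x <- matrix(c(0, 1, 5), 3, 1, dimnames = list(c("a", "b", "c")))
  got <- silhouette_score(x, c(1, 1, 2))
  expect_equal(got, naive_silhouette(x, c(1, 1, 2)), tolerance = 1e-12)
  expect_error(silhouette_score(x, c(1, 1, 1)),
               class = "obsclust_index_error")
})

test_that("Calinski-Harabasz matches the hand-computed 1D toy value", {
  # BGSS = 100, WGSS = 1, n = 4, k = 2 -> (100/1)/(1/2) = 200
  expect_equal(calinski_harabasz(toy_1d, toy_labels), 200.0,
               tolerance = 1e-12)
  expect_error(calinski_harabasz(toy_1d, c(1, 2, 3, 4)),
               class = "obsclust_index_error")
})

test_that("zero within-cluster dispersion yields infinite CH with a warning", {
  x <- matrix(c(0, 0, 5, 5), 4, 1, dimnames = list(sprintf("p%d", 1:4)))
  expect_warning(v <- calinski_harabasz(x, c(1, 1, 2, 2)), "infinite")
  expect_identical(v, Inf)
})

test_that("Davies-Bouldin matches the hand-computed 1D toy value", {
  # s1 = s2 = 0.5, centroid distance 10 -> (0.5+0.5)/10 = 0.1
  expect_equal(davies_bouldin(toy_1d, toy_labels), 0.1, tolerance = 1e-12)
})

test_that("perfectly tight clusters have zero Davies-Bouldin", {
  x <- matrix(c(0, 0, 5, 5), 4, 1, dimnames = list(sprintf("p%d", 1:4)))
  expect_equal(davies_bouldin(x, c(1, 1, 2, 2)), 0)
})

test_that("coincident centroids are skipped with a warning", {
  x <- matrix(c(0, 2, 0, 2, 10, 12), 6, 1,
              dimnames = list(sprintf("p%d", 1:6)))
  expect_warning(v <- davies_bouldin(x, c(1, 1, 2, 2, 3, 3)), "coincident")
  expect_true(is.finite(v))
})

test_that("all three indices match brute force on random instances", {
  for (case in 1:25) {
    set.seed(case)
    n <- sample(10:40, 1)
    d <- sample(1:4, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n, d, dimnames = list(sprintf("p%03d", 1:n)))
    labels <- sample.int(k, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_score(x, labels), naive_silhouette(x, labels),
                 tolerance = 1e-10)
    if (length(unique(labels)) >= 2 && length(unique(labels)) < n) {
      expect_equal(calinski_harabasz(x, labels),
                   naive_calinski_harabasz(x, labels), tolerance = 1e-10)
    }
    expect_equal(davies_bouldin(x, labels), naive_davies_bouldin(x, labels),
                 tolerance = 1e-10)
  }
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  set.seed(10)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(sprintf("p%02d", 1:30)))
  labels <- sample.int(3, 30, replace = TRUE)
  ref <- mean(cluster::silhouette(labels, dist(x))[, "sil_width"])
  expect_equal(silhouette_score(x, labels), ref, tolerance = 1e-10)
})

test_that("indices are invariant to rotation and translation", {
  blobs <- make_blobs(3, per = 8, sep = 6, sd = 0.8, seed = 5)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  x2 <- blobs$x %*% rot + matrix(c(5, -3), nrow(blobs$x), 2, byrow = TRUE)
  rownames(x2) <- rownames(blobs$x)
  for (fn in list(silhouette_score, calinski_harabasz, davies_bouldin)) {
    expect_equal(fn(x2, blobs$labels), fn(blobs$x, blobs$labels),
                 tolerance = 1e-9)
  }
})

test_that("elbow picks the maximal second difference with smallest-k ties", {
  expect_equal(elbow_select(c("1" = 100, "2" = 60, "3" = 20, "4" = 18,
                              "5" = 16)), 3)
  expect_equal(elbow_select(c("2" = 80, "3" = 60, "4" = 40, "5" = 20)), 3)
  expect_error(elbow_select(c("2" = 80, "3" = 60, "5" = 20)),
               class = "obsclust_param_error")
  set.seed(6)
  v <- sort(cumsum(runif(8, 1, 10)), decreasing = TRUE)
  names(v) <- 2:9
  interior <- 2:7
  d2 <- v[interior - 1] - 2 * v[interior] + v[interior + 1]
  expect_equal(elbow_select(v), as.integer(names(v)[interior[which.max(d2)]]))
})

test_that("select_k recovers the planted cluster count on separated blobs", {
  blobs <- make_blobs(3, per = 20, sep = 10, sd = 0.5, seed = 7)
  rep <- select_k(blobs$x, k_range = 2:8, seed = 1)
  expect_equal(rep$selected_k$calinski_harabasz, 3)
  expect_equal(rep$selected_k$davies_bouldin, 3)
  expect_equal(rep$consensus_k, 3)
  expect_false(rep$weak_structure)
  expect_true(all(diff(rep$metrics$inertia) <= 1e-8))
})

test_that("the weak-structure flag tracks the maximum silhouette", {
  # structureless data: the flag must agree with the 0.25 silhouette rule
  set.seed(8)
  x <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(sprintf("p%02d", 1:60)))
  rep <- select_k(x, k_range = 2:6, seed = 1)
  expect_identical(rep$weak_structure, max(rep$metrics$silhouette) < 0.25)

  # clearly separated data must not be flagged
  blobs <- make_blobs(3, per = 15, sep = 10, sd = 0.4, seed = 9)
  expect_false(select_k(blobs$x, k_range = 2:6, seed = 1)$weak_structure)
})

test_that("consensus mode breaks ties toward the smallest k", {
  expect_equal(obsclust:::mode_smallest(c(3, 5, 3, 5)), 3)
  expect_equal(obsclust:::mode_smallest(c(5, 5, 3, 4)), 5)
  expect_equal(obsclust:::mode_smallest(c(10, 2, 10, 2)), 2)
})
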