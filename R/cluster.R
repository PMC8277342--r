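#' Project word vectors onto principal components
#'
#' Mean-centred projection onto the top `n_components` right singular
#' directions. Sign convention: within each component, the loading of
#' largest magnitude is made positive, so projections are reproducible
#' across platforms.
#'
#' @param table An [embedding_table()] (or numeric matrix with rownames).
#' @param n_components Number of components (default 2, for plotting and
#'   distance computations "on the graph").
#' @return An object of class `projected_embedding`: list with `words`,
#'   `coords` (words x components matrix) and `explained_variance_ratio`.
#' @export
pca_project <- function(table, n_components = 2) {
  x <- if (inherits(table, "embedding_table")) table$vectors else table
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  check_number(n_components, "n_components", lower = 1, integer = TRUE)
  if (nrow(x) < n_components + 1) {
    obs_stop(sprintf("need at least %d points for %d components, got %d",
                     n_components + 1, n_components, nrow(x)),
             "obsclust_input_error")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  evr <- if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var else rep(0, k)
  structure(list(words = rownames(x), coords = coords,
                 explained_variance_ratio = evr),
            class = "projected_embedding")
}

#' @export
print.projected_embedding <- function(x, ...) {
  cat(sprintf("<projected_embedding> %d words x %d components (EVR %s)\n",
              nrow(x$coords), ncol(x$coords),
              paste(sprintf("%.3f", x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (inherits(points, "projected_embedding")) return(points$coords)
  if (inherits(points, "embedding_table")) return(points$vectors)
  stopifnot(is.matrix(points), is.numeric(points))
  points
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (c in 2L:k) {
    if (sum(d2) <= 0) {
      # all remaining points coincide with chosen centres
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[c, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[c, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

run_lloyd <- function(x, centers, max_iter) {
  tryCatch(
    stats::kmeans(x, centers = centers, iter.max = max_iter,
                  algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) {
      # "did not converge" warnings: rerun suppressed to keep the result
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = max_iter,
                                     algorithm = "Lloyd"))
    }
  )
}

#' k-means clustering with k-means++ restarts
#'
#' Lloyd's algorithm (via [stats::kmeans()]) from `n_init` k-means++
#' initialisations, keeping the solution with the lowest within-cluster sum
#' of squares. Deterministic given `seed`. Extra initial centre sets can be
#' supplied (e.g. warm starts) and compete with the random restarts.
#'
#' @param points A `projected_embedding`, `embedding_table`, or numeric
#'   matrix with rownames.
#' @param k Number of clusters, `1 <= k <=` number of points.
#' @param seed Integer RNG seed.
#' @param n_init Number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300; iterations
#'   stop earlier at assignment convergence).
#' @param extra_inits Optional list of k x d centre matrices to try in
#'   addition to the random restarts.
#' @return An object of class `cluster_solution`: list with `k`, `labels`
#'   (named integer vector, cluster ids 1..k, every id used), `centers`
#'   (k x d matrix) and `inertia` (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(points, k, seed = 1, n_init = 10, max_iter = 300,
                           extra_inits = NULL) {
  x <- as_point_matrix(points)
  check_number(k, "k", lower = 1, integer = TRUE)
  if (k > nrow(x)) {
    obs_stop(sprintf("k = %d exceeds the number of points (%d)", k, nrow(x)),
             "obsclust_param_error")
  }
  best <- NULL
  with_seed(seed, {
    inits <- c(lapply(seq_len(n_init), function(i) kmeanspp_centers(x, k)),
               extra_inits)
    for (centers in inits) {
      fit <- run_lloyd(x, centers, max_iter)
      if (is.null(fit) || any(fit$size == 0)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) {
    obs_stop("k-means failed for every initialisation (k may exceed the number of distinct points)",
             "obsclust_param_error")
  }
  structure(list(k = as.integer(k),
                 labels = stats::setNames(as.integer(best$cluster),
                                          rownames(x)),
                 centers = best$centers,
                 inertia = best$tot.withinss),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k=%d, n=%d, inertia=%.4g (sizes: %s)\n",
              x$k, length(x$labels), x$inertia,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

check_labels <- function(x, labels) {
  stopifnot(nrow(x) == length(labels))
  labels <- as.integer(as.factor(labels))
  k <- max(labels)
  list(labels = labels, k = k, n = nrow(x))
}

#' Mean silhouette coefficient
#'
#' For each point, `s = (b - a) / max(a, b)` where `a` is the mean distance
#' to the other members of its own cluster and `b` the smallest mean
#' distance to any other cluster; points in singleton clusters score 0. The
#' returned value is the mean over points (Euclidean distances).
#'
#' @param points Matrix-like input accepted by [kmeans_cluster()].
#' @param labels Cluster assignment vector.
#' @return Scalar in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels) {
  x <- as_point_matrix(points)
  lb <- check_labels(x, labels)
  if (lb$k < 2L) {
    obs_stop("silhouette requires at least 2 clusters",
             "obsclust_index_error")
  }
  D <- as.matrix(stats::dist(x))
  sizes <- tabulate(lb$labels, lb$k)
  # mean distance from every point to every cluster
  md <- sapply(seq_len(lb$k), function(c) {
    rowSums(D[, lb$labels == c, drop = FALSE]) / sizes[c]
  })
  s <- numeric(lb$n)
  for (i in seq_len(lb$n)) {
    ci <- lb$labels[i]
    if (sizes[ci] == 1L) {
      s[i] <- 0
      next
    }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1L)  # exclude self
    b <- min(md[i, -ci])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' `(BGSS / (k - 1)) / (WGSS / (n - k))`: the ratio of between-cluster to
#' within-cluster dispersion, scaled by degrees of freedom (higher is
#' better). Zero within-cluster dispersion with distinct centroids yields
#' `Inf` with a warning.
#'
#' @inheritParams silhouette_score
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(points, labels) {
  x <- as_point_matrix(points)
  lb <- check_labels(x, labels)
  if (lb$k < 2L || lb$k >= lb$n) {
    obs_stop("Calinski-Harabasz requires 2 <= k < n", "obsclust_index_error")
  }
  overall <- colMeans(x)
  wgss <- 0
  bgss <- 0
  for (c in seq_len(lb$k)) {
    xc <- x[lb$labels == c, , drop = FALSE]
    ctr <- colMeans(xc)
    wgss <- wgss + sum(sweep(xc, 2, ctr)^2)
    bgss <- bgss + nrow(xc) * sum((ctr - overall)^2)
  }
  if (wgss == 0) {
    warning("zero within-cluster dispersion; Calinski-Harabasz is infinite")
    return(Inf)
  }
  (bgss / (lb$k - 1)) / (wgss / (lb$n - lb$k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio `(s_i + s_j) / d_ij`, where
#' `s` is the mean distance of members to their centroid and `d_ij` the
#' distance between centroids (lower is better). Coincident centroids are
#' skipped with a warning.
#'
#' @inheritParams silhouette_score
#' @return Nonnegative scalar.
#' @export
davies_bouldin <- function(points, labels) {
  x <- as_point_matrix(points)
  lb <- check_labels(x, labels)
  if (lb$k < 2L) {
    obs_stop("Davies-Bouldin requires at least 2 clusters",
             "obsclust_index_error")
  }
  centers <- matrix(NA_real_, lb$k, ncol(x))
  s <- numeric(lb$k)
  for (c in seq_len(lb$k)) {
    xc <- x[lb$labels == c, , drop = FALSE]
    centers[c, ] <- colMeans(xc)
    s[c] <- mean(sqrt(rowSums(sweep(xc, 2, centers[c, ])^2)))
  }
  M <- as.matrix(stats::dist(centers))
  skipped <- FALSE
  r <- numeric(lb$k)
  for (i in seq_len(lb$k)) {
    ratios <- vapply(setdiff(seq_len(lb$k), i), function(j) {
      if (M[i, j] == 0) {
        skipped <<- TRUE
        return(NA_real_)
      }
      (s[i] + s[j]) / M[i, j]
    }, numeric(1))
    r[i] <- if (all(is.na(ratios))) NA_real_ else max(ratios, na.rm = TRUE)
  }
  if (skipped) warning("coincident centroids; affected cluster pairs skipped")
  mean(r, na.rm = TRUE)
}

#' Elbow selection from an inertia profile
#'
#' Returns the interior `k` maximising the discrete second difference
#' `inertia(k-1) - 2*inertia(k) + inertia(k+1)` (the point of maximal
#' curvature of the inertia-vs-k curve); ties go to the smallest `k`.
#'
#' @param inertia_by_k Named numeric vector of inertias, names are
#'   consecutive integer `k` values (at least 4).
#' @return Selected `k` (integer).
#' @export
elbow_select <- function(inertia_by_k) {
  ks <- as.integer(names(inertia_by_k))
  if (length(ks) < 4L || any(diff(ks) != 1L)) {
    obs_stop("elbow selection needs >= 4 consecutive k values",
             "obsclust_param_error")
  }
  v <- as.numeric(inertia_by_k)
  interior <- 2:(length(ks) - 1L)
  d2 <- v[interior - 1L] - 2 * v[interior] + v[interior + 1L]
  ks[interior[which.max(d2)]]
}

#' Select the number of clusters by four heuristics
#'
#' Runs [kmeans_cluster()] for every `k` in `k_range` (each `k` reuses the
#' previous solution, augmented with the point farthest from its centre, as
#' a warm-start candidate, which keeps the inertia profile monotone) and
#' reports the silhouette, Calinski-Harabasz, Davies-Bouldin and inertia per
#' `k`; the per-heuristic selections (argmax silhouette, argmax CH, argmin
#' DB, elbow); and their consensus (modal selection, ties to the smallest
#' `k`). A `weak_structure` flag is set when no `k` reaches silhouette 0.25.
#'
#' @param points Matrix-like input accepted by [kmeans_cluster()].
#' @param k_range Contiguous integer range within `[2, n - 1]` (default 2:8).
#' @param seed Integer RNG seed.
#' @param n_init k-means++ restarts per `k`.
#' @return An object of class `validity_report`: list with `metrics`
#'   (data.frame over `k`), `selected_k` (named list per heuristic),
#'   `consensus_k`, `weak_structure` and `solutions` (list of
#'   `cluster_solution` keyed by `k`).
#' @export
select_k <- function(points, k_range = 2:8, seed = 1, n_init = 10) {
  x <- as_point_matrix(points)
  k_range <- sort(as.integer(k_range))
  if (any(diff(k_range) != 1L)) {
    obs_stop("`k_range` must be contiguous", "obsclust_param_error")
  }
  if (min(k_range) < 2L || max(k_range) > nrow(x) - 1L) {
    obs_stop("`k_range` must lie within [2, n - 1]", "obsclust_param_error")
  }
  solutions <- vector("list", length(k_range))
  names(solutions) <- as.character(k_range)
  metrics <- data.frame(k = k_range, silhouette = NA_real_,
                        calinski_harabasz = NA_real_,
                        davies_bouldin = NA_real_, inertia = NA_real_)
  prev <- NULL
  for (idx in seq_along(k_range)) {
    k <- k_range[idx]
    extra <- NULL
    if (!is.null(prev)) {
      # split the previous solution: add the point farthest from its centre
      dsq <- rowSums((x - prev$centers[prev$labels, , drop = FALSE])^2)
      far <- which.max(dsq)
      extra <- list(rbind(prev$centers, x[far, ]))
    }
    sol <- kmeans_cluster(x, k, seed = seed + k, n_init = n_init,
                          extra_inits = extra)
    solutions[[idx]] <- sol
    metrics$silhouette[idx] <- silhouette_score(x, sol$labels)
    metrics$calinski_harabasz[idx] <- calinski_harabasz(x, sol$labels)
    metrics$davies_bouldin[idx] <- davies_bouldin(x, sol$labels)
    metrics$inertia[idx] <- sol$inertia
    prev <- sol
  }
  selected <- list(
    silhouette = k_range[which.max(metrics$silhouette)],
    calinski_harabasz = k_range[which.max(metrics$calinski_harabasz)],
    davies_bouldin = k_range[which.min(metrics$davies_bouldin)],
    elbow = if (length(k_range) >= 4L) {
      elbow_select(stats::setNames(metrics$inertia, k_range))
    } else {
      NA_integer_
    }
  )
  structure(list(
    metrics = metrics,
    selected_k = selected,
    consensus_k = as.integer(mode_smallest(unlist(selected))),
    weak_structure = max(metrics$silhouette) < 0.25,
    solutions = solutions
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  print(x$metrics, row.names = FALSE)
  sel <- vapply(x$selected_k, function(v) as.integer(v)[1], integer(1))
  cat(sprintf("selected k: %s\n",
              paste(names(sel), sel, sep = "=", collapse = ", ")))
  cat(sprintf("consensus k: %d%s\n", x$consensus_k,
              if (x$weak_structure) " (weak structure: max silhouette < 0.25)"
              else ""))
  invisible(x)
}
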