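# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, not the package's code paths.

naive_silhouette <- function(x, labels) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

naive_calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  overall <- colMeans(x)
  wgss <- 0
  bgss <- 0
  for (cl in unique(labels)) {
    xc <- x[labels == cl, , drop = FALSE]
    ctr <- colMeans(xc)
    for (i in seq_len(nrow(xc))) wgss <- wgss + sum((xc[i, ] - ctr)^2)
    bgss <- bgss + nrow(xc) * sum((ctr - overall)^2)
  }
  (bgss / (k - 1)) / (wgss / (n - k))
}

naive_davies_bouldin <- function(x, labels) {
  cls <- sort(unique(labels))
  k <- length(cls)
  ctr <- matrix(NA_real_, k, ncol(x))
  for (c in seq_len(k)) {
    ctr[c, ] <- colMeans(x[labels == cls[c], , drop = FALSE])
  }
  s <- sapply(seq_len(k), function(c) {
    xc <- x[labels == cls[c], , drop = FALSE]
    mean(apply(xc, 1, function(p) sqrt(sum((p - ctr[c, ])^2))))
  })
  r <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      best <- max(best, (s[i] + s[j]) / d)
    }
    r[i] <- best
  }
  mean(r)
}

# O(L^2) pair enumeration with per-phrase deduplication.
naive_cooccurrence <- function(token_lists, words) {
  n <- length(words)
  X <- matrix(0, n, n, dimnames = list(words, words))
  for (toks in token_lists) {
    u <- unique(toks[toks %in% words])
    if (length(u) < 2) next
    for (a in seq_along(u)) {
      for (b in seq_along(u)) {
        if (a != b) X[u[a], u[b]] <- X[u[a], u[b]] + 1
      }
    }
  }
  X / 1  # counts once per ordered pair per phrase
}

# Adjusted Rand index from the contingency table (chance-corrected).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Planted Gaussian blobs for index tests; centres equally spaced on a circle
# so the minimum pairwise centre distance is exactly `sep`.
make_blobs <- function(k, per, sep = 10, sd = 0.5, d = 2, seed = 1) {
  set.seed(seed)
  radius <- sep / (2 * sin(pi / k))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  ctr <- matrix(0, k, d)
  ctr[, 1] <- radius * cos(ang)
  ctr[, 2] <- radius * sin(ang)
  x <- do.call(rbind, lapply(seq_len(k), function(c) {
    sweep(matrix(rnorm(per * d, 0, sd), per, d), 2, ctr[c, ], "+")
  }))
  rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(k), each = per))
}

# Small fast synthetic spec for unit tests.
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_users = 150, k_true = 3, theme_lexicon_size = 12,
                   shared_core_size = 6, core_mix = 0.2, embed_dim = 16,
                   separation = 10, noise_sd = 0.5, outlier_rate = 0,
                   seed = 11)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

quick_config <- function(spec, seed = 1, n_epochs = 60, ...) {
  synthetic_pipeline_config(spec, seed = seed, n_epochs = n_epochs, ...)
}

random_phrases <- function(n, vocab_words, max_len = 8, seed = 1) {
  set.seed(seed)
  toks <- lapply(seq_len(n), function(i) {
    sample(vocab_words, sample.int(max_len, 1), replace = TRUE)
  })
  phrase_set(toks)
}
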