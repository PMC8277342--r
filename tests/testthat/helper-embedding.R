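# Shared fixtures and reference implementations for the fine-tuning tests.

# Build a cooccurrence object directly from a symmetric count matrix.
cooc_from_matrix <- function(m, words = rownames(m)) {
  dimnames(m) <- list(words, words)
  structure(list(X = Matrix::Matrix(m, sparse = TRUE), words = words),
            class = "cooccurrence")
}

zero_state <- function(words, d) {
  n <- length(words)
  list(W = matrix(0, n, d, dimnames = list(words, NULL)),
       Wt = matrix(0, n, d, dimnames = list(words, NULL)),
       b = setNames(numeric(n), words),
       bt = setNames(numeric(n), words),
       pretrained = NULL)
}

random_state <- function(words, d, seed, pretrained = NULL) {
  set.seed(seed)
  n <- length(words)
  list(W = matrix(rnorm(n * d), n, d, dimnames = list(words, NULL)),
       Wt = matrix(rnorm(n * d), n, d, dimnames = list(words, NULL)),
       b = setNames(rnorm(n), words),
       bt = setNames(rnorm(n), words),
       pretrained = pretrained)
}

random_cooc <- function(words, seed, density = 0.6, max_count = 50) {
  set.seed(seed)
  n <- length(words)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        m[i, j] <- m[j, i] <- sample.int(max_count, 1)
      }
    }
  }
  cooc_from_matrix(m, words)
}

# Plain textbook evaluation of the objective, scalar loops throughout.
naive_mittens_loss <- function(state, Xmat, mu, x_max = 100, alpha = 0.75) {
  n <- nrow(Xmat)
  loss <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- Xmat[i, j]
      if (x <= 0) next
      f <- if (x < x_max) (x / x_max)^alpha else 1
      resid <- sum(state$W[i, ] * state$Wt[j, ]) + state$b[i] + state$bt[j] -
        log(x)
      loss <- loss + f * resid^2
    }
  }
  if (!is.null(state$pretrained)) {
    for (w in rownames(state$pretrained)) {
      dev <- state$W[w, ] + state$Wt[w, ] - state$pretrained[w, ]
      loss <- loss + mu * sum(dev^2)
    }
  }
  unname(loss)
}

# Independently coded plain-GloVe AdaGrad reference: scalar loops over
# ordered nonzero pairs, same stated initialisation and update rule.
reference_glove_fit <- function(Xmat, d, n_epochs, lr, seed,
                                x_max = 100, alpha = 0.75) {
  n <- nrow(Xmat)
  set.seed(seed)
  W <- matrix(runif(n * d, -0.5 / d, 0.5 / d), n, d)
  set.seed(seed + 1)
  Wt <- matrix(runif(n * d, -0.5 / d, 0.5 / d), n, d)
  b <- numeric(n)
  bt <- numeric(n)
  GW <- matrix(1, n, d); GWt <- matrix(1, n, d)
  Gb <- rep(1, n); Gbt <- rep(1, n)
  nz <- which(Xmat > 0, arr.ind = TRUE)
  for (epoch in seq_len(n_epochs)) {
    gW <- matrix(0, n, d); gWt <- matrix(0, n, d)
    gb <- numeric(n); gbt <- numeric(n)
    for (p in seq_len(nrow(nz))) {
      i <- nz[p, 1]; j <- nz[p, 2]
      x <- Xmat[i, j]
      f <- if (x < x_max) (x / x_max)^alpha else 1
      delta <- 2 * f * (sum(W[i, ] * Wt[j, ]) + b[i] + bt[j] - log(x))
      gW[i, ] <- gW[i, ] + delta * Wt[j, ]
      gWt[j, ] <- gWt[j, ] + delta * W[i, ]
      gb[i] <- gb[i] + delta
      gbt[j] <- gbt[j] + delta
    }
    GW <- GW + gW^2; W <- W - lr * gW / sqrt(GW)
    GWt <- GWt + gWt^2; Wt <- Wt - lr * gWt / sqrt(GWt)
    Gb <- Gb + gb^2; b <- b - lr * gb / sqrt(Gb)
    Gbt <- Gbt + gbt^2; bt <- bt - lr * gbt / sqrt(Gbt)
  }
  W + Wt
}
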