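#' Construct an embedding table
#'
#' A thin wrapper around a numeric matrix whose rows are word vectors
#' (rownames are the words). All vectors share one dimension and must be
#' finite.
#'
#' @param vectors Numeric matrix with rownames, one row per word.
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors))) {
    obs_stop("embedding matrix must have word rownames",
             "obsclust_param_error")
  }
  if (!all(is.finite(vectors))) {
    obs_stop("embedding vectors must be finite", "obsclust_numeric_error")
  }
  structure(list(words = rownames(vectors), vectors = vectors,
                 dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words x %d dims\n",
              length(x$words), x$dim))
  invisible(x)
}

#' Subset an embedding table to a word list
#'
#' @param table An [embedding_table()].
#' @param words Words to retain (order preserved); all must be present.
#' @return An [embedding_table()] over `words`.
#' @export
subset_embedding <- function(table, words) {
  stopifnot(inherits(table, "embedding_table"))
  miss <- setdiff(words, table$words)
  if (length(miss) > 0) {
    obs_stop(sprintf("words missing from embedding table: %s",
                     paste(utils::head(miss, 5), collapse = ", ")),
             "obsclust_lookup_error")
  }
  embedding_table(table$vectors[words, , drop = FALSE])
}

#' Configuration for GloVe/Mittens fine-tuning
#'
#' Defaults follow the original GloVe recipe (`x_max = 100`, `alpha = 0.75`)
#' and the Mittens retrofitting default `mu = 0.1`; the learning rate and
#' epoch count are the conventional full-batch AdaGrad settings for small
#' vocabularies.
#'
#' @param dim Vector dimension (pretrained general-purpose vectors are
#'   commonly 100-dimensional).
#' @param x_max Weighting cap: co-occurrence counts at or above `x_max` get
#'   weight 1.
#' @param alpha Weighting exponent in (0, 1].
#' @param mu Nonnegative Mittens penalty weight pulling each trained vector
#'   toward its pretrained reference.
#' @param learning_rate Positive AdaGrad learning rate.
#' @param n_epochs Number of full-batch epochs.
#' @param penalize Either `"sum"` (penalty on the final representation
#'   `w + w_tilde`, the default) or `"w"` (penalty on `w` only).
#' @param seed Integer seed for the random initialisation of words without
#'   pretrained vectors.
#' @return An object of class `embed_config`.
#' @export
embed_config <- function(dim = 100, x_max = 100, alpha = 0.75, mu = 0.1,
                         learning_rate = 0.05, n_epochs = 1000,
                         penalize = c("sum", "w"), seed = 1) {
  check_number(dim, "dim", lower = 1, integer = TRUE)
  check_number(x_max, "x_max", lower = .Machine$double.eps)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  check_number(mu, "mu", lower = 0)
  check_number(learning_rate, "learning_rate", lower = .Machine$double.eps)
  check_number(n_epochs, "n_epochs", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(dim = as.integer(dim), x_max = x_max, alpha = alpha,
                 mu = mu, learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 penalize = match.arg(penalize), seed = as.integer(seed)),
            class = "embed_config")
}

#' GloVe weighting function
#'
#' `f(x) = (x / x_max)^alpha` for `x < x_max`, and 1 otherwise; `f(0) = 0`,
#' so zero-count pairs contribute nothing to the loss.
#'
#' @param x Nonnegative co-occurrence count(s).
#' @param x_max Cap above which the weight saturates at 1.
#' @param alpha Exponent in (0, 1].
#' @return Weight(s) in \[0, 1\].
#' @export
glove_weight <- function(x, x_max = 100, alpha = 0.75) {
  stopifnot(all(x >= 0))
  ifelse(x < x_max, (x / x_max)^alpha, 1)
}

# Internal: dense working pieces for the loss/gradient computations.
# state: list(W, Wt, b, bt, pretrained = matrix over a subset of rows or NULL)
mittens_parts <- function(state, X, cfg) {
  Xd <- as.matrix(X$X)
  Fw <- glove_weight(Xd, cfg$x_max, cfg$alpha)
  L <- matrix(0, nrow(Xd), ncol(Xd))
  nz <- Xd > 0
  L[nz] <- log(Xd[nz])
  pred <- state$W %*% t(state$Wt) +
    matrix(state$b, nrow(Xd), ncol(Xd)) +
    matrix(state$bt, nrow(Xd), ncol(Xd), byrow = TRUE)
  resid <- pred - L
  list(Fw = Fw, resid = resid, nz = nz)
}

penalty_dev <- function(state, cfg) {
  if (is.null(state$pretrained) || nrow(state$pretrained) == 0L) return(NULL)
  ridx <- match(rownames(state$pretrained), rownames(state$W))
  if (anyNA(ridx)) {
    obs_stop("pretrained rows must be a subset of the vocabulary",
             "obsclust_param_error")
  }
  est <- if (cfg$penalize == "sum") {
    state$W[ridx, , drop = FALSE] + state$Wt[ridx, , drop = FALSE]
  } else {
    state$W[ridx, , drop = FALSE]
  }
  list(ridx = ridx, dev = est - state$pretrained)
}

#' Mittens loss
#'
#' The GloVe weighted least-squares objective plus the Mittens proximity
#' penalty:
#' \deqn{J = \sum_{i,j: X_{ij}>0} f(X_{ij}) (w_i \cdot \tilde w_j + b_i +
#'   \tilde b_j - \log X_{ij})^2 + \mu \sum_{i \in R} \lVert \hat w_i - r_i
#'   \rVert^2}
#' where \eqn{\hat w_i = w_i + \tilde w_i} (or \eqn{w_i} under
#' `penalize = "w"`), and `R` is the set of words with pretrained vectors.
#' The sum runs over all ordered pairs with nonzero counts, so each
#' unordered pair of the symmetric matrix contributes twice, as in the
#' canonical GloVe formulation. Natural logarithms are used.
#'
#' @param state Training state: list with `W`, `Wt` (N x d matrices with
#'   word rownames), `b`, `bt` (length-N biases) and optionally
#'   `pretrained` (reference matrix over a subset of the words).
#' @param X A [build_cooccurrence()] result.
#' @param cfg An [embed_config()].
#' @return Nonnegative scalar loss.
#' @export
mittens_loss <- function(state, X, cfg = embed_config(dim = ncol(state$W))) {
  if (!all(vapply(list(state$W, state$Wt, state$b, state$bt),
                  function(p) all(is.finite(p)), logical(1)))) {
    obs_stop("training state contains nonfinite parameters",
             "obsclust_numeric_error")
  }
  parts <- mittens_parts(state, X, cfg)
  loss <- sum(parts$Fw * parts$resid^2)
  pen <- penalty_dev(state, cfg)
  if (!is.null(pen)) loss <- loss + cfg$mu * sum(pen$dev^2)
  loss
}

#' Analytic gradients of the Mittens loss
#'
#' Returns the exact full-batch gradients used by [fit_mittens()], exposed
#' so they can be validated against finite differences.
#'
#' @inheritParams mittens_loss
#' @return List with `W`, `Wt`, `b`, `bt` gradient arrays matching the
#'   state's shapes.
#' @export
mittens_gradients <- function(state, X,
                              cfg = embed_config(dim = ncol(state$W))) {
  parts <- mittens_parts(state, X, cfg)
  Rw <- parts$Fw * parts$resid  # zero wherever X is zero since f(0) = 0
  gW <- 2 * (Rw %*% state$Wt)
  gWt <- 2 * crossprod(Rw, state$W)
  gb <- 2 * rowSums(Rw)
  gbt <- 2 * colSums(Rw)
  pen <- penalty_dev(state, cfg)
  if (!is.null(pen)) {
    gpen <- 2 * cfg$mu * pen$dev
    gW[pen$ridx, ] <- gW[pen$ridx, ] + gpen
    if (cfg$penalize == "sum") {
      gWt[pen$ridx, ] <- gWt[pen$ridx, ] + gpen
    }
  }
  list(W = gW, Wt = gWt, b = gb, bt = gbt)
}

#' Fine-tune word vectors on a co-occurrence matrix (Mittens)
#'
#' Minimises [mittens_loss()] by full-batch AdaGrad. Words with pretrained
#' vectors are initialised as `w_i = r_i / 2`, `w_tilde_i = r_i / 2` (so the
#' summed representation starts exactly at the pretrained vector); words
#' without pretrained vectors are initialised uniformly in
#' `[-0.5/d, 0.5/d]` from `cfg$seed` and train purely from the corpus.
#' Biases start at zero. AdaGrad accumulators start at 1 and each step is
#' `theta <- theta - lr * g / sqrt(G)` after `G <- G + g^2`. The final
#' representation is `w + w_tilde`.
#'
#' @param X A [build_cooccurrence()] result.
#' @param pretrained Optional [embedding_table()] covering any subset of the
#'   vocabulary (its dimension must equal `cfg$dim`).
#' @param cfg An [embed_config()].
#' @param trace If `TRUE`, attach the per-epoch loss trajectory (loss
#'   evaluated at the start of each epoch) as attribute `"loss"`.
#' @return An [embedding_table()] over the co-occurrence vocabulary, with
#'   attribute `"loss"` when `trace = TRUE`.
#' @export
fit_mittens <- function(X, pretrained = NULL, cfg = embed_config(),
                        trace = FALSE) {
  stopifnot(inherits(X, "cooccurrence"))
  words <- X$words
  n <- length(words)
  d <- cfg$dim
  rmat <- NULL
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "embedding_table"))
    if (pretrained$dim != d) {
      obs_stop(sprintf("pretrained dimension (%d) does not match cfg$dim (%d)",
                       pretrained$dim, d), "obsclust_config_error")
    }
    shared <- intersect(words, pretrained$words)
    if (length(shared) > 0) {
      rmat <- pretrained$vectors[shared, , drop = FALSE]
    }
  }

  W <- with_seed(cfg$seed, matrix(stats::runif(n * d, -0.5 / d, 0.5 / d),
                                  n, d, dimnames = list(words, NULL)))
  Wt <- with_seed(cfg$seed + 1L, matrix(stats::runif(n * d, -0.5 / d, 0.5 / d),
                                        n, d, dimnames = list(words, NULL)))
  if (!is.null(rmat)) {
    W[rownames(rmat), ] <- rmat / 2
    Wt[rownames(rmat), ] <- rmat / 2
  }
  b <- stats::setNames(numeric(n), words)
  bt <- stats::setNames(numeric(n), words)
  state <- list(W = W, Wt = Wt, b = b, bt = bt, pretrained = rmat)

  GW <- matrix(1, n, d)
  GWt <- matrix(1, n, d)
  Gb <- rep(1, n)
  Gbt <- rep(1, n)
  lr <- cfg$learning_rate
  losses <- if (trace) numeric(cfg$n_epochs) else NULL

  for (epoch in seq_len(cfg$n_epochs)) {
    if (trace) losses[epoch] <- mittens_loss(state, X, cfg)
    g <- mittens_gradients(state, X, cfg)
    GW <- GW + g$W^2
    state$W <- state$W - lr * g$W / sqrt(GW)
    GWt <- GWt + g$Wt^2
    state$Wt <- state$Wt - lr * g$Wt / sqrt(GWt)
    Gb <- Gb + g$b^2
    state$b <- state$b - lr * g$b / sqrt(Gb)
    Gbt <- Gbt + g$bt^2
    state$bt <- state$bt - lr * g$bt / sqrt(Gbt)
    if (!all(is.finite(state$W))) {
      obs_stop("training diverged to nonfinite parameters; lower learning_rate",
               "obsclust_numeric_error")
    }
  }
  out <- embedding_table(state$W + state$Wt)
  if (trace) attr(out, "loss") <- losses
  out
}

#' Read and write word vectors in the standard text format
#'
#' One word per line: the word followed by `d` whitespace-separated decimal
#' values. `write_vectors()` keeps at least 10 significant digits so that a
#' round trip reproduces vectors to better than 1e-8. `read_vectors()` can
#' restrict to a vocabulary while streaming over a large file.
#'
#' @param table An [embedding_table()].
#' @param path File path.
#' @param words Optional character vector; only these words are retained.
#' @return `read_vectors()` returns an [embedding_table()];
#'   `write_vectors()` returns `path` invisibly.
#' @export
write_vectors <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  lines <- vapply(seq_along(table$words), function(i) {
    paste(table$words[i],
          paste(sprintf("%.10g", table$vectors[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vectors
#' @export
read_vectors <- function(path, words = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    obs_stop("vector file is empty", "obsclust_format_error")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  d <- length(fields[[1L]]) - 1L
  if (d < 1L) {
    obs_stop("line 1 has no vector components", "obsclust_format_error")
  }
  nf <- lengths(fields)
  bad <- which(nf != d + 1L)
  if (length(bad) > 0) {
    obs_stop(sprintf("line %d has %d fields, expected %d",
                     bad[1L], nf[bad[1L]], d + 1L),
             "obsclust_format_error")
  }
  wrd <- vapply(fields, `[[`, character(1), 1L)
  keep <- if (is.null(words)) seq_along(wrd) else which(wrd %in% words)
  if (length(keep) == 0L) {
    obs_stop("no requested words found in vector file",
             "obsclust_format_error")
  }
  vec <- vapply(fields[keep], function(f) as.numeric(f[-1L]), numeric(d))
  vec <- if (d == 1L) matrix(vec, ncol = 1L) else t(vec)
  if (anyNA(vec)) {
    obs_stop("vector file contains non-numeric components",
             "obsclust_format_error")
  }
  rownames(vec) <- wrd[keep]
  embedding_table(vec)
}
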