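#' Split an entry table into two balanced halves
#'
#' Chronological mode sorts entries by timestamp and cuts where the
#' cumulative balancing quantity is closest to half the total, so every
#' timestamp in the first half precedes every timestamp in the second.
#' By-user mode shuffles users (by `seed`) and assigns each greedily to the
#' half with the smaller running total, so the user sets are disjoint.
#' Balancing can count entries or cleaned word tokens.
#'
#' @param entries Entry `data.frame`.
#' @param mode `"chronological"` or `"by_user"`.
#' @param balance_on `"words"` (cleaned token count, the default) or
#'   `"entries"`.
#' @param seed Integer seed for the user shuffle in by-user mode.
#' @return An object of class `split_result`: list with `half_a`, `half_b`
#'   (entry `data.frame`s), `mode`, `balance_on` and `sizes` (balancing
#'   totals per half).
#' @export
split_sample <- function(entries, mode = c("chronological", "by_user"),
                         balance_on = c("words", "entries"), seed = 1) {
  mode <- match.arg(mode)
  balance_on <- match.arg(balance_on)
  if (is.null(entries) || nrow(entries) < 2L) {
    obs_stop("need at least 2 entries to split", "obsclust_input_error")
  }
  weight <- if (balance_on == "entries") {
    rep(1, nrow(entries))
  } else {
    texts <- paste(
      ifelse(is.na(entries$obsession), "", entries$obsession),
      ifelse(is.na(entries$trigger), "", as.character(entries$trigger)),
      ifelse(is.na(entries$exposure), "", as.character(entries$exposure)),
      ifelse(is.na(entries$compulsion), "", as.character(entries$compulsion))
    )
    lengths(clean_tokens(texts))
  }

  if (mode == "chronological") {
    ord <- order(entries$timestamp)
    w <- weight[ord]
    cum <- cumsum(w)
    cut <- which.min(abs(cum - sum(w) / 2))
    cut <- min(max(cut, 1L), length(ord) - 1L)  # keep both halves non-empty
    a_idx <- ord[seq_len(cut)]
    b_idx <- ord[seq(cut + 1L, length(ord))]
  } else {
    users <- unique(entries$user_id)
    if (length(users) < 2L) {
      obs_stop("by-user split needs at least 2 users", "obsclust_input_error")
    }
    per_user <- tapply(weight, entries$user_id, sum)
    shuffled <- with_seed(seed, sample(users))
    tot <- c(a = 0, b = 0)
    assign_a <- logical(length(shuffled))
    for (u in seq_along(shuffled)) {
      assign_a[u] <- tot["a"] <= tot["b"]
      half <- if (assign_a[u]) "a" else "b"
      tot[half] <- tot[half] + per_user[[shuffled[u]]]
    }
    a_users <- shuffled[assign_a]
    a_idx <- which(entries$user_id %in% a_users)
    b_idx <- which(!(entries$user_id %in% a_users))
  }
  half_a <- entries[a_idx, , drop = FALSE]
  half_b <- entries[b_idx, , drop = FALSE]
  rownames(half_a) <- rownames(half_b) <- NULL
  structure(list(half_a = half_a, half_b = half_b, mode = mode,
                 balance_on = balance_on,
                 sizes = c(a = sum(weight[a_idx]), b = sum(weight[b_idx]))),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %s split: %d + %d entries (%s: %g / %g)\n",
              x$mode, nrow(x$half_a), nrow(x$half_b), x$balance_on,
              x$sizes["a"], x$sizes["b"]))
  invisible(x)
}

#' Inter-word Euclidean distance matrix
#'
#' Distances between word coordinates "on the graph" (typically the 2D
#' principal-component projection).
#'
#' @param proj A [pca_project()] result (or matrix with word rownames).
#' @param words Optional word subset/order; all must be present.
#' @return Symmetric matrix of Euclidean distances with zero diagonal and
#'   word dimnames.
#' @export
distance_matrix <- function(proj, words = NULL) {
  coords <- if (inherits(proj, "projected_embedding")) proj$coords else proj
  stopifnot(is.matrix(coords), !is.null(rownames(coords)))
  if (!is.null(words)) {
    miss <- setdiff(words, rownames(coords))
    if (length(miss) > 0) {
      obs_stop(sprintf("word not present in projection: %s",
                       paste(utils::head(miss, 5), collapse = ", ")),
               "obsclust_lookup_error")
    }
    coords <- coords[words, , drop = FALSE]
  }
  as.matrix(stats::dist(coords))
}

#' Row-wise Pearson correlations between two distance matrices
#'
#' For each shared word, the Pearson correlation between its row of
#' distances in the two matrices, excluding the self-distance entry (a
#' constant zero that would distort the correlation). Rows with zero
#' variance in either matrix yield `NA` with a warning.
#'
#' @param d_a,d_b Distance matrices with word dimnames sharing at least 3
#'   words.
#' @return Named numeric vector of per-word correlations over the shared
#'   words.
#' @export
rowwise_pearson <- function(d_a, d_b) {
  shared <- intersect(rownames(d_a), rownames(d_b))
  if (length(shared) < 3L) {
    obs_stop("need at least 3 shared words to correlate rows",
             "obsclust_input_error")
  }
  A <- d_a[shared, shared, drop = FALSE]
  B <- d_b[shared, shared, drop = FALSE]
  r <- stats::setNames(numeric(length(shared)), shared)
  degenerate <- character()
  for (i in seq_along(shared)) {
    a <- A[i, -i]
    b <- B[i, -i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      r[i] <- NA_real_
      degenerate <- c(degenerate, shared[i])
    } else {
      r[i] <- stats::cor(a, b)
    }
  }
  if (length(degenerate) > 0) {
    warning(sprintf("zero-variance distance rows, correlation undefined for: %s",
                    paste(utils::head(degenerate, 5), collapse = ", ")))
  }
  r
}

#' Summarise split-half stability
#'
#' @param per_word_r Named vector of per-word correlations (as from
#'   [rowwise_pearson()]); `NA`s are excluded from the summary.
#' @param threshold Correlation threshold (default 0.90) used for the
#'   "fraction above" summary.
#' @return An object of class `stability_report`: list with `per_word_r`,
#'   `n_words`, `fraction_above`, `median_r`, `threshold` and `stable`
#'   (`TRUE` when more than half the words reach the threshold).
#' @export
stability_summary <- function(per_word_r, threshold = 0.90) {
  if (length(per_word_r) == 0L) {
    obs_stop("empty correlation map", "obsclust_input_error")
  }
  ok <- per_word_r[!is.na(per_word_r)]
  fraction_above <- mean(ok >= threshold)
  structure(list(per_word_r = per_word_r,
                 n_words = length(ok),
                 fraction_above = fraction_above,
                 median_r = stats::median(ok),
                 threshold = threshold,
                 stable = fraction_above > 0.5),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d words; median r = %.3f; %.1f%% >= %.2f -> %s\n",
    x$n_words, x$median_r, 100 * x$fraction_above, x$threshold,
    if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Split-half stability of the full pipeline
#'
#' Splits the corpus, reruns the full pipeline (vocabulary selection through
#' co-occurrence, Mittens fine-tuning and PCA) independently per half,
#' computes the inter-word distance matrix of each half over the shared
#' post-filter analysis vocabulary, and summarises the per-word Pearson
#' correlations between the two matrices. A whole-matrix correlation over
#' the vectorised upper triangles is attached for reference.
#'
#' @param entries Entry `data.frame`.
#' @param pretrained Optional [embedding_table()] shared by both halves.
#' @param config A [pipeline_config()].
#' @param mode,balance_on,seed Passed to [split_sample()].
#' @param threshold Passed to [stability_summary()].
#' @return A `stability_report` with extra fields `shared_words`,
#'   `whole_matrix_r`, `split` (the `split_result`) and `words_only_in`
#'   (words unique to one half's analysis vocabulary).
#' @export
split_half_stability <- function(entries, pretrained = NULL,
                                 config = pipeline_config(),
                                 mode = "by_user", balance_on = "words",
                                 seed = 1, threshold = 0.90) {
  sp <- split_sample(entries, mode = mode, balance_on = balance_on,
                     seed = seed)
  run_half <- function(half) {
    run_pipeline(half, pretrained = pretrained, config = config,
                 choose_k = FALSE)
  }
  ra <- run_half(sp$half_a)
  rb <- run_half(sp$half_b)
  shared <- intersect(ra$analysis_words, rb$analysis_words)
  if (length(shared) < 3L) {
    obs_stop("fewer than 3 analysis words shared between halves",
             "obsclust_input_error")
  }
  da <- distance_matrix(ra$projection, shared)
  db <- distance_matrix(rb$projection, shared)
  r <- rowwise_pearson(da, db)
  rep <- stability_summary(r, threshold = threshold)
  ut <- upper.tri(da)
  rep$whole_matrix_r <- stats::cor(da[ut], db[ut])
  rep$shared_words <- shared
  rep$words_only_in <- list(
    a = setdiff(ra$analysis_words, shared),
    b = setdiff(rb$analysis_words, shared)
  )
  rep$split <- sp
  rep
}
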