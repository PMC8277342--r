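#' Per-cluster word and token frequency table
#'
#' For each cluster: the number of distinct analysis words assigned to it
#' and the total token count (sum of the words' corpus frequencies).
#'
#' @param labels Named vector mapping words to cluster ids (e.g. the
#'   `labels` of a `cluster_solution`).
#' @param vocab A [build_vocabulary()] result covering all labelled words.
#' @return An object of class `cluster_frequency_table`: `data.frame` with
#'   columns `cluster`, `unique_words`, `total_tokens`, plus attributes
#'   `total_unique` and `total_tokens`.
#' @export
cluster_frequency_table <- function(labels, vocab) {
  if (length(labels) == 0L) {
    out <- data.frame(cluster = integer(), unique_words = integer(),
                      total_tokens = integer())
  } else {
    words <- names(labels)
    miss <- setdiff(words, vocab$word)
    if (length(miss) > 0) {
      obs_stop(sprintf("labelled word absent from vocabulary: %s",
                       paste(utils::head(miss, 5), collapse = ", ")),
               "obsclust_lookup_error")
    }
    freq <- word_frequencies(vocab)[words]
    cl <- sort(unique(labels))
    out <- data.frame(
      cluster = cl,
      unique_words = vapply(cl, function(c) sum(labels == c), integer(1)),
      total_tokens = vapply(cl, function(c) as.integer(sum(freq[labels == c])),
                            integer(1))
    )
  }
  rownames(out) <- NULL
  attr(out, "total_unique") <- sum(out$unique_words)
  attr(out, "total_tokens") <- sum(out$total_tokens)
  class(out) <- c("cluster_frequency_table", "data.frame")
  out
}

#' Chi-square goodness-of-fit test against equal expected counts
#'
#' `statistic = sum((O - E)^2 / E)` with `E = total / c` for `c` categories,
#' `df = c - 1`, no continuity correction; the p-value comes from the upper
#' tail of the chi-square distribution. This is the test form that compares
#' relative word frequencies across clusters.
#'
#' @param counts Integer vector of nonnegative counts (>= 2 categories,
#'   positive total).
#' @return An object of class `chisq_result`: list with `statistic`, `df`,
#'   `p_value`.
#' @export
chisq_gof <- function(counts) {
  if (length(counts) < 2L || any(counts < 0) || anyNA(counts)) {
    obs_stop("`counts` must be >= 2 nonnegative values",
             "obsclust_input_error")
  }
  if (sum(counts) <= 0) {
    obs_stop("`counts` must have a positive total", "obsclust_input_error")
  }
  ht <- suppressWarnings(stats::chisq.test(counts))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pairwise chi-square comparisons between clusters
#'
#' For every cluster pair, a goodness-of-fit test of the two counts of the
#' chosen measure against equal expected frequencies, with
#' Bonferroni-adjusted p-values for the pairwise family.
#'
#' @param table A [cluster_frequency_table()].
#' @param measure `"unique"` (distinct words) or `"tokens"` (total token
#'   counts).
#' @return `data.frame` with one row per cluster pair: `cluster_a`,
#'   `cluster_b`, `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
pairwise_chisq <- function(table, measure = c("unique", "tokens")) {
  measure <- match.arg(measure)
  if (nrow(table) < 2L) {
    obs_stop("need at least 2 clusters for pairwise comparisons",
             "obsclust_input_error")
  }
  counts <- if (measure == "unique") table$unique_words else
    table$total_tokens
  pairs <- utils::combn(seq_len(nrow(table)), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]
    j <- pairs[2L, p]
    ht <- chisq_gof(c(counts[i], counts[j]))
    data.frame(cluster_a = table$cluster[i], cluster_b = table$cluster[j],
               statistic = ht$statistic, df = ht$df, p_value = ht$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  rownames(out) <- NULL
  out
}
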