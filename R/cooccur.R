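#' Build the phrase-level word co-occurrence matrix
#'
#' For each phrase, every unordered pair of distinct in-vocabulary words
#' present in the phrase increments both `X[i, j]` and `X[j, i]` by one —
#' i.e. co-occurrence is phrase co-membership, with no window or distance
#' weighting. By default duplicate tokens within a phrase count once per
#' pair per phrase (set semantics); with `distinct = FALSE` each pair of
#' token occurrences counts, i.e. `X[i, j]` gains `n_i * n_j` for token
#' multiplicities `n_i`, `n_j`. Out-of-vocabulary tokens are ignored, the
#' diagonal is zero, and the matrix is stored sparsely.
#'
#' @param phrases A [phrase_set()].
#' @param vocab A [build_vocabulary()] result (or character vector of words).
#' @param distinct If `TRUE` (default), deduplicate tokens within a phrase
#'   before pairing.
#' @return An object of class `cooccurrence`: list with `X` (sparse
#'   symmetric `dgCMatrix` with dimnames) and `words`.
#' @export
build_cooccurrence <- function(phrases, vocab, distinct = TRUE) {
  stopifnot(inherits(phrases, "phrase_set"))
  words <- if (is.character(vocab)) vocab else vocab$word
  if (length(words) == 0L) {
    obs_stop("vocabulary is empty", "obsclust_input_error")
  }
  n <- length(words)
  ii <- vector("list", length(phrases$tokens))
  jj <- vector("list", length(phrases$tokens))
  xx <- vector("list", length(phrases$tokens))
  for (p in seq_along(phrases$tokens)) {
    idx <- match(phrases$tokens[[p]], words)
    idx <- idx[!is.na(idx)]
    if (distinct) {
      u <- unique(idx)
      if (length(u) < 2L) next
      pr <- utils::combn(u, 2L)
      ii[[p]] <- pr[1L, ]
      jj[[p]] <- pr[2L, ]
      xx[[p]] <- rep.int(1, ncol(pr))
    } else {
      tab <- table(idx)
      u <- as.integer(names(tab))
      m <- as.numeric(tab)
      if (length(u) < 2L) next
      pr <- utils::combn(seq_along(u), 2L)
      ii[[p]] <- u[pr[1L, ]]
      jj[[p]] <- u[pr[2L, ]]
      xx[[p]] <- m[pr[1L, ]] * m[pr[2L, ]]
    }
  }
  i <- unlist(ii, use.names = FALSE)
  j <- unlist(jj, use.names = FALSE)
  x <- unlist(xx, use.names = FALSE)
  X <- if (length(i) == 0L) {
    Matrix::Matrix(0, n, n, sparse = TRUE, dimnames = list(words, words))
  } else {
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                         dims = c(n, n), dimnames = list(words, words))
  }
  structure(list(X = X, words = words), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  nz <- Matrix::nnzero(x$X)
  cat(sprintf("<cooccurrence> %d words, %d nonzero cells (%d pairs)\n",
              length(x$words), nz, nz %/% 2))
  invisible(x)
}

#' Read and write co-occurrence matrices as TSV
#'
#' The on-disk format is a three-column TSV `word_i`, `word_j`, `count`
#' holding the upper triangle (`i < j` in vocabulary order); the symmetric
#' matrix is reconstructed on read over the supplied word list.
#'
#' @param cooc A [build_cooccurrence()] result.
#' @param path File path.
#' @param words Character vector defining the vocabulary (row/column order)
#'   when reading.
#' @return `read_cooccurrence()` returns a `cooccurrence` object;
#'   `write_cooccurrence()` returns `path` invisibly.
#' @export
write_cooccurrence <- function(cooc, path) {
  stopifnot(inherits(cooc, "cooccurrence"))
  s <- as.data.frame(Matrix::summary(cooc$X))
  s <- s[s$i < s$j, , drop = FALSE]
  s <- s[order(s$i, s$j), , drop = FALSE]
  df <- data.frame(word_i = cooc$words[s$i], word_j = cooc$words[s$j],
                   count = s$x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path, words) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  i <- match(df$word_i, words)
  j <- match(df$word_j, words)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(df$word_i[is.na(i)], df$word_j[is.na(j)]))
    obs_stop(sprintf("co-occurrence file contains words absent from the vocabulary: %s",
                     paste(utils::head(bad, 5), collapse = ", ")),
             "obsclust_format_error")
  }
  n <- length(words)
  X <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(df$count, df$count),
                            dims = c(n, n), dimnames = list(words, words))
  structure(list(X = X, words = words), class = "cooccurrence")
}
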