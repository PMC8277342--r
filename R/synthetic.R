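#' Specification of a synthetic obsession-report corpus
#'
#' Describes a corpus of short free-text entries from many users, with a
#' small number of latent semantic themes, a shared "harm-like" core lexicon
#' creating central convergence, and a heavy-tailed entries-per-user
#' distribution (mode 1, roughly 95\% of users contributing at most five
#' entries, with rare extreme outliers). A matching synthetic "pretrained"
#' embedding table carries the planted theme geometry, so the whole
#' downstream pipeline can be exercised and validated without any real data.
#'
#' @param n_users Number of users contributing entries.
#' @param k_true Number of planted semantic themes.
#' @param theme_lexicon_size Words per theme lexicon.
#' @param shared_core_size Words in the shared core lexicon.
#' @param core_mix Probability in \[0, 1\] that any token is drawn from the
#'   shared core lexicon rather than the user's theme lexicon.
#' @param entries_per_user_probs Named probability vector over entry counts
#'   per user (names are the counts). The default places 67\% of users at a
#'   single entry, 95\% at five or fewer, and spreads the remainder over
#'   6--10, approximating the heavy-tailed histogram seen in app data.
#' @param outlier_rate Probability that a user is an extreme outlier whose
#'   entry count is drawn uniformly from `outlier_entries`.
#' @param outlier_entries Integer range `c(lo, hi)` of outlier entry counts.
#' @param phrase_len_probs Probability vector over obsession token counts
#'   1..8.
#' @param extra_field_prob Probability that each of the optional trigger /
#'   exposure / compulsion fields is present on an entry.
#' @param embed_dim Dimension of the synthetic pretrained vectors.
#' @param separation Pairwise Euclidean distance between planted theme
#'   centroids in embedding space.
#' @param noise_sd Standard deviation of the per-coordinate Gaussian noise
#'   added to each word's centroid.
#' @param time_range Character or POSIXct length-2 vector; entry timestamps
#'   are drawn uniformly over this interval so chronological splits are
#'   meaningful.
#' @param dirty If `TRUE`, tokens are decorated with random punctuation and
#'   casing to exercise the cleaning stage.
#' @param seed Integer RNG seed; identical specs yield identical corpora and
#'   embedding tables.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_corpus()], [generate_pretrained_embeddings()],
#'   [theme_lexicon()], [core_lexicon()]
#' @export
#' @examples
#' spec <- synthetic_spec(n_users = 200, seed = 42)
#' entries <- generate_corpus(spec)
#' head(entries)
synthetic_spec <- function(n_users = 2000,
                           k_true = 3,
                           theme_lexicon_size = 50,
                           shared_core_size = 25,
                           core_mix = 0.2,
                           entries_per_user_probs = c(
                             "1" = 0.67, "2" = 0.17, "3" = 0.07,
                             "4" = 0.03, "5" = 0.02,
                             "6" = 0.008, "7" = 0.008, "8" = 0.008,
                             "9" = 0.008, "10" = 0.008
                           ),
                           outlier_rate = 1e-4,
                           outlier_entries = c(100L, 200L),
                           phrase_len_probs = c(0.30, 0.25, 0.18, 0.12,
                                                0.08, 0.04, 0.02, 0.01),
                           extra_field_prob = 0.3,
                           embed_dim = 100,
                           separation = 10,
                           noise_sd = 0.5,
                           time_range = c("2018-01-01", "2020-01-01"),
                           dirty = FALSE,
                           seed = 1) {
  check_number(n_users, "n_users", lower = 1, integer = TRUE)
  check_number(k_true, "k_true", lower = 1, integer = TRUE)
  check_number(theme_lexicon_size, "theme_lexicon_size", lower = 1,
               integer = TRUE)
  check_number(shared_core_size, "shared_core_size", lower = 0,
               integer = TRUE)
  check_number(core_mix, "core_mix", lower = 0, upper = 1)
  check_prob_vector(entries_per_user_probs, "entries_per_user_probs")
  if (is.null(names(entries_per_user_probs))) {
    names(entries_per_user_probs) <- seq_along(entries_per_user_probs)
  }
  check_number(outlier_rate, "outlier_rate", lower = 0, upper = 1)
  check_prob_vector(phrase_len_probs, "phrase_len_probs")
  check_number(extra_field_prob, "extra_field_prob", lower = 0, upper = 1)
  check_number(embed_dim, "embed_dim", lower = 1, integer = TRUE)
  if (embed_dim < k_true) {
    obs_stop("`embed_dim` must be at least `k_true` to place theme centroids",
             "obsclust_param_error")
  }
  check_number(separation, "separation", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  tr <- as.POSIXct(time_range, tz = "UTC")
  if (length(tr) != 2L || anyNA(tr) || tr[1] >= tr[2]) {
    obs_stop("`time_range` must be two increasing timestamps",
             "obsclust_param_error")
  }
  structure(
    list(
      n_users = as.integer(n_users), k_true = as.integer(k_true),
      theme_lexicon_size = as.integer(theme_lexicon_size),
      shared_core_size = as.integer(shared_core_size),
      core_mix = core_mix,
      entries_per_user_probs = entries_per_user_probs,
      outlier_rate = outlier_rate,
      outlier_entries = as.integer(outlier_entries),
      phrase_len_probs = phrase_len_probs,
      extra_field_prob = extra_field_prob,
      embed_dim = as.integer(embed_dim),
      separation = separation, noise_sd = noise_sd,
      time_range = as.numeric(tr),
      dirty = isTRUE(dirty), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_spec> %d users, %d themes x %d words + %d core words\n",
           "  core_mix=%.2f, separation=%g, noise_sd=%g, dim=%d, seed=%d\n"),
    x$n_users, x$k_true, x$theme_lexicon_size, x$shared_core_size,
    x$core_mix, x$separation, x$noise_sd, x$embed_dim, x$seed
  ))
  invisible(x)
}

#' Planted lexicons of a synthetic spec
#'
#' `theme_lexicon()` returns the list of per-theme word lists;
#' `core_lexicon()` returns the shared core words. Tokens are lowercase
#' alphanumeric so they survive cleaning unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @return For `theme_lexicon()`, a list of `k_true` character vectors; for
#'   `core_lexicon()`, a character vector.
#' @export
theme_lexicon <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lapply(seq_len(spec$k_true), function(i) {
    sprintf("t%dw%03d", i, seq_len(spec$theme_lexicon_size))
  })
}

#' @rdname theme_lexicon
#' @export
core_lexicon <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$shared_core_size == 0L) return(character())
  sprintf("core%03d", seq_len(spec$shared_core_size))
}

# Decorate a clean token with punctuation/casing noise ("dirty mode").
dirty_token <- function(tok) {
  pre <- sample(c("", "", "", "(", "\"", "*"), length(tok), replace = TRUE)
  post <- sample(c("", "", "!", "!!!", ",", ".", ")", "?"), length(tok),
                 replace = TRUE)
  up <- runif(length(tok)) < 0.3
  tok[up] <- toupper(tok[up])
  paste0(pre, tok, post)
}

#' Generate a synthetic entry table
#'
#' Each user is assigned one latent theme; each of their entries carries an
#' obsession text (and, with probability `extra_field_prob` each, trigger /
#' exposure / compulsion texts) whose tokens are drawn from the shared core
#' lexicon with probability `core_mix` and from the user's theme lexicon
#' otherwise. Entry counts per user follow `entries_per_user_probs` with
#' rare outliers, and timestamps are uniform over `time_range`. Output is
#' deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return A `data.frame` with columns `user_id`, `timestamp` (numeric
#'   seconds since the epoch, sorted increasing), `obsession`, `trigger`,
#'   `exposure`, `compulsion` (optional fields are `NA` when absent) and
#'   `true_theme` (the planted theme label).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  themes <- theme_lexicon(spec)
  core <- core_lexicon(spec)
  if (spec$shared_core_size == 0L && spec$core_mix > 0) {
    obs_stop("core_mix > 0 requires a non-empty shared core lexicon",
             "obsclust_param_error")
  }

  with_seed(spec$seed, {
    user_theme <- sample.int(spec$k_true, spec$n_users, replace = TRUE)
    counts <- as.integer(names(spec$entries_per_user_probs))[
      sample.int(length(spec$entries_per_user_probs), spec$n_users,
                 replace = TRUE, prob = spec$entries_per_user_probs)
    ]
    is_outlier <- runif(spec$n_users) < spec$outlier_rate
    if (any(is_outlier)) {
      counts[is_outlier] <- sample(
        seq(spec$outlier_entries[1], spec$outlier_entries[2]),
        sum(is_outlier), replace = TRUE
      )
    }
    n_entries <- sum(counts)
    entry_user <- rep.int(seq_len(spec$n_users), counts)
    entry_theme <- user_theme[entry_user]

    draw_text <- function(theme_id, n_tokens) {
      from_core <- runif(n_tokens) < spec$core_mix
      tok <- character(n_tokens)
      n_core <- sum(from_core)
      if (n_core > 0) {
        tok[from_core] <- core[sample.int(length(core), n_core,
                                          replace = TRUE)]
      }
      if (n_core < n_tokens) {
        lex <- themes[[theme_id]]
        tok[!from_core] <- lex[sample.int(length(lex), n_tokens - n_core,
                                          replace = TRUE)]
      }
      paste(tok, collapse = " ")
    }

    lens <- sample.int(length(spec$phrase_len_probs), n_entries,
                       replace = TRUE, prob = spec$phrase_len_probs)
    obsession <- vapply(seq_len(n_entries),
                        function(i) draw_text(entry_theme[i], lens[i]),
                        character(1))
    optional_field <- function() {
      present <- runif(n_entries) < spec$extra_field_prob
      out <- rep(NA_character_, n_entries)
      if (any(present)) {
        k <- sample.int(3L, sum(present), replace = TRUE)
        idx <- which(present)
        out[idx] <- vapply(seq_along(idx),
                           function(j) draw_text(entry_theme[idx[j]], k[j]),
                           character(1))
      }
      out
    }
    trigger <- optional_field()
    exposure <- optional_field()
    compulsion <- optional_field()
    timestamp <- runif(n_entries, spec$time_range[1], spec$time_range[2])

    if (spec$dirty) {
      # decorate texts after all structural draws so a dirty corpus is the
      # clean corpus with surface noise added
      dirty_field <- function(v) {
        ok <- !is.na(v)
        v[ok] <- vapply(strsplit(v[ok], " ", fixed = TRUE), function(t) {
          paste(dirty_token(t), collapse = " ")
        }, character(1))
        v
      }
      obsession <- dirty_field(obsession)
      trigger <- dirty_field(trigger)
      exposure <- dirty_field(exposure)
      compulsion <- dirty_field(compulsion)
    }

    out <- data.frame(
      user_id = sprintf("u%05d", entry_user),
      timestamp = timestamp,
      obsession = obsession,
      trigger = trigger,
      exposure = exposure,
      compulsion = compulsion,
      true_theme = entry_theme,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$timestamp), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic "pretrained" embedding table
#'
#' Theme centroids are placed on orthogonal axes at pairwise Euclidean
#' distance `separation`; each theme word's vector is its theme centroid
#' plus per-coordinate Gaussian noise `noise_sd`, and each shared-core
#' word's vector is the mean of the theme centroids plus the same noise.
#' This stands in for a large general-purpose pretrained vector table while
#' carrying a known, recoverable theme geometry.
#'
#' @param spec A [synthetic_spec()].
#' @return An [embedding_table()] over the full planted lexicon, with an
#'   attribute `"true_theme"` (named integer vector; `NA` for core words).
#' @export
generate_pretrained_embeddings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  themes <- theme_lexicon(spec)
  core <- core_lexicon(spec)
  d <- spec$embed_dim
  # Orthogonal placement: centroid i = (separation / sqrt(2)) * e_i gives
  # exact pairwise distance `separation`.
  centroids <- matrix(0, spec$k_true, d)
  for (i in seq_len(spec$k_true)) {
    centroids[i, i] <- spec$separation / sqrt(2)
  }
  core_centroid <- colMeans(centroids)

  words <- c(unlist(themes), core)
  theme_of <- c(rep(seq_len(spec$k_true), each = spec$theme_lexicon_size),
                rep(NA_integer_, length(core)))
  with_seed(spec$seed, {
    mu <- rbind(centroids[theme_of[seq_along(unlist(themes))], , drop = FALSE],
                matrix(core_centroid, length(core), d, byrow = TRUE))
    noise <- matrix(stats::rnorm(length(words) * d, 0, spec$noise_sd),
                    length(words), d)
    vec <- mu + noise
    rownames(vec) <- words
    tab <- embedding_table(vec)
    attr(tab, "true_theme") <- stats::setNames(theme_of, words)
    tab
  })
}
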