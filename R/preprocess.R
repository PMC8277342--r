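#' Remove users contributing an extreme number of entries
#'
#' Users whose total entry count exceeds `max_entries` are dropped entirely
#' (both of the extreme outliers in typical app data contributed over 100
#' entries each); all other entries are preserved in their original order.
#'
#' @param entries Entry `data.frame` with at least a `user_id` column.
#' @param max_entries Maximum entries a user may contribute (default 100).
#' @return The filtered entry `data.frame`.
#' @export
remove_outlier_users <- function(entries, max_entries = 100) {
  check_number(max_entries, "max_entries", lower = 1, integer = TRUE)
  counts <- table(entries$user_id)
  keep <- entries$user_id %in% names(counts)[counts <= max_entries]
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Clean a character vector of raw texts into a list of token vectors:
# lowercase, split on any non-alphanumeric character, drop empties.
clean_tokens <- function(texts) {
  texts[is.na(texts)] <- ""
  toks <- strsplit(tolower(texts), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Assemble cleaned phrases from raw entries
#'
#' Per entry, the obsession text and any trigger / exposure / compulsion
#' texts are concatenated into a single phrase, lowercased, and split on any
#' non-alphanumeric character (so punctuation, special characters and
#' hyphens act as separators). An optional spelling-correction map is then
#' applied token-wise. Entries whose phrase ends up empty are dropped.
#'
#' @param entries Entry `data.frame` with columns `user_id`, `timestamp`,
#'   `obsession` and optionally `trigger`, `exposure`, `compulsion`.
#' @param corrections Optional named character vector mapping misspelled
#'   tokens to replacements (e.g. `c(germz = "germs")`).
#' @return A `phrase_set`: list with parallel elements `tokens` (list of
#'   character vectors), `user_id`, and `timestamp`.
#' @export
assemble_phrases <- function(entries, corrections = NULL) {
  field <- function(nm) {
    if (nm %in% names(entries)) as.character(entries[[nm]]) else
      rep(NA_character_, nrow(entries))
  }
  raw <- paste(
    ifelse(is.na(field("obsession")), "", field("obsession")),
    ifelse(is.na(field("trigger")), "", field("trigger")),
    ifelse(is.na(field("exposure")), "", field("exposure")),
    ifelse(is.na(field("compulsion")), "", field("compulsion"))
  )
  toks <- clean_tokens(raw)
  if (!is.null(corrections)) {
    stopifnot(is.character(corrections), !is.null(names(corrections)))
    toks <- lapply(toks, function(t) {
      hit <- t %in% names(corrections)
      t[hit] <- unname(corrections[t[hit]])
      t
    })
  }
  keep <- lengths(toks) > 0
  phrase_set(tokens = toks[keep],
             user_id = as.character(entries$user_id)[keep],
             timestamp = as.numeric(entries$timestamp)[keep])
}

#' Construct a phrase set
#'
#' A `phrase_set` holds cleaned phrases columnar-style: a list of token
#' vectors plus parallel user ids and timestamps.
#'
#' @param tokens List of character vectors (no empty tokens).
#' @param user_id Character vector, one per phrase.
#' @param timestamp Numeric vector, one per phrase.
#' @return An object of class `phrase_set`.
#' @export
phrase_set <- function(tokens, user_id = rep(NA_character_, length(tokens)),
                       timestamp = rep(NA_real_, length(tokens))) {
  stopifnot(is.list(tokens), length(user_id) == length(tokens),
            length(timestamp) == length(tokens))
  structure(list(tokens = tokens, user_id = as.character(user_id),
                 timestamp = as.numeric(timestamp)),
            class = "phrase_set")
}

#' @export
length.phrase_set <- function(x) length(x$tokens)

#' @export
print.phrase_set <- function(x, ...) {
  cat(sprintf("<phrase_set> %d phrases, %d tokens\n",
              length(x), sum(lengths(x$tokens))))
  invisible(x)
}

#' Lemmatize the tokens of a phrase set
#'
#' Each token is replaced by its lemma under a pluggable lemmatizer;
#' phrase structure (order, user, timestamp) is preserved. The default is a
#' bundled lookup table with identity fallback, so the operation is total
#' and idempotent.
#'
#' @param phrases A [phrase_set()].
#' @param lemmatizer Vectorised function mapping a character vector of
#'   tokens to lemmas; see [lookup_lemmatizer()].
#' @return A [phrase_set()] with lemmatized tokens.
#' @export
lemmatize <- function(phrases, lemmatizer = lookup_lemmatizer()) {
  stopifnot(inherits(phrases, "phrase_set"), is.function(lemmatizer))
  phrase_set(tokens = lapply(phrases$tokens, lemmatizer),
             user_id = phrases$user_id, timestamp = phrases$timestamp)
}

#' Build a frequency-ranked vocabulary
#'
#' Frequencies count token occurrences across all phrases (not per-user
#' document frequency). Words are ranked by descending frequency with
#' lexicographic tie-break, and assigned 0-based indices in that order.
#'
#' @param phrases A [phrase_set()].
#' @return An object of class `vocabulary`: a `data.frame` with columns
#'   `word`, `frequency`, `index` (0-based rank order).
#' @export
build_vocabulary <- function(phrases) {
  stopifnot(inherits(phrases, "phrase_set"))
  all_tokens <- unlist(phrases$tokens, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    obs_stop("cannot build a vocabulary from an empty corpus",
             "obsclust_input_error")
  }
  tab <- table(all_tokens)
  df <- data.frame(word = names(tab), frequency = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$word), , drop = FALSE]
  df$index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  class(df) <- c("vocabulary", "data.frame")
  df
}

#' Vocabulary accessors
#'
#' @param vocab A [build_vocabulary()] result.
#' @return `vocab_size()` returns the number of distinct words;
#'   `word_frequencies()` a named integer vector of token counts.
#' @export
vocab_size <- function(vocab) nrow(vocab)

#' @rdname vocab_size
#' @export
word_frequencies <- function(vocab) {
  stats::setNames(vocab$frequency, vocab$word)
}

#' Select the most frequent fraction of the vocabulary
#'
#' Returns the first `ceiling(fraction * N)` words in vocabulary rank order
#' (descending frequency, lexicographic tie-break). The reference analysis
#' keeps the top 7\% of words, which balances coverage of common words
#' against plot legibility.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param fraction Proportion in (0, 1].
#' @return Character vector of selected words, most frequent first.
#' @export
select_top_fraction <- function(vocab, fraction = 0.07) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    obs_stop("`fraction` must be in (0, 1]", "obsclust_param_error")
  }
  # tolerance guards float artefacts such as 0.07 * 100 = 7.000000000000001
  n <- ceiling(fraction * vocab_size(vocab) - 1e-9)
  n <- max(1L, min(vocab_size(vocab), as.integer(n)))
  vocab$word[seq_len(n)]
}

#' Filter words by part of speech
#'
#' Words whose tag falls in `excluded_tags` are removed, preserving order.
#' The default exclusions mirror the standard curation of a symptom
#' vocabulary: adverbs, modals, third-person singular present verbs,
#' gerunds, past participles, "to", prepositions / subordinating
#' conjunctions, and personal pronouns.
#'
#' @param words Character vector.
#' @param tagger Vectorised word -> Penn Treebank tag function; see
#'   [lookup_tagger()].
#' @param excluded_tags Character vector of tags to drop.
#' @return Filtered character vector.
#' @export
pos_filter <- function(words, tagger = lookup_tagger(),
                       excluded_tags = default_excluded_tags()) {
  stopifnot(is.character(words), is.function(tagger))
  if (length(words) == 0L) return(words)
  tags <- tagger(words)
  words[!(tags %in% excluded_tags)]
}

#' Apply a reviewed exclusion list
#'
#' Removes words found in `stoplist`, preserving order. This models the
#' manual curation step in which non-clinically-relevant words are struck
#' from the analysis vocabulary; keeping the list as data makes the step
#' reproducible and versionable.
#'
#' @param words Character vector.
#' @param stoplist Character vector of words to remove.
#' @return Filtered character vector.
#' @export
apply_exclusion_list <- function(words, stoplist = character()) {
  words[!(words %in% stoplist)]
}
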