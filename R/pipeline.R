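#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults mirror the
#' reference analysis of app-collected obsession reports: users contributing
#' more than 100 entries are dropped, the top 7\% of the lemmatized
#' vocabulary is kept, adverb/modal/gerund/participle/preposition/pronoun
#' tags are excluded, and fine-tuning uses the standard GloVe/Mittens
#' hyperparameters.
#'
#' @param top_fraction Fraction of the frequency-ranked vocabulary retained.
#' @param max_user_entries Outlier cutoff on entries per user.
#' @param corrections Optional named character vector of spelling
#'   corrections applied token-wise.
#' @param stoplist Character vector of reviewed exclusions removed from the
#'   analysis vocabulary.
#' @param excluded_tags Penn Treebank tags removed by the POS filter.
#' @param lemmatizer,tagger Pluggable token functions; see
#'   [lookup_lemmatizer()] and [lookup_tagger()].
#' @param embed An [embed_config()].
#' @param k_range Candidate cluster numbers for [select_k()].
#' @param n_init k-means++ restarts per `k`.
#' @param n_components Number of principal components used for clustering
#'   and distances (2 reproduces the "cluster what you plot" convention;
#'   set to the embedding dimension to cluster in full space).
#' @param seed Integer seed for the clustering stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(top_fraction = 0.07,
                            max_user_entries = 100,
                            corrections = NULL,
                            stoplist = character(),
                            excluded_tags = default_excluded_tags(),
                            lemmatizer = lookup_lemmatizer(),
                            tagger = lookup_tagger(),
                            embed = embed_config(),
                            k_range = 2:8,
                            n_init = 10,
                            n_components = 2,
                            seed = 1) {
  structure(list(top_fraction = top_fraction,
                 max_user_entries = max_user_entries,
                 corrections = corrections, stoplist = stoplist,
                 excluded_tags = excluded_tags, lemmatizer = lemmatizer,
                 tagger = tagger, embed = embed, k_range = k_range,
                 n_init = n_init, n_components = n_components,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Pipeline configuration for synthetic validation corpora
#'
#' The synthetic generator emits a small, already-curated lexicon, so the
#' study configuration keeps the whole frequency-ranked vocabulary
#' (`top_fraction = 1`) and supplies the generator's shared-core lexicon as
#' the reviewed exclusion list: the core words are ubiquitous,
#' theme-uninformative tokens by construction (they sit at the mean of the
#' theme centroids), and retaining them would add a genuine central cluster
#' on top of the planted themes, changing the question being validated from
#' "are the planted subtypes recovered?" to "is the core detected as its own
#' group?". Mittens runs for 200 epochs at this vocabulary size; all other
#' settings are the package defaults.
#'
#' @param spec The [synthetic_spec()] the corpus was generated from.
#' @param seed Seed for fine-tuning initialisation and clustering.
#' @param n_epochs Full-batch AdaGrad epochs (default 200).
#' @param ... Further arguments passed to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
synthetic_pipeline_config <- function(spec, seed = 1, n_epochs = 200, ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pipeline_config(
    top_fraction = 1,
    stoplist = core_lexicon(spec),
    embed = embed_config(dim = spec$embed_dim, n_epochs = n_epochs,
                         seed = seed),
    seed = seed,
    ...
  )
}

#' Run the full semantic-subtyping pipeline
#'
#' Stages, in order: outlier-user removal, phrase assembly and cleaning,
#' lemmatization, vocabulary construction, co-occurrence matrix over the
#' full vocabulary, GloVe/Mittens fine-tuning, analysis-vocabulary selection
#' (top fraction, POS filter, exclusion list), projection onto principal
#' components and, optionally, cluster-number selection with k-means.
#'
#' @param entries Entry `data.frame` (see [generate_corpus()] /
#'   [read_entries()] for the expected columns).
#' @param pretrained Optional [embedding_table()] of pretrained vectors
#'   covering any subset of the vocabulary.
#' @param config A [pipeline_config()].
#' @param choose_k If `FALSE`, stop after the projection (used by the
#'   split-half stability analysis).
#' @return An object of class `pipeline_result`: list with `vocab`,
#'   `analysis_words`, `cooccurrence`, `embeddings`, `projection`,
#'   `validity` (a `validity_report`, or `NULL`), `clusters` (the
#'   `cluster_solution` at the consensus k, or `NULL`), `frequency_table`
#'   and `config`.
#' @export
run_pipeline <- function(entries, pretrained = NULL,
                         config = pipeline_config(), choose_k = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  entries <- remove_outlier_users(entries, config$max_user_entries)
  phrases <- assemble_phrases(entries, config$corrections)
  phrases <- lemmatize(phrases, config$lemmatizer)
  vocab <- build_vocabulary(phrases)
  cooc <- build_cooccurrence(phrases, vocab)
  emb <- fit_mittens(cooc, pretrained, config$embed)

  words <- select_top_fraction(vocab, config$top_fraction)
  words <- pos_filter(words, config$tagger, config$excluded_tags)
  words <- apply_exclusion_list(words, config$stoplist)
  if (length(words) < config$n_components + 1) {
    obs_stop("analysis vocabulary too small after filtering",
             "obsclust_input_error")
  }
  proj <- pca_project(subset_embedding(emb, words), config$n_components)

  validity <- NULL
  clusters <- NULL
  freq_tab <- NULL
  if (choose_k) {
    k_range <- config$k_range
    k_range <- k_range[k_range <= length(words) - 1L]
    validity <- select_k(proj, k_range = k_range, seed = config$seed,
                         n_init = config$n_init)
    clusters <- validity$solutions[[as.character(validity$consensus_k)]]
    freq_tab <- cluster_frequency_table(clusters$labels, vocab)
  }
  structure(list(entries = entries, vocab = vocab, analysis_words = words,
                 cooccurrence = cooc, embeddings = emb, projection = proj,
                 validity = validity, clusters = clusters,
                 frequency_table = freq_tab, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d entries, %d-word vocabulary, %d analysis words\n",
    nrow(x$entries), vocab_size(x$vocab), length(x$analysis_words)))
  if (!is.null(x$validity)) {
    cat(sprintf("consensus k = %d (silhouette=%d, CH=%d, DB=%d, elbow=%d)\n",
                x$validity$consensus_k,
                x$validity$selected_k$silhouette,
                x$validity$selected_k$calinski_harabasz,
                x$validity$selected_k$davies_bouldin,
                x$validity$selected_k$elbow))
  }
  invisible(x)
}

#' Per-word results table
#'
#' One row per analysis word: corpus frequency, the two principal-component
#' coordinates, and (when clustering was run) the cluster label at the
#' consensus k.
#'
#' @param result A [run_pipeline()] result.
#' @return A `data.frame` with columns `word`, `frequency`, `PC1`, `PC2`,
#'   ... and `cluster`.
#' @export
results_table <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  words <- result$analysis_words
  coords <- result$projection$coords[words, , drop = FALSE]
  out <- data.frame(word = words,
                    frequency = unname(word_frequencies(result$vocab)[words]),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(coords))) out[[paste0("PC", j)]] <- coords[, j]
  out$cluster <- if (!is.null(result$clusters)) {
    unname(result$clusters$labels[words])
  } else {
    NA_integer_
  }
  out
}
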