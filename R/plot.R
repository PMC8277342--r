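#' Word-cluster scatter plot
#'
#' Plots analysis words at their two principal-component coordinates,
#' coloured by cluster, with label size scaled by the square root of corpus
#' frequency (so common words dominate visually, as in the standard
#' presentation of embedded symptom vocabularies).
#'
#' @param result A [run_pipeline()] result that includes clustering.
#' @param max_size Largest label size.
#' @return A `ggplot` object.
#' @export
plot_clusters <- function(result, max_size = 6) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    obs_stop("plot_clusters() requires the ggplot2 package",
             "obsclust_param_error")
  }
  df <- results_table(result)
  if (all(is.na(df$cluster))) {
    obs_stop("pipeline result has no clustering; rerun with choose_k = TRUE",
             "obsclust_param_error")
  }
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2, label = word,
                                   colour = cluster,
                                   size = sqrt(frequency))) +
    ggplot2::geom_text(show.legend = c(size = FALSE)) +
    ggplot2::scale_size_continuous(range = c(2, max_size), guide = "none") +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster") +
    ggplot2::theme_minimal()
}
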