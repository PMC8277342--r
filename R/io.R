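#' Read and write entry tables
#'
#' Entry tables are exchanged as CSV or JSON-lines with columns `user_id`,
#' `timestamp` (numeric seconds), `obsession`, `trigger`, `exposure`,
#' `compulsion`, and optionally `true_theme` (synthetic data only). Missing
#' optional texts are empty/`NA`.
#'
#' @param entries Entry `data.frame`.
#' @param path File path; format inferred from the extension (`.csv` or
#'   `.jsonl`) unless given explicitly.
#' @param format `"csv"` or `"jsonl"`.
#' @return `read_entries()` returns the entry `data.frame`;
#'   `write_entries()` returns `path` invisibly.
#' @export
write_entries <- function(entries, path,
                          format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl"
    else "csv"
  }
  if (format == "csv") {
    utils::write.csv(entries, path, row.names = FALSE, na = "")
  } else {
    lines <- vapply(seq_len(nrow(entries)), function(i) {
      jsonlite::toJSON(as.list(entries[i, , drop = FALSE]),
                       auto_unbox = TRUE, na = "null", digits = NA)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_entries
#' @export
read_entries <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl"
    else "csv"
  }
  if (format == "csv") {
    out <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(user_id = "character"))
    for (col in c("obsession", "trigger", "exposure", "compulsion")) {
      if (col %in% names(out)) {
        out[[col]] <- as.character(out[[col]])
        out[[col]][!nzchar(out[[col]]) | is.na(out[[col]])] <- NA_character_
      }
    }
  } else {
    rows <- lapply(readLines(path), function(l) {
      v <- jsonlite::fromJSON(l)
      v[vapply(v, is.null, logical(1))] <- NA
      as.data.frame(v, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  if (!all(c("user_id", "timestamp", "obsession") %in% names(out))) {
    obs_stop("entry file must have user_id, timestamp and obsession columns",
             "obsclust_format_error")
  }
  out$timestamp <- as.numeric(out$timestamp)
  out
}

#' Read and write vocabularies as TSV
#'
#' Columns `word`, `frequency`, `index` (0-based rank order).
#'
#' @param vocab A [build_vocabulary()] result.
#' @param path File path.
#' @return `read_vocabulary()` returns a `vocabulary`; `write_vocabulary()`
#'   returns `path` invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(as.data.frame(vocab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer"))
  class(df) <- c("vocabulary", "data.frame")
  df
}

#' Write an analysis report as JSON
#'
#' Serialises a `validity_report` or `stability_report` (dropping bulky
#' components such as stored cluster solutions) for downstream consumption.
#'
#' @param report A `validity_report` or `stability_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- if (inherits(report, "validity_report")) {
    list(metrics = report$metrics,
         selected_k = report$selected_k,
         consensus_k = report$consensus_k,
         weak_structure = report$weak_structure)
  } else if (inherits(report, "stability_report")) {
    list(n_words = report$n_words,
         median_r = report$median_r,
         fraction_above = report$fraction_above,
         threshold = report$threshold,
         stable = report$stable,
         whole_matrix_r = report$whole_matrix_r,
         per_word_r = as.list(report$per_word_r))
  } else {
    obs_stop("unsupported report type", "obsclust_param_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
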