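# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    obs_stop("`seed` must be a single finite number", "obsclust_param_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

obs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "obsclust_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, class = "obsclust_param_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    obs_stop(sprintf("`%s` must be a single finite number", name), class)
  }
  if (x < lower || x > upper) {
    obs_stop(sprintf("`%s` must be in [%s, %s], got %s",
                     name, format(lower), format(upper), format(x)), class)
  }
  if (integer && x != round(x)) {
    obs_stop(sprintf("`%s` must be a whole number, got %s", name, format(x)),
             class)
  }
  invisible(x)
}

check_prob_vector <- function(p, name, class = "obsclust_param_error") {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0)) {
    obs_stop(sprintf("`%s` must be a nonnegative probability vector", name),
             class)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    obs_stop(sprintf("`%s` must sum to 1 (got %.8f)", name, sum(p)), class)
  }
  invisible(p)
}

# Mode of an integer-valued vector with ties broken toward the smallest value.
mode_smallest <- function(x) {
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  counts <- vapply(ux, function(u) sum(x == u), numeric(1))
  ux[which.max(counts)]
}
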