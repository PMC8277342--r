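test_that("glove weighting caps at one and vanishes at zero", {
  expect_equal(glove_weight(100, 100, 0.75), 1)
  expect_equal(glove_weight(250, 100, 0.75), 1)
  expect_equal(glove_weight(0, 100, 0.75), 0)
  expect_equal(glove_weight(1, 100, 0.75), 100^(-0.75), tolerance = 1e-12)
  expect_equal(glove_weight(1, 100, 0.75), 0.0316227766, tolerance = 1e-9)
})

test_that("loss is zero at a perfect fit and matches a hand computation", {
  words <- c("w1", "w2")
  x12 <- 7
  X <- cooc_from_matrix(matrix(c(0, x12, x12, 0), 2, 2), words)
  st <- zero_state(words, 2)
  st$b[] <- log(x12) / 2
  st$bt[] <- log(x12) / 2
  cfg <- embed_config(dim = 2, mu = 0)
  expect_equal(mittens_loss(st, X, cfg), 0, tolerance = 1e-14)

  # all-zero parameters, mu = 0.1: glove term is 2 * f(e) * (log e)^2 =
  # 2 * f(e), penalty term is mu * sum ||r||^2
  Xe <- cooc_from_matrix(matrix(c(0, exp(1), exp(1), 0), 2, 2), words)
  st0 <- zero_state(words, 2)
  st0$pretrained <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE,
                           dimnames = list(words, NULL))
  cfg01 <- embed_config(dim = 2, mu = 0.1)
  expect_equal(mittens_loss(st0, Xe, cfg01),
               2 * (exp(1) / 100)^0.75 + 0.1 * (1 + 4 + 9 + 16),
               tolerance = 1e-12)
})

test_that("with mu = 0 the loss reduces to the plain GloVe objective", {
  words <- sprintf("w%d", 1:6)
  X <- random_cooc(words, seed = 31)
  st <- random_state(words, 4, seed = 32)
  cfg <- embed_config(dim = 4, mu = 0)
  expect_equal(mittens_loss(st, X, cfg),
               naive_mittens_loss(st, as.matrix(X$X), mu = 0),
               tolerance = 1e-10)
})

test_that("loss with penalty matches the naive textbook evaluation", {
  words <- sprintf("w%d", 1:5)
  X <- random_cooc(words, seed = 41)
  pre <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(words, NULL))
  st <- random_state(words, 3, seed = 42, pretrained = pre)
  cfg <- embed_config(dim = 3, mu = 0.7)
  expect_equal(mittens_loss(st, X, cfg),
               naive_mittens_loss(st, as.matrix(X$X), mu = 0.7),
               tolerance = 1e-10)
})

test_that("loss is invariant to vocabulary reordering", {
  words <- sprintf("w%d", 1:6)
  X <- random_cooc(words, seed = 51)
  pre <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(words, NULL))
  st <- random_state(words, 3, seed = 52, pretrained = pre)
  cfg <- embed_config(dim = 3, mu = 0.5)
  perm <- c(4, 1, 6, 2, 5, 3)
  Xp <- cooc_from_matrix(as.matrix(X$X)[perm, perm], words[perm])
  stp <- list(W = st$W[perm, ], Wt = st$Wt[perm, ], b = st$b[perm],
              bt = st$bt[perm], pretrained = pre[perm, ])
  expect_equal(mittens_loss(stp, Xp, cfg), mittens_loss(st, X, cfg),
               tolerance = 1e-10)
})

test_that("nonfinite parameters raise a numeric error", {
  words <- c("w1", "w2")
  X <- cooc_from_matrix(matrix(c(0, 1, 1, 0), 2), words)
  st <- zero_state(words, 2)
  st$W[1, 1] <- NaN
  expect_error(mittens_loss(st, X, embed_config(dim = 2)),
               class = "obsclust_numeric_error")
})

test_that("analytic gradients match central finite differences", {
  words <- sprintf("w%d", 1:5)
  X <- random_cooc(words, seed = 61)
  pre <- matrix(rnorm(3 * 3), 3, 3, dimnames = list(words[c(1, 3, 5)], NULL))
  st <- random_state(words, 3, seed = 62, pretrained = pre)
  for (pen in c("sum", "w")) {
    cfg <- embed_config(dim = 3, mu = 0.4, penalize = pen)
    g <- mittens_gradients(st, X, cfg)
    h <- 1e-5
    fd_check <- function(field) {
      arr <- st[[field]]
      fd <- array(0, dim = if (is.null(dim(arr))) length(arr) else dim(arr))
      for (idx in seq_along(arr)) {
        stp <- st
        stm <- st
        stp[[field]][idx] <- arr[idx] + h
        stm[[field]][idx] <- arr[idx] - h
        fd[idx] <- (mittens_loss(stp, X, cfg) - mittens_loss(stm, X, cfg)) /
          (2 * h)
      }
      rel <- max(abs(fd - as.numeric(g[[field]]))) /
        max(1, max(abs(g[[field]])))
      expect_lt(rel, 1e-4)
    }
    for (field in c("W", "Wt", "b", "bt")) fd_check(field)
  }
})

test_that("mu = 0 fit reproduces an independently coded plain-GloVe loop", {
  words <- sprintf("w%d", 1:5)
  X <- random_cooc(words, seed = 71, density = 0.8)
  cfg <- embed_config(dim = 3, mu = 0, learning_rate = 0.05, n_epochs = 50,
                      seed = 5)
  fit <- fit_mittens(X, pretrained = NULL, cfg = cfg)
  ref <- reference_glove_fit(as.matrix(X$X), d = 3, n_epochs = 50,
                             lr = 0.05, seed = 5)
  expect_equal(unname(fit$vectors), ref, tolerance = 1e-10)
})

test_that("an overwhelming penalty pins the fit to the pretrained vectors", {
  words <- sprintf("w%d", 1:5)
  X <- random_cooc(words, seed = 81, density = 0.8)
  pre <- embedding_table(matrix(rnorm(5 * 3), 5, 3,
                                dimnames = list(words, NULL)))
  cfg <- embed_config(dim = 3, mu = 1e6, n_epochs = 10)
  fit <- fit_mittens(X, pre, cfg)
  dev <- sqrt(rowSums((fit$vectors - pre$vectors[words, ])^2))
  expect_lt(max(dev), 1e-2)
})

test_that("training reduces the loss on a toy problem", {
  words <- sprintf("w%d", 1:5)
  X <- random_cooc(words, seed = 91, density = 0.8)
  cfg <- embed_config(dim = 3, mu = 0, learning_rate = 0.05, n_epochs = 50,
                      seed = 2)
  fit <- fit_mittens(X, NULL, cfg, trace = TRUE)
  losses <- attr(fit, "loss")
  expect_lt(losses[50], losses[1])
})

test_that("deviation from pretrained vectors is non-increasing in mu", {
  words <- sprintf("w%d", 1:6)
  X <- random_cooc(words, seed = 101, density = 0.8)
  pre <- embedding_table(matrix(rnorm(6 * 3, sd = 2), 6, 3,
                                dimnames = list(words, NULL)))
  devs <- sapply(c(0, 0.1, 1, 10, 100), function(mu) {
    cfg <- embed_config(dim = 3, mu = mu, n_epochs = 100, seed = 3)
    fit <- fit_mittens(X, pre, cfg)
    sum((fit$vectors - pre$vectors[words, ])^2)
  })
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("words without pretrained vectors still train to finite vectors", {
  words <- sprintf("w%d", 1:6)
  X <- random_cooc(words, seed = 111, density = 0.9)
  pre <- embedding_table(matrix(rnorm(3 * 3), 3, 3,
                                dimnames = list(words[1:3], NULL)))
  cfg <- embed_config(dim = 3, mu = 0.5, n_epochs = 40, seed = 4)
  fit <- fit_mittens(X, pre, cfg)
  expect_true(all(is.finite(fit$vectors)))
  expect_setequal(fit$words, words)
  # penalty counts only the covered subset
  st <- zero_state(words, 3)
  st$pretrained <- pre$vectors
  expect_equal(mittens_loss(st, X, embed_config(dim = 3, mu = 1)),
               naive_mittens_loss(st, as.matrix(X$X), mu = 1),
               tolerance = 1e-10)
})

test_that("dimension mismatch with the pretrained table is a config error", {
  words <- c("w1", "w2")
  X <- cooc_from_matrix(matrix(c(0, 2, 2, 0), 2), words)
  pre <- embedding_table(matrix(0, 2, 4, dimnames = list(words, NULL)))
  expect_error(fit_mittens(X, pre, embed_config(dim = 3)),
               class = "obsclust_config_error")
})

test_that("vector files round-trip and reject malformed lines", {
  tab <- embedding_table(matrix(rnorm(9), 3, 3,
                                dimnames = list(c("cat", "dog", "rat"), NULL)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_vectors(tab, path)
  back <- read_vectors(path)
  expect_equal(back$vectors[tab$words, ], tab$vectors, tolerance = 1e-8)

  # vocabulary restriction
  two <- read_vectors(path, words = c("dog", "rat"))
  expect_setequal(two$words, c("dog", "rat"))

  # malformed line reported with its number
  lines <- readLines(path)
  lines[2] <- "cat 0.1 0.2"
  writeLines(lines, path)
  err <- tryCatch(read_vectors(path), error = function(e) e)
  expect_s3_class(err, "obsclust_format_error")
  expect_match(conditionMessage(err), "line 2")
})
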