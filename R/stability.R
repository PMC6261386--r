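#' Fit behavioral linguistic traits end to end from a message corpus
#'
#' Convenience pipeline: tokenize, build vocabulary, build the standardized
#' user-term matrix, fit the ML factor model, rotate. Filtering is left to
#' [filter_users()] so the pipeline composes with the pipe.
#'
#' @param corpus Message tibble.
#' @param k Number of factors (5 is the headline configuration; 3, 10 and 30
#'   are the documented comparison presets).
#' @param top_k Vocabulary size (`NULL`: all non-stopword terms).
#' @param rotation `"promax"`, `"varimax"`, `"equamax"`, or `"none"`.
#' @param stopwords Stopword list.
#' @param transform Cell statistic, see [build_user_term_matrix()].
#' @param seed Seed recorded in the model.
#' @param ... Passed to [fit_factor_analysis()].
#' @return A rotated `factor_model` (scores for the fitting users in
#'   `$scores`).
#' @export
induce_traits <- function(corpus, k = 5, top_k = NULL,
                          rotation = c("promax", "varimax", "equamax", "none"),
                          stopwords = wt_stopwords(),
                          transform = "relfreq", seed = 1L, ...) {
  rotation <- match.arg(rotation)
  corpus <- with_tokens(corpus)
  if (is.null(top_k))
    top_k <- length(setdiff(unique(unlist(corpus$tokens, use.names = FALSE)),
                            stopwords))
  vocab <- build_vocabulary(corpus, top_k = top_k, stopwords = stopwords)
  utm <- build_user_term_matrix(corpus, vocab, transform = transform)
  model <- fit_factor_analysis(utm, k = k, seed = seed, ...)
  if (rotation != "none") model <- rotate_factors(model, method = rotation)
  model
}

#' Test-retest stability of factor scores over calendar windows
#'
#' Messages are split at random into a training portion (stratified per user,
#' `train_fraction` of each user's messages) and a held-out test portion. The
#' model is fit on the training user-term matrix; the test portion is cut
#' into consecutive calendar windows, each window's matrix is built with the
#' model's vocabulary and standardization, scores are inferred per window,
#' and each factor's scores at lag t are correlated with its window-0 scores
#' over the users present in both windows.
#'
#' @param corpus Message tibble with timestamps.
#' @param k Number of factors.
#' @param top_k Vocabulary size for the training fit.
#' @param rotation Rotation method for the fitted model.
#' @param train_fraction Fraction of each user's messages used for training.
#' @param window_months Calendar window length.
#' @param min_words Per-window word threshold for scoring users (also applied
#'   to training users overall).
#' @param stopwords Stopword list.
#' @param seed Seed controlling the message split.
#' @return An object of class `stability_report` with `$retest` (tibble
#'   `factor`, `lag`, `r`, `n`), `$window_scores` (list of score tibbles),
#'   and `$model`.
#' @export
test_retest <- function(corpus, k = 5, top_k = NULL, rotation = "promax",
                        train_fraction = 0.75, window_months = 6,
                        min_words = 1000, stopwords = wt_stopwords(),
                        seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  corpus <- with_tokens(corpus)
  in_train <- logical(nrow(corpus))
  withr::with_seed(derive_seed(seed, 11L), {
    for (idx in split(seq_len(nrow(corpus)), corpus$user_id)) {
      n_tr <- max(1L, round(length(idx) * train_fraction))
      in_train[idx[sample.int(length(idx), n_tr)]] <- TRUE
    }
  })
  train <- corpus[in_train, , drop = FALSE]
  test <- corpus[!in_train, , drop = FALSE]

  train <- filter_users(train, min_words = min_words, max_age = NULL,
                        require_country = NULL)
  model <- induce_traits(train, k = k, top_k = top_k, rotation = rotation,
                         stopwords = stopwords, seed = seed)

  windows <- window_corpus(test, window_months = window_months,
                           min_words_per_window = min_words)
  if (length(windows) < 2)
    warn("fewer than 2 windows with qualifying users; retest curve is trivial")
  window_scores <- lapply(windows, function(wc) {
    utm <- build_user_term_matrix(wc, model$vocabulary, transform = model$transform)
    score_users(model, utm)
  })
  lags <- as.integer(sub("window_", "", names(windows)))
  base <- window_scores[[which.min(lags)]]
  rows <- list()
  for (wi in seq_along(windows)) {
    lag <- lags[wi] - min(lags)
    cur <- window_scores[[wi]]
    common <- intersect(base$user_id, cur$user_id)
    if (length(common) < 3) {
      warn(sprintf("window %d shares fewer than 3 users with window 0; lag omitted",
                   lags[wi]))
      next
    }
    A <- score_matrix(dplyr::filter(base, .data$user_id %in% common))$F
    B <- score_matrix(dplyr::filter(cur, .data$user_id %in% common))$F
    r <- vapply(seq_len(k), function(f) cor(A[, f], B[, f]), 1)
    rows[[length(rows) + 1L]] <-
      tibble(factor = seq_len(k), lag = lag, r = r, n = length(common))
  }
  structure(list(retest = dplyr::bind_rows(rows),
                 window_scores = window_scores, model = model,
                 dropout = NULL, seed = seed),
            class = "stability_report")
}

#' Dropout reliability of the induced factors
#'
#' Refits the model `n_runs` times, each time on the training matrix with an
#' independent random `drop_fraction` of training users removed
#' (standardization recomputed on the retained users), scores the fixed
#' held-out test users with every refit, aligns every unordered pair of runs
#' with the Hungarian algorithm on the test-set scores, and reports the mean
#' over pairs of the mean absolute aligned correlation.
#'
#' @param train_matrix,test_matrix `user_term_matrix` objects over disjoint
#'   user sets sharing a vocabulary.
#' @param k Number of factors.
#' @param rotation Rotation applied to each refit.
#' @param drop_fraction Fraction of training users dropped per run, in (0,1).
#' @param n_runs Number of refits (at least 2).
#' @param seed Seed controlling the drops.
#' @return An object of class `stability_report` with `$dropout` (tibble
#'   `run_i`, `run_j`, `mean_abs_corr`), `$dropout_mean`, `$n_runs`,
#'   `$drop_fraction`.
#' @export
dropout_reliability <- function(train_matrix, test_matrix, k = 5,
                                rotation = "promax", drop_fraction = 0.2,
                                n_runs = 100L, seed = 1L) {
  stopifnot(inherits(train_matrix, "user_term_matrix"),
            inherits(test_matrix, "user_term_matrix"))
  if (drop_fraction <= 0 || drop_fraction >= 1)
    abort("drop_fraction must lie strictly inside (0, 1)")
  if (n_runs < 2) abort("n_runs must be at least 2")
  if (length(intersect(train_matrix$users, test_matrix$users)) > 0L)
    abort("train and test user sets must be disjoint")
  n_tr <- length(train_matrix$users)
  n_drop <- round(drop_fraction * n_tr)
  score_sets <- withr::with_seed(derive_seed(seed, 13L), {
    lapply(seq_len(n_runs), function(run) {
      keep <- train_matrix$users
      if (n_drop > 0L) keep <- keep[-sample.int(n_tr, n_drop)]
      sub <- subset_users(train_matrix, keep)
      model <- fit_factor_analysis(sub, k = k, seed = seed)
      if (rotation != "none") model <- rotate_factors(model, method = rotation)
      score_users(model, test_matrix)
    })
  })
  pairs <- utils::combn(n_runs, 2L)
  vals <- apply(pairs, 2L, function(ij)
    align_factors(score_sets[[ij[1]]], score_sets[[ij[2]]])$mean_abs_corr)
  structure(list(retest = NULL, window_scores = NULL, model = NULL,
                 dropout = tibble(run_i = pairs[1L, ], run_j = pairs[2L, ],
                                  mean_abs_corr = vals),
                 dropout_mean = mean(vals), n_runs = as.integer(n_runs),
                 drop_fraction = drop_fraction, seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  if (!is.null(x$retest)) {
    cat(sprintf("  retest: %d factor(s), lags %s\n",
                length(unique(x$retest$factor)),
                paste(sort(unique(x$retest$lag)), collapse = ", ")))
  }
  if (!is.null(x$dropout)) {
    cat(sprintf("  dropout: mean aligned |r| = %.3f over %d run pairs (drop %.0f%%)\n",
                x$dropout_mean, nrow(x$dropout), 100 * x$drop_fraction))
  }
  invisible(x)
}

#' @describeIn test_retest Tidy the retest curves (or dropout pairs when the
#'   report has no retest component).
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
tidy.stability_report <- function(x, ...) {
  if (!is.null(x$retest)) x$retest else x$dropout
}

#' @describeIn test_retest One-row summary.
#' @export
glance.stability_report <- function(x, ...) {
  tibble(
    n_lags = if (!is.null(x$retest)) length(unique(x$retest$lag)) else NA_integer_,
    mean_retest_r = if (!is.null(x$retest)) mean(x$retest$r) else NA_real_,
    dropout_mean = x$dropout_mean %||% NA_real_,
    n_runs = x$n_runs %||% NA_integer_
  )
}
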