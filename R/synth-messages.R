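#' Generate a message corpus from planted traits
#'
#' For every user and window, a word total is drawn from the configured
#' log-normal (resampled to be at least its minimum), and that many words are
#' drawn i.i.d. from the user's word distribution
#' `softmax(baseline_logfreq + true_loadings %*% trait)`. The word stream is
#' partitioned into messages of random length (Poisson around
#' `mean_message_length`) with uniform timestamps inside the window.
#'
#' @param pop A [generate_population()] result.
#' @param config The same [synth_config()] the population was generated from.
#' @return A tibble (`user_id`, `timestamp` POSIXct UTC, `text`) sorted by
#'   user then timestamp, with attribute `word_totals`: a tibble
#'   (`user_id`, `window`, `n_words`) recording the generator's bookkeeping.
#' @export
generate_messages <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "synth_population"))
  if (config$n_users < 1L) abort("empty population")
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    n <- cfg$n_users; V <- cfg$vocab_size
    bounds <- window_bounds(cfg$start_date, cfg$n_windows, cfg$window_months)
    out <- vector("list", cfg$n_windows)
    totals <- vector("list", cfg$n_windows)
    user_ids <- pop$demographics$user_id
    for (w in seq_len(cfg$n_windows)) {
      n_words <- draw_word_totals(n, cfg$words_per_user)
      # V x n matrix of per-user word probabilities under the softmax link.
      logits <- pop$baseline_logfreq + pop$true_loadings %*% t(pop$traits[[w]])
      probs <- softmax_cols(logits)
      counts <- vapply(seq_len(n), function(u) rmultinom(1L, n_words[u], probs[, u])[, 1L],
                       integer(V))
      out[[w]] <- assemble_messages(counts, n_words, user_ids, pop$vocabulary,
                                    cfg$mean_message_length,
                                    bounds[w], bounds[w + 1])
      totals[[w]] <- tibble(user_id = user_ids, window = w - 1L, n_words = n_words)
    }
    corpus <- dplyr::bind_rows(out)
    corpus <- dplyr::arrange(corpus, .data$user_id, .data$timestamp)
    attr(corpus, "word_totals") <- dplyr::bind_rows(totals)
    corpus
  })
}

draw_word_totals <- function(n, wpu) {
  x <- round(rlnorm(n, wpu$meanlog, wpu$sdlog))
  bad <- which(x < wpu$min)
  while (length(bad) > 0L) {
    x[bad] <- round(rlnorm(length(bad), wpu$meanlog, wpu$sdlog))
    bad <- bad[x[bad] < wpu$min]
  }
  as.integer(x)
}

# Message lengths for one user: 1 + Poisson(mean_len - 1) draws until the
# word budget is covered; the last message is trimmed to fit.
draw_message_lengths <- function(total, mean_len) {
  lens <- integer(0)
  covered <- 0L
  while (covered < total) {
    need <- ceiling((total - covered) / mean_len) + 8L
    add <- rpois(need, mean_len - 1) + 1L
    lens <- c(lens, add)
    covered <- covered + sum(add)
  }
  cl <- cumsum(lens)
  m <- which(cl >= total)[1L]
  lens <- lens[seq_len(m)]
  lens[m] <- lens[m] - (cl[m] - total)
  lens[lens > 0L]
}

# counts: V x n word counts for one window. Builds shuffled per-user word
# streams, cuts them into messages, and collapses the whole window with a
# single paste/strsplit pass so cost stays linear in the word total.
assemble_messages <- function(counts, n_words, user_ids, vocabulary,
                              mean_len, t0, t1) {
  n <- length(n_words)
  tokens <- unlist(lapply(seq_len(n), function(u) {
    ids <- rep.int(seq_along(vocabulary), counts[, u])
    vocabulary[ids[sample.int(length(ids))]]
  }), use.names = FALSE)
  n_tok <- colSums(counts)

  lens_by_user <- lapply(seq_len(n), function(u) draw_message_lengths(n_tok[u], mean_len))
  lens <- unlist(lens_by_user, use.names = FALSE)
  msg_user <- rep.int(seq_len(n), lengths(lens_by_user))

  last_tok <- cumsum(lens)
  tokens[last_tok] <- paste0(tokens[last_tok], "\n")
  joined <- paste(tokens, collapse = " ")
  texts <- strsplit(joined, "\n ", fixed = TRUE)[[1L]]
  texts[length(texts)] <- sub("\n$", "", texts[length(texts)])
  stopifnot(length(texts) == length(lens))

  ts <- as.POSIXct(t0, tz = "UTC") +
    runif(length(texts)) * as.numeric(difftime(t1, t0, units = "secs"))
  tibble(user_id = user_ids[msg_user], timestamp = ts, text = texts)
}

window_bounds <- function(start_date, n_windows, window_months) {
  starts <- lubridate::`%m+%`(
    start_date,
    lubridate::period(months = (seq_len(n_windows + 1L) - 1L) * window_months))
  lubridate::force_tz(lubridate::as_datetime(starts), "UTC")
}
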