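#' Tokenize message text
#'
#' Lowercases, splits on whitespace, strips punctuation from word tokens while
#' keeping word-internal apostrophes (`"didn't"` stays whole), and keeps
#' emoticon-like tokens (`":)"`, `":-D"`, `"<3"`) intact. A total function on
#' strings: empty input yields an empty token vector.
#'
#' @param text Character vector of messages.
#' @return A list of character token vectors, one element per input message.
#' @export
#' @examples
#' tokenize("Goodbye to anybody I didn't get to catch up with")[[1]]
tokenize <- function(text) {
  if (length(text) == 0L) return(list())
  text <- tolower(as.character(text))
  text[is.na(text)] <- ""
  raw <- strsplit(text, "[ \t\r\n]+")
  flat <- unlist(raw, use.names = FALSE)
  n_per <- lengths(raw)
  if (length(flat) == 0L) return(rep(list(character(0)), length(text)))
  emo <- grepl("^[<>]?[:;=8xX][-'o^*]?[][)(}{dpb3oc*\\\\/|]+$|^<3+$|^\\^_*\\^$",
               flat, perl = TRUE)
  clean <- flat
  clean[!emo] <- gsub("[^\\p{L}\\p{N}']+", "", flat[!emo], perl = TRUE)
  clean[!emo] <- gsub("^'+|'+$", "", clean[!emo], perl = TRUE)
  keep <- nzchar(clean)
  msg_id <- rep.int(seq_along(n_per), n_per)
  out <- split(clean[keep], factor(msg_id[keep], levels = seq_along(text)))
  unname(out)
}

# Tokenizes once and caches the result in a `tokens` list-column so repeated
# corpus operations do not re-tokenize.
with_tokens <- function(corpus) {
  if ("tokens" %in% names(corpus)) return(corpus)
  corpus$tokens <- tokenize(corpus$text)
  corpus
}

user_token_counts <- function(corpus) {
  corpus <- with_tokens(corpus)
  tibble(user_id = corpus$user_id, n_tokens = lengths(corpus$tokens)) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n_tokens = sum(.data$n_tokens), .groups = "drop")
}

#' The packaged English stopword list
#'
#' Very frequent function words removed before building the vocabulary.
#' Override by passing your own character vector to [build_vocabulary()].
#'
#' @return Character vector of stopwords.
#' @export
wt_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "wordtraits")
  readLines(path, warn = FALSE)
}

#' Filter users by word count, age, and country
#'
#' Retains users who posted at least `min_words` tokens ("less than 1000
#' words" are dropped, so exactly 1000 is retained), are at most `max_age`
#' years old, and are from the required country. Age and country filters are
#' skipped when the metadata column is absent.
#'
#' @param corpus Message tibble (`user_id`, `timestamp`, `text`).
#' @param user_meta Optional tibble with `user_id` and any of `age`,
#'   `country`, `language_ok`.
#' @param min_words Minimum total token count per retained user.
#' @param max_age Maximum age in years (inclusive); `NULL` skips.
#' @param require_country Required country code; `NULL` skips.
#' @return The filtered corpus, with attribute `drop_counts`: named integer
#'   vector of users dropped per criterion.
#' @export
filter_users <- function(corpus, user_meta = NULL, min_words = 1000,
                         max_age = 65, require_country = "US") {
  if (min_words < 1) abort("min_words must be at least 1")
  corpus <- with_tokens(corpus)
  counts <- user_token_counts(corpus)
  drop_words <- counts$user_id[counts$n_tokens < min_words]
  drop_age <- character(0)
  drop_country <- character(0)
  if (!is.null(user_meta)) {
    if (!is.null(max_age) && "age" %in% names(user_meta))
      drop_age <- user_meta$user_id[!is.na(user_meta$age) & user_meta$age > max_age]
    if (!is.null(require_country) && "country" %in% names(user_meta))
      drop_country <- user_meta$user_id[!is.na(user_meta$country) &
                                          user_meta$country != require_country]
  }
  dropped <- unique(c(drop_words, drop_age, drop_country))
  out <- corpus[!(corpus$user_id %in% dropped), , drop = FALSE]
  attr(out, "drop_counts") <- c(min_words = length(drop_words),
                                max_age = length(drop_age),
                                country = length(drop_country),
                                total_users_dropped = length(dropped))
  out
}

#' Build the analysis vocabulary
#'
#' Removes stopwords first, then keeps the `top_k` remaining terms by total
#' corpus frequency, ties broken lexicographically (deterministic).
#'
#' @param corpus Message tibble.
#' @param top_k Number of vocabulary terms to keep.
#' @param stopwords Character vector of stopwords ([wt_stopwords()] by
#'   default).
#' @return An object of class `vocabulary`: list with `terms` (ordered),
#'   `term_freq` (corpus counts, same order), `stopwords_removed`.
#' @export
build_vocabulary <- function(corpus, top_k, stopwords = wt_stopwords()) {
  if (top_k < 1) abort("top_k must be at least 1")
  corpus <- with_tokens(corpus)
  tab <- table(unlist(corpus$tokens, use.names = FALSE))
  terms <- names(tab)
  freq <- as.integer(tab)
  is_stop <- terms %in% stopwords
  stopwords_removed <- terms[is_stop]
  terms <- terms[!is_stop]
  freq <- freq[!is_stop]
  ord <- order(-freq, terms, method = "radix")
  terms <- terms[ord]; freq <- freq[ord]
  if (length(terms) < top_k) {
    warn(sprintf("only %d distinct non-stopword terms available (top_k = %d); keeping all",
                 length(terms), top_k))
    top_k <- length(terms)
  }
  structure(list(terms = terms[seq_len(top_k)],
                 term_freq = freq[seq_len(top_k)],
                 stopwords_removed = stopwords_removed),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms (%d stopword types removed)\n",
              length(x$terms), length(x$stopwords_removed)))
  cat("  head:", paste(head(x$terms, 8L), collapse = ", "), "\n")
  invisible(x)
}

#' Build the standardized user-term matrix
#'
#' Accumulates raw counts per (user, term), converts to per-user relative
#' frequencies over the in-vocabulary tokens (rows sum to 1), optionally
#' applies a square-root variance-stabilizing transform, and z-scores each
#' column. The fitting-set column means and standard deviations are stored so
#' new users can later be standardized onto the same scale.
#'
#' @param corpus Message tibble (filtered).
#' @param vocab A [build_vocabulary()] result.
#' @param transform `"relfreq"` (default) or `"relfreq_sqrt"`.
#' @return An object of class `user_term_matrix`: list with `users`,
#'   `vocabulary`, `counts` (sparse users x V), `rel_freq` (dense, after the
#'   transform), `standardized`, `col_means`, `col_sds`, `transform`,
#'   `corpus_term_freq`.
#' @export
build_user_term_matrix <- function(corpus, vocab,
                                   transform = c("relfreq", "relfreq_sqrt")) {
  transform <- match.arg(transform)
  stopifnot(inherits(vocab, "vocabulary"))
  corpus <- with_tokens(corpus)
  toks <- unlist(corpus$tokens, use.names = FALSE)
  uid <- rep.int(corpus$user_id, lengths(corpus$tokens))
  j <- match(toks, vocab$terms)
  ok <- !is.na(j)
  users <- sort(unique(corpus$user_id))
  i <- match(uid[ok], users)
  counts <- Matrix::sparseMatrix(i = i, j = j[ok], x = 1,
                                 dims = c(length(users), length(vocab$terms)),
                                 dimnames = list(users, vocab$terms))
  counts <- methods::as(counts, "CsparseMatrix")
  totals <- Matrix::rowSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warn(sprintf("%d user(s) with no in-vocabulary tokens dropped", sum(empty)))
    counts <- counts[!empty, , drop = FALSE]
    users <- users[!empty]
    totals <- totals[!empty]
  }
  rel <- as.matrix(counts / totals)
  if (transform == "relfreq_sqrt") rel <- sqrt(rel)
  mu <- colMeans(rel)
  sds <- apply(rel, 2L, sd)
  degenerate <- !is.finite(sds) | sds < 1e-12
  sds[degenerate] <- 1
  std <- sweep(sweep(rel, 2L, mu, "-"), 2L, sds, "/")
  structure(list(users = users, vocabulary = vocab, counts = counts,
                 rel_freq = rel, standardized = std,
                 col_means = mu, col_sds = sds,
                 degenerate_terms = vocab$terms[degenerate],
                 transform = transform,
                 corpus_term_freq = vocab$term_freq),
            class = "user_term_matrix")
}

#' Wrap a plain numeric matrix as a user-term matrix
#'
#' Convenience constructor for simulation studies that operate directly on a
#' users x variables matrix without any text: the matrix is taken as the
#' (transformed) relative-frequency matrix and z-scored column-wise.
#'
#' @param x Numeric matrix (users x variables).
#' @param users Optional user ids (defaults to rownames or `u1..un`).
#' @param terms Optional variable names (defaults to colnames or `v1..vV`).
#' @return A `user_term_matrix`.
#' @export
as_user_term_matrix <- function(x, users = NULL, terms = NULL) {
  x <- as.matrix(x)
  users <- users %||% rownames(x) %||% paste0("u", seq_len(nrow(x)))
  terms <- terms %||% colnames(x) %||% paste0("v", seq_len(ncol(x)))
  dimnames(x) <- list(users, terms)
  vocab <- structure(list(terms = terms,
                          term_freq = rep(1L, length(terms)),
                          stopwords_removed = character(0)),
                     class = "vocabulary")
  mu <- colMeans(x)
  sds <- apply(x, 2L, sd)
  degenerate <- !is.finite(sds) | sds < 1e-12
  sds[degenerate] <- 1
  std <- sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
  structure(list(users = users, vocabulary = vocab,
                 counts = methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
                 rel_freq = x, standardized = std,
                 col_means = mu, col_sds = sds,
                 degenerate_terms = terms[degenerate],
                 transform = "relfreq",
                 corpus_term_freq = rep(1L, length(terms))),
            class = "user_term_matrix")
}

#' @export
print.user_term_matrix <- function(x, ...) {
  cat(sprintf("<user_term_matrix> %d users x %d terms (%s transform)\n",
              length(x$users), length(x$vocabulary$terms), x$transform))
  invisible(x)
}

#' @export
dim.user_term_matrix <- function(x) c(length(x$users), length(x$vocabulary$terms))

#' Restrict a user-term matrix to a subset of users
#'
#' Keeps the given users and recomputes the column standardization on the
#' subset (the fitting-set convention), as dropout refits require.
#'
#' @param utm A `user_term_matrix`.
#' @param keep_users Character vector of user ids to retain (all must be
#'   present).
#' @return A `user_term_matrix` over the retained users.
#' @export
subset_users <- function(utm, keep_users) {
  stopifnot(inherits(utm, "user_term_matrix"))
  idx <- match(keep_users, utm$users)
  stopifnot(!anyNA(idx))
  rel <- utm$rel_freq[idx, , drop = FALSE]
  mu <- colMeans(rel)
  sds <- apply(rel, 2L, sd)
  degenerate <- !is.finite(sds) | sds < 1e-12
  sds[degenerate] <- 1
  std <- sweep(sweep(rel, 2L, mu, "-"), 2L, sds, "/")
  structure(list(users = utm$users[idx], vocabulary = utm$vocabulary,
                 counts = utm$counts[idx, , drop = FALSE],
                 rel_freq = rel, standardized = std,
                 col_means = mu, col_sds = sds,
                 degenerate_terms = utm$vocabulary$terms[degenerate],
                 transform = utm$transform,
                 corpus_term_freq = utm$corpus_term_freq),
            class = "user_term_matrix")
}

#' Split a corpus into consecutive calendar windows
#'
#' Windows are consecutive half-open calendar intervals of `window_months`
#' months anchored at the corpus minimum timestamp; a message falling exactly
#' on a boundary instant belongs to the later window. Within each window,
#' users with fewer than `min_words_per_window` tokens are dropped for that
#' window only.
#'
#' @param corpus Message tibble with parseable timestamps.
#' @param window_months Window length in months.
#' @param min_words_per_window Per-window word threshold.
#' @return A named list of window corpora (`window_0`, `window_1`, ...;
#'   empty windows omitted) with attribute `boundaries` (POSIXct).
#' @export
window_corpus <- function(corpus, window_months = 6, min_words_per_window = 1000) {
  if (window_months < 1) abort("window_months must be at least 1")
  corpus <- with_tokens(corpus)
  ts <- corpus$timestamp
  stopifnot(!anyNA(ts))
  start <- min(ts)
  bounds <- start
  while (max(bounds) <= max(ts)) {
    nxt <- lubridate::`%m+%`(start,
                             lubridate::period(months = window_months * length(bounds)))
    bounds <- c(bounds, nxt)
  }
  w <- findInterval(ts, bounds, rightmost.closed = FALSE) - 1L
  out <- list()
  for (wi in sort(unique(w))) {
    sub <- corpus[w == wi, , drop = FALSE]
    counts <- user_token_counts(sub)
    keep <- counts$user_id[counts$n_tokens >= min_words_per_window]
    sub <- sub[sub$user_id %in% keep, , drop = FALSE]
    if (nrow(sub) > 0L) out[[paste0("window_", wi)]] <- sub
  }
  attr(out, "boundaries") <- bounds
  out
}
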