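test_that("tokenize lowercases, keeps apostrophes and emoticons, strips punctuation", {
  expect_identical(tokenize("")[[1]], character(0))
  expect_identical(
    tokenize("Goodbye to anybody I didn't get to catch up with")[[1]],
    c("goodbye", "to", "anybody", "i", "didn't", "get", "to", "catch",
      "up", "with"))
  expect_identical(tokenize("AAA aaa AaA")[[1]], c("aaa", "aaa", "aaa"))
  expect_identical(tokenize("hello, world!!")[[1]], c("hello", "world"))
  expect_identical(tokenize("so happy :) today :-D <3")[[1]],
                   c("so", "happy", ":)", "today", ":-d", "<3"))
  expect_identical(tokenize("'quoted' word")[[1]], c("quoted", "word"))
  # vectorized: one element per message, empties preserved
  out <- tokenize(c("one two", "", "three"))
  expect_length(out, 3L)
  expect_identical(out[[2]], character(0))
})

test_that("filter_users applies the strict less-than word threshold", {
  corp <- corpus_from_tokens(
    list(rep("w", 999), rep("w", 1000), rep("w", 1500)),
    c("short", "exact", "long"))
  kept <- filter_users(corp, min_words = 1000)
  expect_setequal(unique(kept$user_id), c("exact", "long"))
  expect_equal(unname(attr(kept, "drop_counts")["min_words"]), 1L)

  # all users passing: output identical to input
  all_pass <- filter_users(corp, min_words = 10)
  expect_identical(all_pass$text, corp$text)
  expect_error(filter_users(corp, min_words = 0), "min_words")
})

test_that("age and country filters use metadata and commute with word filter", {
  corp <- corpus_from_tokens(
    list(rep("w", 2000), rep("w", 2000), rep("w", 2000), rep("w", 100)),
    c("ok", "old", "abroad", "quiet"))
  meta <- tibble::tibble(user_id = c("ok", "old", "abroad", "quiet"),
                         age = c(30, 70, 25, 25),
                         country = c("US", "US", "FR", "US"))
  kept <- filter_users(corp, meta, min_words = 1000)
  expect_setequal(unique(kept$user_id), "ok")

  # order independence: sequential application in any order ends the same
  seq1 <- filter_users(filter_users(filter_users(corp, min_words = 1000),
                                    meta, min_words = 1),
                       meta, min_words = 1, max_age = NULL)
  seq2 <- filter_users(filter_users(corp, meta, min_words = 1,
                                    require_country = NULL),
                       meta, min_words = 1000, max_age = NULL)
  expect_setequal(unique(seq1$user_id), unique(kept$user_id))
  expect_setequal(unique(seq2$user_id), unique(kept$user_id))
})

test_that("build_vocabulary removes stopwords then ranks by frequency", {
  toks <- c(rep("the", 100), rep("cat", 5), rep("dog", 3))
  corp <- corpus_from_tokens(list(toks), "u1")
  v <- build_vocabulary(corp, top_k = 2, stopwords = "the")
  expect_identical(v$terms, c("cat", "dog"))
  expect_identical(v$term_freq, c(5L, 3L))
  expect_identical(v$stopwords_removed, "the")

  # lexicographic tie-break
  v2 <- build_vocabulary(corpus_from_tokens(list(c(rep("bb", 5), rep("aa", 5))), "u1"),
                         top_k = 1, stopwords = character(0))
  expect_identical(v2$terms, "aa")

  # asking for more terms than exist keeps all with a warning
  expect_warning(v3 <- build_vocabulary(corp, top_k = 10, stopwords = "the"),
                 "keeping all")
  expect_length(v3$terms, 2L)
})

test_that("vocabulary rank order recovers the planted Zipf baseline", {
  fx <- small_fixture()
  v <- build_vocabulary(fx$corpus, top_k = fx$cfg$vocab_size,
                        stopwords = character(0))
  planted_rank <- match(v$terms, fx$pop$vocabulary)
  expect_gt(cor(seq_along(planted_rank), planted_rank, method = "spearman"),
            0.95)
})

test_that("user-term matrix normalizes rows and z-scores columns", {
  corp <- corpus_from_tokens(list(c("aa", "aa", "bb", "bb"),
                                  c("aa", "bb", "bb", "bb")),
                             c("u1", "u2"))
  v <- build_vocabulary(corp, 2, stopwords = character(0))
  utm <- build_user_term_matrix(corp, v)
  expect_equal(unname(utm$rel_freq["u1", c("aa", "bb")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(utm$rel_freq)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(colMeans(utm$standardized)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(utm$standardized, 2, sd)), c(1, 1),
               tolerance = 1e-6)

  # idempotence: applying stored means/sds to the fitting matrix reproduces it
  re_std <- sweep(sweep(utm$rel_freq, 2, utm$col_means), 2, utm$col_sds, "/")
  expect_equal(re_std, utm$standardized, tolerance = 1e-12)

  # sqrt transform flag changes the stored cells
  utm_sq <- build_user_term_matrix(corp, v, transform = "relfreq_sqrt")
  expect_equal(unname(utm_sq$rel_freq["u1", "aa"]), sqrt(0.5))
})

test_that("rel_freq is invariant to message partition and record order", {
  toks <- c(rep("aa", 6), rep("bb", 3), rep("cc", 3))
  one_msg <- corpus_from_tokens(list(toks), "u1")
  many_msg <- corpus_from_tokens(split(toks, rep(1:4, each = 3)),
                                 rep("u1", 4))
  v <- build_vocabulary(one_msg, 3, stopwords = character(0))
  expect_equal(build_user_term_matrix(one_msg, v)$rel_freq,
               build_user_term_matrix(many_msg, v)$rel_freq)

  fx <- small_fixture()
  shuffled <- fx$corpus[withr::with_seed(1, sample(nrow(fx$corpus))), ]
  utm_shuffled <- build_user_term_matrix(shuffled, fx$vocab)
  expect_equal(utm_shuffled$rel_freq, fx$utm$rel_freq)
})

test_that("users with no in-vocabulary tokens are dropped with a warning", {
  corp <- corpus_from_tokens(list(c("aa", "bb"), c("zz", "zz")),
                             c("u1", "u2"))
  v <- build_vocabulary(corpus_from_tokens(list(c("aa", "bb")), "u1"), 2,
                        stopwords = character(0))
  expect_warning(utm <- build_user_term_matrix(corp, v), "dropped")
  expect_identical(utm$users, "u1")
})

test_that("windows are half-open calendar intervals anchored at the start", {
  t0 <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  boundary <- as.POSIXct("2010-07-01 00:00:00", tz = "UTC")
  corp <- tibble::tibble(
    user_id = c("u1", "u1", "u1"),
    timestamp = c(t0, boundary - 1, boundary),
    text = c(paste(rep("aa", 1000), collapse = " "),
             paste(rep("bb", 1000), collapse = " "),
             paste(rep("cc", 1000), collapse = " ")))
  w <- window_corpus(corp, window_months = 6, min_words_per_window = 1)
  expect_named(w, c("window_0", "window_1"))
  expect_setequal(w$window_0$text, corp$text[1:2])
  expect_identical(w$window_1$text, corp$text[3])       # boundary -> later window

  # single-month corpus: one window holding everyone
  w1 <- window_corpus(corp[1:2, ], window_months = 6, min_words_per_window = 1)
  expect_length(w1, 1L)
  expect_error(window_corpus(corp, window_months = 0), "window_months")
})

test_that("windowed synthetic corpora agree with generator bookkeeping", {
  cfg <- synth_config(n_users = 60, vocab_size = 50, n_factors = 2,
                      markers_per_factor = 8, n_windows = 3,
                      words_per_user = list(meanlog = log(1400), sdlog = 0.25,
                                            min = 1000),
                      seed = 9)
  pop <- generate_population(cfg)
  corp <- generate_messages(pop)
  w <- window_corpus(corp, window_months = 6, min_words_per_window = 1000)
  expect_length(w, 3L)
  totals <- attr(corp, "word_totals")
  for (wi in 0:2) {
    expected_users <- totals$user_id[totals$window == wi & totals$n_words >= 1000]
    expect_setequal(unique(w[[paste0("window_", wi)]]$user_id), expected_users)
  }
})
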