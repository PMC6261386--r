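# Shared small-scale fixtures, generated in code and cached per test run.

small_config <- function(...) {
  defaults <- list(
    n_users = 150, vocab_size = 80, n_factors = 2, markers_per_factor = 15,
    words_per_user = list(meanlog = log(1500), sdlog = 0.3, min = 1000),
    likes_specs = list(n_items = 60, n_clusters = 3,
                       within_p = 0.6, background_p = 0.02),
    seed = 7
  )
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- small_config()
    pop <- generate_population(cfg)
    corpus <- generate_messages(pop)
    vocab <- build_vocabulary(corpus, top_k = cfg$vocab_size)
    utm <- build_user_term_matrix(corpus, vocab)
    model <- rotate_factors(fit_factor_analysis(utm, k = cfg$n_factors),
                            "promax")
    .fixture_cache$fx <- list(cfg = cfg, pop = pop, corpus = corpus,
                              vocab = vocab, utm = utm, model = model)
  }
  .fixture_cache$fx
}

# Planted traits as a score tibble aligned with generator user ids.
trait_scores <- function(pop, window = 1) {
  m <- pop$traits[[window]]
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(user_id = pop$demographics$user_id),
                   tibble::as_tibble(m))
}

# One-message-per-line corpus from explicit token vectors.
corpus_from_tokens <- function(token_lists, user_ids,
                               t0 = as.POSIXct("2010-01-01", tz = "UTC")) {
  tibble::tibble(
    user_id = user_ids,
    timestamp = t0 + seq_along(user_ids),
    text = vapply(token_lists, paste, "", collapse = " ")
  )
}

# All permutations of 1..n (test oracle for the assignment solver).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1L), function(p) c(i, p + (p >= i)))
  }))
}

# Principal angles (degrees) between the column spaces of A and B.
principal_angles <- function(A, B) {
  Qa <- qr.Q(qr(A)); Qb <- qr.Q(qr(B))
  acos(pmin(1, svd(crossprod(Qa, Qb))$d)) * 180 / pi
}
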