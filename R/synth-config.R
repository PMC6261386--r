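#' Configuration for the synthetic social-media population
#'
#' Bundles every knob of the generative model behind the synthetic corpus:
#' latent traits drawn from a correlated multivariate normal, word use tied to
#' traits through a softmax link over a Zipfian baseline vocabulary, outcomes
#' linearly driven by traits and demographics, and block-structured likes.
#' The demographic defaults (62.8% female, median age 22, mean age 25.49,
#' at least 1000 words per retained user) mirror the large US Facebook
#' populations used in open-vocabulary language studies.
#'
#' @param n_users Number of users to simulate.
#' @param vocab_size Number of distinct word types.
#' @param n_factors Number of planted latent traits `k`.
#' @param markers_per_factor Number of marker words assigned to each factor;
#'   marker sets are disjoint and signs are split evenly.
#' @param loading_magnitude Absolute log-scale word-use shift per unit trait
#'   for marker words. The default 0.5 gives per-marker word-trait
#'   correlations in the 0.3-0.8 range at the default word budget: strong
#'   enough for factor recovery, far from noiseless.
#' @param factor_correlation Common off-diagonal of the trait correlation
#'   matrix (oblique traits).
#' @param stability_rho AR(1) autocorrelation of traits across consecutive
#'   6-month windows; 1 freezes traits, 0 redraws them each window.
#' @param n_windows Number of consecutive calendar windows of messages.
#' @param words_per_user List with `meanlog`, `sdlog`, `min`: per-user,
#'   per-window word totals are log-normal, resampled to be at least `min`
#'   (default 1000, the usual retention threshold).
#' @param zipf_exponent Exponent of the rank-frequency law for baseline word
#'   probabilities.
#' @param outcome_specs List of outcome specifications, see [outcome_spec()].
#'   `NULL` uses [default_outcome_specs()].
#' @param likes_specs List with `n_items`, `n_clusters`, `within_p`,
#'   `background_p` for the block-structured likes matrix.
#' @param female_fraction Probability a simulated user is female.
#' @param age_params List with `median` and `mean` of the right-skewed age
#'   distribution (shifted log-normal, truncated to 13-65 years).
#' @param mean_message_length Mean words per message when partitioning a
#'   user's word stream into status updates.
#' @param window_months Calendar length of one window.
#' @param start_date Date at which window 0 opens.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#'
#' @return A validated list of class `synth_config`.
#' @seealso [generate_population()], [generate_messages()],
#'   [generate_outcomes()], [generate_likes()]
#' @export
#' @examples
#' cfg <- synth_config(n_users = 50, vocab_size = 60, n_factors = 2,
#'                     markers_per_factor = 10, seed = 1)
#' pop <- generate_population(cfg)
synth_config <- function(n_users = 2000,
                         vocab_size = 500,
                         n_factors = 3,
                         markers_per_factor = 40,
                         loading_magnitude = 0.5,
                         factor_correlation = 0.25,
                         stability_rho = 0.8,
                         n_windows = 1,
                         words_per_user = list(meanlog = log(3500), sdlog = 0.6, min = 1000),
                         zipf_exponent = 1.07,
                         outcome_specs = NULL,
                         likes_specs = list(n_items = 300, n_clusters = 3,
                                            within_p = 0.5, background_p = 0.01),
                         female_fraction = 0.628,
                         age_params = list(median = 22, mean = 25.49),
                         mean_message_length = 25,
                         window_months = 6,
                         start_date = as.Date("2010-01-01"),
                         seed = 1L) {
  if (is.null(outcome_specs)) outcome_specs <- default_outcome_specs(n_factors)
  cfg <- list(
    n_users = as.integer(n_users), vocab_size = as.integer(vocab_size),
    n_factors = as.integer(n_factors),
    markers_per_factor = as.integer(markers_per_factor),
    loading_magnitude = loading_magnitude,
    factor_correlation = factor_correlation,
    stability_rho = stability_rho, n_windows = as.integer(n_windows),
    words_per_user = words_per_user, zipf_exponent = zipf_exponent,
    outcome_specs = outcome_specs, likes_specs = likes_specs,
    female_fraction = female_fraction, age_params = age_params,
    mean_message_length = mean_message_length,
    window_months = as.integer(window_months), start_date = start_date,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_users >= 1, cfg$vocab_size >= 1, cfg$n_factors >= 1,
            cfg$markers_per_factor >= 1, cfg$loading_magnitude >= 0,
            cfg$zipf_exponent > 0, cfg$n_windows >= 1)
  if (cfg$n_factors > cfg$vocab_size)
    abort("n_factors must not exceed vocab_size", class = "wordtraits_config_error")
  if (cfg$markers_per_factor * cfg$n_factors > cfg$vocab_size)
    abort("markers_per_factor * n_factors must not exceed vocab_size",
          class = "wordtraits_config_error")
  if (cfg$factor_correlation < 0 || cfg$factor_correlation >= 1)
    abort("factor_correlation must lie in [0, 1)", class = "wordtraits_config_error")
  if (cfg$stability_rho < 0 || cfg$stability_rho > 1)
    abort("stability_rho must lie in [0, 1]", class = "wordtraits_config_error")
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1)
    abort("female_fraction must lie in [0, 1]", class = "wordtraits_config_error")
  ls <- cfg$likes_specs
  if (!is.null(ls)) {
    probs <- c(ls$within_p, ls$background_p)
    if (any(probs < 0 | probs > 1))
      abort("likes probabilities must lie in [0, 1]", class = "wordtraits_config_error")
    if (ls$within_p < ls$background_p)
      abort("within_p must be at least background_p", class = "wordtraits_config_error")
  }
  Phi <- trait_correlation(cfg)
  if (any(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    abort("trait correlation matrix is not positive definite",
          class = "wordtraits_config_error")
  invisible(cfg)
}

trait_correlation <- function(cfg) {
  k <- cfg$n_factors
  Phi <- matrix(cfg$factor_correlation, k, k)
  diag(Phi) <- 1
  Phi
}

#' Specify one synthetic outcome
#'
#' @param name Column name of the outcome.
#' @param beta_traits Numeric coefficient vector over the `k` latent traits.
#' @param beta_age,beta_gender Coefficients on z-scored age and the 0/1
#'   female indicator.
#' @param noise_var Variance of the additive Gaussian noise.
#' @param type `"continuous"` or `"binary"` (binary outcomes threshold the
#'   latent continuous value at its median).
#' @return A list consumed by [generate_outcomes()].
#' @export
outcome_spec <- function(name, beta_traits, beta_age = 0, beta_gender = 0,
                         noise_var = 1, type = c("continuous", "binary")) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, noise_var >= 0)
  list(name = name, beta_traits = as.numeric(beta_traits),
       beta_age = beta_age, beta_gender = beta_gender,
       noise_var = noise_var, type = type)
}

#' Default synthetic outcome roster
#'
#' A small battery echoing the outcomes used to validate language-based
#' traits: log income, IQ, satisfaction with life, a depression score, and
#' generic additional questionnaire items. Coefficients give moderate
#' theoretical R-squared (roughly 0.1-0.3), plus one pure-noise item.
#'
#' @param k Number of latent traits the coefficients span.
#' @return List of [outcome_spec()] entries.
#' @export
default_outcome_specs <- function(k) {
  b <- function(...) {
    x <- c(...); v <- numeric(k); n <- min(k, length(x))
    v[seq_len(n)] <- x[seq_len(n)]; v
  }
  list(
    outcome_spec("log_income", b(0.5, -0.2), beta_age = 0.25, noise_var = 1),
    outcome_spec("iq",         b(0.45, 0.1, 0.2), noise_var = 1),
    outcome_spec("swl",        b(0.3, 0.3), beta_gender = 0.1, noise_var = 1),
    outcome_spec("depression", b(-0.25, 0.35, 0.1), beta_age = -0.1, noise_var = 1),
    outcome_spec("q_item_1",   b(0.35), noise_var = 1),
    outcome_spec("q_item_2",   b(0, 0.35), noise_var = 1),
    outcome_spec("q_item_3",   b(0), noise_var = 1)
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d users, %d words, k = %d (%d markers/factor, magnitude %.2f)\n",
    x$n_users, x$vocab_size, x$n_factors, x$markers_per_factor, x$loading_magnitude))
  cat(sprintf("  windows: %d x %d months, stability rho = %.2f, seed = %d\n",
              x$n_windows, x$window_months, x$stability_rho, x$seed))
  invisible(x)
}
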