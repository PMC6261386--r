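test_that("trait autocorrelation across windows follows the AR(1) law", {
  # rho = 1: traits frozen across windows
  cfg1 <- synth_config(n_users = 200, vocab_size = 40, n_factors = 2,
                       markers_per_factor = 5, stability_rho = 1, n_windows = 3,
                       seed = 2)
  pop1 <- generate_population(cfg1)
  expect_identical(pop1$traits[[1]], pop1$traits[[2]])
  expect_identical(pop1$traits[[1]], pop1$traits[[3]])

  # rho = 0: consecutive windows decorrelated within sampling error
  cfg0 <- synth_config(n_users = 5000, vocab_size = 40, n_factors = 3,
                       markers_per_factor = 5, stability_rho = 0, n_windows = 2,
                       seed = 3)
  pop0 <- generate_population(cfg0)
  for (f in 1:3)
    expect_lt(abs(cor(pop0$traits[[1]][, f], pop0$traits[[2]][, f])), 0.05)

  # intermediate rho: corr(window t, window 0) = rho^t +- 3/sqrt(n)
  cfg <- synth_config(n_users = 4000, vocab_size = 40, n_factors = 2,
                      markers_per_factor = 5, stability_rho = 0.6,
                      n_windows = 4, seed = 4)
  pop <- generate_population(cfg)
  for (t in 1:3) for (f in 1:2)
    expect_lt(abs(cor(pop$traits[[1]][, f], pop$traits[[t + 1]][, f]) - 0.6^t),
              3 / sqrt(4000))

  # window-0 traits standardized within sampling error
  expect_equal(unname(colMeans(pop$traits[[1]])), c(0, 0), tolerance = 0.1)
  expect_equal(unname(apply(pop$traits[[1]], 2, sd)), c(1, 1), tolerance = 0.05)
})

test_that("demographics match the configured female fraction and skewed ages", {
  cfg <- synth_config(n_users = 100000, vocab_size = 10, n_factors = 2,
                      markers_per_factor = 2, seed = 5)
  pop <- generate_population(cfg)
  expect_equal(mean(pop$demographics$gender), 0.628, tolerance = 0.005 / 0.628)
  expect_equal(median(pop$demographics$age), 22, tolerance = 0.02)
  expect_equal(mean(pop$demographics$age), 25.49, tolerance = 0.02)
  expect_gte(min(pop$demographics$age), 13)
  expect_lte(max(pop$demographics$age), 65)
})

test_that("word draws follow the softmax link between traits and frequencies", {
  # no trait signal: every user's word distribution is the Zipf baseline
  cfg0 <- synth_config(n_users = 80, vocab_size = 50, n_factors = 2,
                       markers_per_factor = 5, loading_magnitude = 0,
                       words_per_user = list(meanlog = log(2000), sdlog = 0.2,
                                             min = 1000),
                       seed = 6)
  pop0 <- generate_population(cfg0)
  corp0 <- generate_messages(pop0)
  utm0 <- build_user_term_matrix(corp0, build_vocabulary(corp0, 50, stopwords = character(0)))
  expected <- exp(pop0$baseline_logfreq)
  names(expected) <- pop0$vocabulary
  got <- colMeans(utm0$rel_freq)[names(expected)]
  expect_lt(mean(abs(got - expected)), 0.002)

  # opposite-trait users: closed-form softmax separation on a marker word
  cfg1 <- synth_config(n_users = 2, vocab_size = 40, n_factors = 1,
                       markers_per_factor = 2, loading_magnitude = 0.8,
                       words_per_user = list(meanlog = log(2e5), sdlog = 0.01,
                                             min = 2e5),
                       seed = 7)
  pop1 <- generate_population(cfg1)
  pop1$traits[[1]][] <- c(1, -1)
  corp1 <- generate_messages(pop1)
  utm1 <- build_user_term_matrix(corp1, build_vocabulary(corp1, 40, stopwords = character(0)))
  marker <- rownames(pop1$true_loadings)[pop1$true_loadings[, 1] > 0][1]
  expect_gt(utm1$rel_freq[1, marker], utm1$rel_freq[2, marker])
  # empirical distributions track the exact softmax probabilities
  p_exp <- wordtraits:::softmax_cols(
    pop1$baseline_logfreq + pop1$true_loadings %*% t(pop1$traits[[1]]))
  rownames(p_exp) <- pop1$vocabulary
  for (u in 1:2)
    expect_lt(sum(abs(utm1$rel_freq[u, rownames(p_exp)] - p_exp[, u])), 0.02)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config()
  pop_a <- generate_population(cfg)
  pop_b <- generate_population(cfg)
  expect_identical(pop_a$traits, pop_b$traits)
  corp_a <- generate_messages(pop_a)
  corp_b <- generate_messages(pop_b)
  expect_identical(corp_a$text, corp_b$text)
  expect_identical(corp_a$timestamp, corp_b$timestamp)
  expect_identical(generate_outcomes(pop_a), generate_outcomes(pop_b))
  expect_identical(generate_likes(pop_a), generate_likes(pop_b))
})

test_that("outcomes realize their linear model and theoretical R-squared", {
  k2 <- function(...) c(..., rep(0, 2 - length(c(...))))
  # noiseless single-factor outcome is perfectly rank-correlated with the trait
  cfg <- synth_config(
    n_users = 400, vocab_size = 20, n_factors = 2, markers_per_factor = 3,
    factor_correlation = 0,
    outcome_specs = list(
      outcome_spec("pure", k2(1), noise_var = 0),
      outcome_spec("noise_only", k2(0), noise_var = 1),
      outcome_spec("r2_25", k2(1 / sqrt(3)), noise_var = 1)
    ),
    seed = 8)
  pop <- generate_population(cfg)
  out <- generate_outcomes(pop)
  expect_equal(cor(out$pure, pop$traits[[1]][, 1], method = "spearman"), 1)

  # beta = 0: no correlation with any trait beyond sampling error
  cfg_big <- cfg; cfg_big$n_users <- 5000L
  pop_big <- generate_population(cfg_big)
  out_big <- generate_outcomes(pop_big)
  for (f in 1:2)
    expect_lt(abs(cor(out_big$noise_only, pop_big$traits[[1]][, f])), 2 / sqrt(5000))

  # theoretical R^2 = 0.25 matches the oracle fit with the true coefficients
  expect_equal(unname(attr(out_big, "theoretical_r2")["r2_25"]), 0.25,
               tolerance = 1e-12)
  signal <- pop_big$traits[[1]][, 1] / sqrt(3)
  r2_emp <- 1 - var(out_big$r2_25 - signal) / var(out_big$r2_25)
  expect_equal(r2_emp, 0.25, tolerance = 0.02 / 0.25)

  # coefficient-length mismatch errors
  bad <- cfg
  bad$outcome_specs <- list(outcome_spec("bad", c(1, 2, 3)))
  expect_error(generate_outcomes(pop, bad), "coefficient length")
})

test_that("likes carry the planted block structure", {
  cfg <- small_config(likes_specs = list(n_items = 60, n_clusters = 3,
                                         within_p = 1, background_p = 0))
  pop <- generate_population(cfg)
  likes <- generate_likes(pop)
  ic <- attr(likes, "item_cluster")
  uc <- attr(likes, "user_cluster")
  names(uc) <- pop$demographics$user_id
  item_of <- as.integer(sub("item", "", likes$item_id))
  # within_p = 1, background_p = 0: every like is inside the user's own block
  expect_true(all(ic[item_of] == uc[likes$user_id]))
  # and every user likes every item of their block (exact block-diagonal)
  expect_equal(nrow(likes),
               sum(table(ic)[uc]))

  # background_p = within_p: no block structure left
  cfg_flat <- small_config(likes_specs = list(n_items = 60, n_clusters = 3,
                                              within_p = 0.3, background_p = 0.3))
  likes_flat <- generate_likes(generate_population(cfg_flat))
  ic_f <- attr(likes_flat, "item_cluster")
  uc_f <- attr(likes_flat, "user_cluster")
  names(uc_f) <- generate_population(cfg_flat)$demographics$user_id
  inside <- mean(ic_f[as.integer(sub("item", "", likes_flat$item_id))] ==
                   uc_f[likes_flat$user_id])
  share <- mean(table(ic_f)[uc_f] / length(ic_f))
  expect_lt(abs(inside - share), 0.05)

  # invalid probability ordering is rejected
  expect_error(small_config(likes_specs = list(n_items = 10, n_clusters = 2,
                                               within_p = 0.1, background_p = 0.5)),
               "within_p")
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_factors = 10, vocab_size = 5), "exceed")
  expect_error(synth_config(markers_per_factor = 300, vocab_size = 100,
                            n_factors = 3), "exceed")
  expect_error(synth_config(factor_correlation = 1.2), "factor_correlation")
  expect_error(synth_config(stability_rho = 1.5), "stability_rho")
})
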