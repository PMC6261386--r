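test_that("NMF recovers exact block structure and is seed-deterministic", {
  cfg <- small_config(likes_specs = list(n_items = 60, n_clusters = 3,
                                         within_p = 1, background_p = 0))
  pop <- generate_population(cfg)
  likes <- generate_likes(pop)
  cl <- cluster_likes(likes, top_items = 60, n_clusters = 3, seed = 1)
  truth <- attr(likes, "item_cluster")[
    as.integer(sub("item", "", cl$items))]
  expect_equal(cluster_purity(cl$item_assignment, truth), 1)

  cl2 <- cluster_likes(likes, top_items = 60, n_clusters = 3, seed = 1)
  expect_identical(cl$item_membership, cl2$item_membership)
  expect_identical(cl$user_labels, cl2$user_labels)
})

test_that("NMF separates noisy planted clusters", {
  cfg <- small_config(n_users = 400,
                      likes_specs = list(n_items = 60, n_clusters = 3,
                                         within_p = 0.6, background_p = 0.02))
  cfg$n_users <- 400L
  pop <- generate_population(cfg)
  likes <- generate_likes(pop)
  cl <- cluster_likes(likes, top_items = 60, n_clusters = 3, seed = 2)
  truth <- attr(likes, "item_cluster")[as.integer(sub("item", "", cl$items))]
  expect_gte(cluster_purity(cl$item_assignment, truth), 0.95)
  # continuous user weights make the median-split labels near-balanced
  for (c in paste0("c", 1:3))
    expect_equal(mean(cl$user_labels[[c]]), 0.5, tolerance = 0.1)
  expect_error(cluster_likes(likes, top_items = 60, n_clusters = 500), "exceeds")
})

test_that("ridge regression discriminates realizable from null targets", {
  set.seed(50)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 1))
  rep_good <- evaluate_regression(X, y, n_splits = 5, seed = 1)
  expect_gt(rep_good$mean, 0.99)
  expect_equal(rep_good$n_splits, 5L)
  expect_equal(rep_good$mean, mean(rep_good$splits[[1]]))

  y_null <- rnorm(2000)
  X_null <- matrix(rnorm(2000 * 5), 2000, 5)
  rep_null <- evaluate_regression(X_null, y_null, n_splits = 10, seed = 2)
  expect_lt(abs(rep_null$mean), 0.05)

  expect_error(evaluate_regression(X, rep(1, n)), "constant")
  # deterministic given seed
  rep_again <- evaluate_regression(X, y, n_splits = 5, seed = 1)
  expect_identical(rep_good$splits, rep_again$splits)
})

test_that("trait-score features approach the oracle predictive correlation", {
  k2 <- function(...) c(..., rep(0, 2 - length(c(...))))
  # best-case r = 0.6: beta'Phi beta / (beta'Phi beta + noise) = 0.36
  cfg <- synth_config(n_users = 1500, vocab_size = 20, n_factors = 2,
                      markers_per_factor = 3, factor_correlation = 0,
                      outcome_specs = list(outcome_spec(
                        "y", k2(0.6), noise_var = 0.64)),
                      seed = 51)
  pop <- generate_population(cfg)
  out <- generate_outcomes(pop)
  oracle <- evaluate_regression(pop$traits[[1]], out$y, n_splits = 5, seed = 3)
  expect_equal(oracle$mean, 0.6, tolerance = 0.1 / 0.6)
})

test_that("logistic classification reads separable and null targets correctly", {
  set.seed(52)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4)
  labels <- cbind(t1 = as.integer(X %*% c(2, -1, 0, 1) > 0),
                  t2 = as.integer(X %*% c(0, 1, 2, 0) > 0))
  rep_sep <- evaluate_classification(X, labels, n_splits = 5, seed = 1)
  expect_gt(rep_sep$mean, 95)
  expect_identical(rep_sep$metric, "auc")

  n2 <- 800
  null_labels <- cbind(a = rbinom(n2, 1, 0.5), b = rbinom(n2, 1, 0.5))
  rep_null <- evaluate_classification(matrix(rnorm(n2 * 4), n2, 4), null_labels,
                                      n_splits = 5, seed = 2)
  expect_lt(abs(rep_null$mean - 50), 5)

  # duplicated features barely change a regularized fit
  rep_dup <- evaluate_classification(cbind(X, X), labels, n_splits = 5, seed = 1)
  expect_lt(abs(rep_dup$mean - rep_sep$mean), 2)

  # single-class targets are skipped with a warning
  one_class <- cbind(t1 = labels[, 1], dead = rep(1L, n))
  expect_warning(rep_skip <- evaluate_classification(X, one_class,
                                                     n_splits = 3, seed = 1),
                 "single-class")
  expect_equal(nrow(attr(rep_skip, "per_target")), 2L)
  expect_true(is.na(attr(rep_skip, "per_target")$mean_auc[2]))
})

test_that("covariates concatenate, standardize, and align by user id", {
  set.seed(53)
  demo <- tibble::tibble(user_id = paste0("u", 1:50),
                         age = runif(50, 15, 60),
                         gender = rbinom(50, 1, 0.6))
  feats <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  out <- add_covariates(feats, demo)
  expect_equal(ncol(out), 7L)
  expect_equal(mean(out[, "age_z"]), 0, tolerance = 1e-12)
  expect_equal(sd(out[, "age_z"]), 1, tolerance = 1e-12)

  # demographics alone reproduce the baseline feature set
  base <- add_covariates(NULL, demo)
  expect_identical(colnames(base), c("age_z", "gender"))

  # permuted user order aligns back through the join
  sc <- tibble::as_tibble(as.data.frame(feats)) |>
    dplyr::mutate(user_id = demo$user_id, .before = 1)
  perm <- sample(50)
  out_perm <- add_covariates(sc[perm, ], demo)
  expect_equal(out_perm[order(rownames(out_perm)), ],
               {o <- add_covariates(sc, demo); o[order(rownames(o)), ]})
})

test_that("residualization removes demographic variance from scores", {
  set.seed(54)
  n <- 500
  demo <- tibble::tibble(user_id = paste0("u", 1:n),
                         age = runif(n, 15, 60), gender = rbinom(n, 1, 0.5))
  age_z <- as.numeric(scale(demo$age))
  # scores equal to 2 * age_z vanish after residualization
  sc <- tibble::tibble(user_id = demo$user_id, f1 = 2 * age_z,
                       f2 = rnorm(n))
  res <- residualize(sc, demo)
  expect_lt(max(abs(res$f1)), 1e-10)
  # already-orthogonal scores are unchanged
  ortho <- residuals(lm(sc$f2 ~ age_z + demo$gender))
  sc2 <- tibble::tibble(user_id = demo$user_id, f1 = ortho)
  res2 <- residualize(sc2, demo)
  expect_equal(res2$f1, unname(ortho), tolerance = 1e-8)
  # planted age effect is removed exactly
  sc3 <- tibble::tibble(user_id = demo$user_id,
                        f1 = rnorm(n) + 0.3 * age_z)
  res3 <- residualize(sc3, demo)
  expect_lt(abs(cor(res3$f1, demo$age[match(res3$user_id, demo$user_id)])),
            1e-8)
})

test_that("targets rank deterministically by metric", {
  reports <- tibble::tibble(outcome = c("a", "b", "c"),
                            metric = "pearson_r",
                            mean = c(0.23, 0.09, 0.22))
  rk <- rank_targets(reports, top_n = 1)
  expect_identical(rk$name, c("a", "c", "b"))
  expect_identical(rk$end, c("top", NA, "bottom"))

  single <- rank_targets(tibble::tibble(outcome = "only", metric = "auc",
                                        mean = 60))
  expect_identical(single$end, "top")

  mixed <- dplyr::bind_rows(reports,
                            tibble::tibble(outcome = "d", metric = "auc",
                                           mean = 55))
  expect_error(rank_targets(mixed), "mixed metrics")

  # ties break by name
  tied <- tibble::tibble(outcome = c("zz", "aa"), metric = "pearson_r",
                         mean = c(0.5, 0.5))
  expect_identical(rank_targets(tied)$name, c("aa", "zz"))
})
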