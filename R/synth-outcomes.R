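#' Generate per-user outcomes from planted traits
#'
#' Each continuous outcome is `beta_traits %*% trait + beta_age * age_z +
#' beta_gender * gender + noise`, using window-0 traits. Binary outcomes
#' threshold the latent continuous value at its median (balanced classes).
#' Income-style outcomes should be specified on the log scale, matching the
#' convention of modelling skewed income logarithmically.
#'
#' @param pop A [generate_population()] result.
#' @param config The generating [synth_config()].
#' @return A tibble with `user_id`, `age`, `gender`, and one column per
#'   outcome, with attribute `theoretical_r2`: a named vector of each
#'   continuous outcome's population R-squared implied by the coefficients,
#'   trait correlation and noise variance.
#' @export
generate_outcomes <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "synth_population"))
  specs <- config$outcome_specs
  if (length(specs) == 0L) abort("outcome_specs is empty")
  k <- config$n_factors
  withr::with_seed(derive_seed(config$seed, 3L), {
    traits <- pop$traits[[1L]]
    demo <- pop$demographics
    age_z <- as.numeric(scale(demo$age))
    out <- demo
    r2 <- numeric(0)
    p_f <- config$female_fraction
    for (spec in specs) {
      if (length(spec$beta_traits) != k)
        abort(sprintf("outcome '%s': coefficient length %d does not match k = %d",
                      spec$name, length(spec$beta_traits), k))
      signal <- drop(traits %*% spec$beta_traits) +
        spec$beta_age * age_z + spec$beta_gender * demo$gender
      y <- signal + rnorm(nrow(demo), sd = sqrt(spec$noise_var))
      # Population signal variance: traits ~ MVN(0, Phi), demographics treated
      # as independent of traits; gender is Bernoulli(p).
      var_signal <- drop(t(spec$beta_traits) %*% pop$trait_corr %*% spec$beta_traits) +
        spec$beta_age^2 + spec$beta_gender^2 * p_f * (1 - p_f)
      denom <- var_signal + spec$noise_var
      r2[spec$name] <- if (denom > 0) var_signal / denom else NA_real_
      if (spec$type == "binary") {
        y <- as.integer(y > median(y))
        r2[spec$name] <- NA_real_
      }
      out[[spec$name]] <- y
    }
    attr(out, "theoretical_r2") <- r2
    out
  })
}

#' Generate a sparse user-likes matrix with planted block structure
#'
#' Items are partitioned into `n_clusters` blocks; each user belongs to one
#' cluster (the trait-space direction they project on most, drawn in
#' [generate_population()]). A user likes an item of their own cluster with
#' probability `within_p` and any other item with probability `background_p`.
#'
#' @param pop A [generate_population()] result.
#' @param config The generating [synth_config()].
#' @return A tibble of triplets (`user_id`, `item_id`, `value` = 1), with
#'   attributes `item_cluster` and `user_cluster` (the planted assignments)
#'   and `n_items`.
#' @export
generate_likes <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "synth_population"))
  ls <- config$likes_specs
  if (is.null(ls)) abort("likes_specs is missing from the configuration")
  if (ls$within_p < ls$background_p)
    abort("within_p must be at least background_p", class = "wordtraits_config_error")
  withr::with_seed(derive_seed(config$seed, 4L), {
    n <- config$n_users
    item_cluster <- pop$likes_truth$item_cluster
    user_cluster <- pop$likes_truth$user_cluster
    # n x n_items probability matrix exploiting the block structure.
    same <- outer(user_cluster, item_cluster, "==")
    p <- ifelse(same, ls$within_p, ls$background_p)
    hit <- matrix(runif(length(p)) < p, nrow = n)
    idx <- which(hit, arr.ind = TRUE)
    likes <- tibble(
      user_id = pop$demographics$user_id[idx[, 1L]],
      item_id = sprintf("item%04d", idx[, 2L]),
      value = 1L
    )
    likes <- dplyr::arrange(likes, .data$user_id, .data$item_id)
    attr(likes, "item_cluster") <- item_cluster
    attr(likes, "user_cluster") <- user_cluster
    attr(likes, "n_items") <- ls$n_items
    likes
  })
}
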