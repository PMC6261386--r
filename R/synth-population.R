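#' Generate a synthetic population with planted latent traits
#'
#' Draws per-user latent traits (window 0) from a zero-mean, unit-variance
#' multivariate normal with the configured factor correlation; traits in later
#' windows follow a stationary AR(1) with coefficient `stability_rho`, so that
#' `cor(trait_t, trait_0) = rho^t` in expectation. Each factor receives
#' `markers_per_factor` disjoint marker words with loadings of magnitude
#' `loading_magnitude` and evenly split signs; all other loadings are zero.
#' Ages follow a shifted log-normal matched to the configured median and mean,
#' truncated to 13-65 years by resampling.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_population` with elements
#'   `traits` (list of `n_users x k` matrices, one per window),
#'   `demographics` (tibble `user_id`, `age`, `gender`; gender is a 0/1
#'   female indicator), `true_loadings` (`vocab_size x k`),
#'   `baseline_logfreq`, `vocabulary` (word strings, rank order),
#'   `trait_corr`, `likes_truth`, and the generating `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_users; k <- cfg$n_factors; V <- cfg$vocab_size
    Phi <- trait_correlation(cfg)
    R <- chol(Phi)
    draw_traits <- function() matrix(rnorm(n * k), n, k) %*% R
    traits <- vector("list", cfg$n_windows)
    traits[[1]] <- draw_traits()
    rho <- cfg$stability_rho
    if (cfg$n_windows > 1) {
      for (w in 2:cfg$n_windows) {
        innov <- if (rho < 1) sqrt(1 - rho^2) * draw_traits() else 0
        traits[[w]] <- rho * traits[[w - 1]] + innov
      }
    }
    names(traits) <- paste0("window_", seq_len(cfg$n_windows) - 1L)

    demographics <- tibble(
      user_id = sprintf("u%05d", seq_len(n)),
      age = draw_ages(n, cfg$age_params),
      gender = rbinom(n, 1L, cfg$female_fraction)
    )

    vocabulary <- sprintf("w%04d", seq_len(V))
    ranks <- seq_len(V)
    logfreq <- -cfg$zipf_exponent * log(ranks)
    baseline_logfreq <- logfreq - log(sum(exp(logfreq)))

    # Marker placement is a structural property of the configuration, not a
    # random draw: markers are spread deterministically across the frequency
    # spectrum and interleaved across factors, so two populations generated
    # from the same configuration (different seeds) share one word-trait
    # structure and can serve as training and held-out samples.
    n_mark <- cfg$markers_per_factor * k
    pool <- unique(as.integer(round(seq(1, V, length.out = n_mark))))
    pool <- sort(c(pool, setdiff(seq_len(V), pool))[seq_len(n_mark)])
    true_loadings <- matrix(0, V, k,
                            dimnames = list(vocabulary, paste0("f", seq_len(k))))
    for (f in seq_len(k)) {
      ids <- pool[seq(f, n_mark, by = k)]
      signs <- rep_len(c(1, -1), length(ids))
      true_loadings[ids, f] <- signs * cfg$loading_magnitude
    }

    likes_truth <- NULL
    if (!is.null(cfg$likes_specs)) {
      ls <- cfg$likes_specs
      item_cluster <- rep(seq_len(ls$n_clusters), length.out = ls$n_items)
      item_cluster <- sort(item_cluster)
      # Each cluster attracts users through a random direction in trait space;
      # a user's (hard) cluster is the direction their traits project on most.
      dirs <- matrix(rnorm(k * ls$n_clusters), k, ls$n_clusters)
      dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
      proj <- traits[[1]] %*% dirs
      user_cluster <- max.col(proj, ties.method = "first")
      likes_truth <- list(item_cluster = item_cluster, user_cluster = user_cluster)
    }

    structure(list(
      traits = traits, demographics = demographics,
      true_loadings = true_loadings, baseline_logfreq = baseline_logfreq,
      vocabulary = vocabulary, trait_corr = Phi,
      likes_truth = likes_truth, config = cfg
    ), class = "synth_population")
  })
}

# Shifted log-normal ages: age = 13 + X with X log-normal truncated at the
# cap (resampling). mu/sigma are solved numerically so that the *truncated*
# distribution hits the target median and mean.
draw_ages <- function(n, age_params, min_age = 13, max_age = 65) {
  U <- max_age - min_age
  m <- age_params$median - min_age
  mt <- age_params$mean - min_age
  obj <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    FU <- stats::plnorm(U, mu, s)
    med <- stats::qlnorm(0.5 * FU, mu, s)
    mean_tr <- exp(mu + s^2 / 2) * pnorm((log(U) - mu - s^2) / s) / FU
    (med - m)^2 + (mean_tr - mt)^2
  }
  par <- stats::optim(c(log(m), log(0.8)), obj)$par
  mu <- par[1]; sigma <- exp(par[2])
  age <- min_age + rlnorm(n, mu, sigma)
  bad <- which(age > max_age)
  while (length(bad) > 0L) {
    age[bad] <- min_age + rlnorm(length(bad), mu, sigma)
    bad <- bad[age[bad] > max_age]
  }
  age
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf("<synth_population> %d users, %d words, k = %d, %d window(s)\n",
              x$config$n_users, x$config$vocab_size, x$config$n_factors,
              x$config$n_windows))
  invisible(x)
}
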