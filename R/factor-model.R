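#' Fit the latent factor model M = F L' + E
#'
#' `method = "ml_fa"` maximizes the Gaussian factor-model likelihood with
#' heteroscedastic residual variances Psi by expectation-maximization on the
#' sample correlation matrix of the standardized user-term matrix. The
#' initialization is deterministic (principal-axis start from the spectral
#' decomposition), and convergence is declared when the relative
#' log-likelihood change drops below `tol`. `method = "svd"` returns the
#' rank-k truncated decomposition as loadings with Psi = 0 — the isotropic
#' special case of the factor model. Both return unrotated loadings with an
#' identity factor correlation; see [rotate_factors()].
#'
#' @param M A `user_term_matrix` (or plain numeric matrix, standardized
#'   internally).
#' @param k Number of factors, `1 <= k < min(n_users, V)`.
#' @param method `"ml_fa"` or `"svd"`.
#' @param seed Integer recorded in the model (estimation itself is
#'   deterministic).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error naming it.
#' @param psi_floor Lower bound on residual variances (Heywood protection).
#' @return An object of class `factor_model`: list with `loadings` (V x k
#'   pattern matrix), `psi`, `phi`, `weights` (V x k regression scoring
#'   weights), `scores` (training-set score tibble), `rotation`,
#'   `method`, `k`, `loglik`, `n_iter`, `converged`, `vocabulary`,
#'   `col_means`, `col_sds`, `transform`, `n_users`, `seed`, and
#'   `unrotated` (loadings, psi, scores kept for re-rotation).
#' @export
fit_factor_analysis <- function(M, k, method = c("ml_fa", "svd"), seed = 1L,
                                tol = 1e-6, max_iter = 2000L, psi_floor = 1e-4) {
  method <- match.arg(method)
  if (!inherits(M, "user_term_matrix")) M <- as_user_term_matrix(M)
  X <- M$standardized
  n <- nrow(X); V <- ncol(X)
  if (k < 1 || k >= min(n, V))
    abort(sprintf("k = %d out of range: need 1 <= k < min(n_users, V) = %d",
                  k, min(n, V)))
  S <- crossprod(X) / (n - 1)

  if (method == "ml_fa") {
    fit <- fa_em(S, k, n, tol = tol, max_iter = max_iter, psi_floor = psi_floor)
  } else {
    es <- eigen(S, symmetric = TRUE)
    L <- es$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(es$values[seq_len(k)], 0)), k)
    fit <- list(loadings = L, psi = rep(0, V),
                loglik = NA_real_, n_iter = 0L, converged = TRUE)
  }
  L <- fix_column_signs(fit$loadings)
  dimnames(L) <- list(M$vocabulary$terms, paste0("f", seq_len(k)))
  psi <- fit$psi
  W <- scoring_weights(L, psi, diag(k))
  Fhat <- X %*% W
  model <- structure(list(
    loadings = L, psi = psi, phi = diag(k), weights = W,
    scores = scores_tibble(M$users, Fhat),
    rotation = "none", method = method, k = as.integer(k),
    loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
    vocabulary = M$vocabulary, col_means = M$col_means, col_sds = M$col_sds,
    transform = M$transform, n_users = n, seed = as.integer(seed),
    unrotated = list(loadings = L, weights = W, scores = Fhat)
  ), class = "factor_model")
  model
}

# EM for maximum-likelihood factor analysis on a covariance/correlation
# matrix S (Rubin & Thayer). All per-iteration algebra is O(V^2 k) through
# the Woodbury identity. Returns the loadings at the highest log-likelihood.
fa_em <- function(S, k, n, tol = 1e-6, max_iter = 2000L, psi_floor = 1e-4,
                  L0 = NULL, psi0 = NULL) {
  V <- ncol(S)
  if (is.null(L0)) {
    es <- eigen(S, symmetric = TRUE)
    L <- es$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(es$values[seq_len(k)], psi_floor)), k)
  } else L <- L0
  psi <- psi0 %||% pmax(diag(S) - rowSums(L^2), psi_floor)
  dS <- diag(S)
  ll_of <- function(L, psi) {
    A <- t(L / psi)                              # k x V, = L' Psi^-1
    Mk <- diag(k) + A %*% L
    G <- solve(Mk)
    logdet <- sum(log(psi)) + determinant(Mk, logarithm = TRUE)$modulus
    ASA <- A %*% S %*% t(A)
    trace <- sum(dS / psi) - sum(G * ASA)
    -n / 2 * (V * log(2 * pi) + as.numeric(logdet) + trace)
  }
  ll <- ll_of(L, psi)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- t(L / psi)
    G <- solve(diag(k) + A %*% L)                # symmetric k x k
    B <- G %*% A                                 # beta = L' Sigma^-1, k x V
    BS <- B %*% S                                # k x V
    Delta <- G + BS %*% t(B)                     # E[ff'] = I - B L + B S B'
    Lnew <- t(solve(Delta, BS))                  # V x k
    psi_new <- pmax(dS - rowSums(Lnew * t(BS)), psi_floor)
    L <- Lnew; psi <- psi_new
    ll_new <- ll_of(L, psi)
    if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1e-10)) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  if (!converged)
    abort(sprintf("EM for factor analysis did not converge within %d iterations",
                  max_iter), class = "wordtraits_convergence_error")
  list(loadings = L, psi = psi, loglik = ll, n_iter = it, converged = converged)
}

# Sign convention: make the largest-magnitude entry of each column positive.
fix_column_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    m <- which.max(abs(L[, j]))
    if (L[m, j] < 0) L[, j] <- -L[, j]
  }
  L
}

# Thurstone regression scoring weights W (V x k): F_hat = M_std W with
# W = Sigma^-1 L Phi = Psi^-1 L (Phi^-1 + L' Psi^-1 L)^-1 via Woodbury.
# For Psi = 0 (truncated SVD) this degenerates to least-squares projection.
scoring_weights <- function(L, psi, phi) {
  k <- ncol(L)
  if (all(psi <= 0)) {
    # pattern * phi is the structure matrix; project onto the column space
    return(L %*% solve(crossprod(L)))
  }
  Lp <- L / psi
  Lp %*% solve(solve(phi) + crossprod(L, Lp))
}

#' Fitted covariance implied by a factor model
#'
#' `L Phi L' + diag(Psi)`; invariant under rotation.
#'
#' @param model A `factor_model`.
#' @return V x V matrix.
#' @export
fitted_covariance <- function(model) {
  model$loadings %*% model$phi %*% t(model$loadings) + diag(model$psi)
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> k = %d, %s estimation, %s rotation, %d users x %d terms\n",
              x$k, x$method, x$rotation, x$n_users, nrow(x$loadings)))
  if (is.finite(x$loglik %||% NA))
    cat(sprintf("  log-likelihood %.2f after %d EM iterations\n", x$loglik, x$n_iter))
  invisible(x)
}

#' @describeIn fit_factor_analysis Tidy the loadings into a long tibble
#'   (`term`, `factor`, `loading`, `communality`, `uniqueness`).
#' @param x A `factor_model`.
#' @param ... Unused.
#' @export
tidy.factor_model <- function(x, ...) {
  L <- x$loadings
  comm <- rowSums((L %*% x$phi) * L)
  tibble(term = rep(rownames(L), ncol(L)),
         factor = rep(seq_len(ncol(L)), each = nrow(L)),
         loading = as.numeric(L),
         communality = rep(comm, ncol(L)),
         uniqueness = rep(x$psi, ncol(L)))
}

#' @describeIn fit_factor_analysis One-row model summary.
#' @export
glance.factor_model <- function(x, ...) {
  tibble(k = x$k, method = x$method, rotation = x$rotation,
         n_users = x$n_users, n_terms = nrow(x$loadings),
         loglik = x$loglik, n_iter = x$n_iter, converged = x$converged)
}
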