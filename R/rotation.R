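# Orthomax family of orthogonal rotations (gamma = 1: varimax, gamma = k/2:
# equamax, gamma = 0: quartimax), with optional Kaiser row normalization.
# Iterative SVD algorithm (the same scheme stats::varimax uses, generalized
# to arbitrary gamma).
orthomax_rotation <- function(L, gamma = 1, normalize = TRUE, eps = 1e-6,
                              max_iter = 1000L) {
  k <- ncol(L)
  if (k < 2) return(list(loadings = L, rotmat = diag(k)))
  sc <- rep(1, nrow(L))
  if (normalize) {
    sc <- sqrt(rowSums(L^2))
    sc[sc < 1e-12] <- 1
    L <- L / sc
  }
  p <- nrow(L)
  R <- diag(k)
  d <- 0
  for (i in seq_len(max_iter)) {
    z <- L %*% R
    B <- crossprod(L, z^3 - gamma * z %*% diag(colSums(z^2), k) / p)
    sv <- svd(B)
    R <- sv$u %*% t(sv$v)
    d_old <- d
    d <- sum(sv$d)
    if (d < d_old * (1 + eps)) break
  }
  list(loadings = (L %*% R) * sc, rotmat = R)
}

# Promax oblique target rotation applied to orthogonally rotated loadings.
# The target is the element-wise power of the orthogonal solution; the
# transformation is the column-normalized least-squares map onto it. Returns
# pattern loadings Lambda = L U and factor correlations Phi = (U'U)^-1, so
# Lambda Phi Lambda' = L L' exactly.
promax_rotation <- function(L, power = 4) {
  k <- ncol(L)
  if (k < 2) return(list(loadings = L, phi = diag(k), trans = diag(k)))
  Q <- L * abs(L)^(power - 1)
  U <- solve(crossprod(L), crossprod(L, Q))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), k)
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  list(loadings = L %*% U, phi = phi, trans = U)
}

#' Rotate a fitted factor model
#'
#' Orthogonal rotations (`varimax`, `equamax`) return rotated loadings with an
#' identity factor correlation. `promax` first applies the configured initial
#' orthogonal rotation (equamax by default, so the final model is a promax
#' rotation on top of an equamax solution) and then the oblique promax target
#' rotation with the given power, returning pattern loadings and the factor
#' correlation matrix. The fitted covariance `L Phi L' + Psi` is unchanged by
#' any rotation. Scoring weights and training scores are recomputed for the
#' rotated factors.
#'
#' @param model An unrotated or orthogonally rotated `factor_model`.
#' @param method `"varimax"`, `"equamax"`, or `"promax"`.
#' @param promax_power Power of the promax target (default 4).
#' @param initial_orthogonal Orthogonal rotation applied before promax.
#' @param normalize Kaiser row normalization for the orthogonal step.
#' @return The rotated `factor_model`.
#' @export
rotate_factors <- function(model, method = c("promax", "varimax", "equamax"),
                           promax_power = 4,
                           initial_orthogonal = c("equamax", "varimax"),
                           normalize = TRUE) {
  method <- match.arg(method)
  initial_orthogonal <- match.arg(initial_orthogonal)
  stopifnot(inherits(model, "factor_model"))
  if (!model$rotation %in% c("none", "varimax", "equamax"))
    abort("model is already obliquely rotated; refit or rotate from the unrotated solution")
  if (promax_power < 1) abort("promax_power must be at least 1")
  L0 <- model$unrotated$loadings
  F0 <- model$unrotated$scores
  k <- ncol(L0)
  gamma_of <- function(m) if (m == "varimax") 1 else k / 2
  if (method %in% c("varimax", "equamax")) {
    or <- orthomax_rotation(L0, gamma = gamma_of(method), normalize = normalize)
    L <- or$loadings
    phi <- diag(k)
    trans <- or$rotmat          # F_rot = F0 %*% R for orthonormal R
  } else {
    or <- orthomax_rotation(L0, gamma = gamma_of(initial_orthogonal),
                            normalize = normalize)
    pr <- promax_rotation(or$loadings, power = promax_power)
    L <- pr$loadings
    phi <- pr$phi
    # Lambda = L0 (R U); regression scores transform by U (U'U)^-1 applied
    # after the orthogonal rotation.
    trans <- or$rotmat %*% pr$trans %*% solve(crossprod(pr$trans))
  }
  sgn <- numeric(k)
  for (j in seq_len(k)) {
    m <- which.max(abs(L[, j]))
    sgn[j] <- if (L[m, j] < 0) -1 else 1
  }
  L <- sweep(L, 2L, sgn, "*")
  phi <- diag(sgn, k) %*% phi %*% diag(sgn, k)
  trans <- sweep(trans, 2L, sgn, "*")
  dimnames(L) <- dimnames(model$unrotated$loadings)
  Fhat <- F0 %*% trans
  model$loadings <- L
  model$phi <- phi
  # W_rot = W0 %*% trans: identical to scoring_weights(L, psi, phi) for the
  # ML model, and keeps the Psi = 0 (SVD) case consistent with the scores.
  model$weights <- model$unrotated$weights %*% trans
  model$scores <- scores_tibble(model$scores$user_id, Fhat)
  model$rotation <- if (method == "promax")
    paste0("promax(", initial_orthogonal, ", m=", promax_power, ")") else method
  model
}
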