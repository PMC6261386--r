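#' Solve the minimum-cost assignment problem (Hungarian algorithm)
#'
#' Exact O(n^3) primal-dual (potentials + shortest augmenting path)
#' implementation for square cost matrices.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) abort("cost matrix must be square")
  if (any(!is.finite(cost))) abort("cost matrix must be finite")
  if (n == 0L) return(integer(0))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials; index 1 is the dummy column 0
  p <- integer(n + 1L)     # p[j + 1]: row currently matched to column j
  way <- integer(n)        # way[j]: previous column (0-based) on the path
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      usedj <- which(used) - 1L
      for (j in usedj) {
        u[p[j + 1L]] <- u[p[j + 1L]] + delta
        v[j + 1L] <- v[j + 1L] - delta
      }
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[p[j + 1L]] <- j
  out
}

#' Align two sets of factor scores
#'
#' Builds the cost matrix `1 - |pearson(a_i, b_j)|` and solves the optimal
#' assignment with the Hungarian algorithm. Factor sign is arbitrary, so the
#' match quality uses absolute correlations; the signs of the matched
#' correlations are reported so aligned scores can be compared directionally.
#'
#' @param scores_a,scores_b Score tibbles (`user_id`, `f1`..`fk`) or numeric
#'   matrices over the same users.
#' @return An object of class `factor_alignment`: list with `permutation`
#'   (`permutation[i]` is the column of `scores_b` matched to factor `i` of
#'   `scores_a`), `signs`, `matched_abs_corr`, `mean_abs_corr`, and the full
#'   correlation matrix `corr`.
#' @export
align_factors <- function(scores_a, scores_b) {
  a <- score_matrix(scores_a)
  b <- score_matrix(scores_b)
  if (!identical(a$users, b$users)) {
    idx <- match(a$users, b$users)
    if (anyNA(idx)) abort("score sets cover different users")
    b$F <- b$F[idx, , drop = FALSE]
  }
  if (ncol(a$F) != ncol(b$F)) abort("score sets have different numbers of factors")
  const_a <- apply(a$F, 2L, sd) < 1e-12
  const_b <- apply(b$F, 2L, sd) < 1e-12
  if (any(const_a) || any(const_b))
    warn("constant score column(s): correlations treated as 0")
  R <- suppressWarnings(cor(a$F, b$F))
  R[!is.finite(R)] <- 0
  perm <- solve_assignment(1 - abs(R))
  matched <- R[cbind(seq_len(ncol(a$F)), perm)]
  signs <- ifelse(matched < 0, -1, 1)
  structure(list(permutation = perm, signs = signs,
                 matched_abs_corr = abs(matched),
                 mean_abs_corr = mean(abs(matched)),
                 corr = R),
            class = "factor_alignment")
}

#' @export
print.factor_alignment <- function(x, ...) {
  cat(sprintf("<factor_alignment> k = %d, mean |r| = %.3f\n",
              length(x$permutation), x$mean_abs_corr))
  cat("  permutation:", paste(x$permutation, collapse = " "),
      " signs:", paste(ifelse(x$signs > 0, "+", "-"), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn align_factors Tidy per-factor match table.
#' @param x A `factor_alignment`.
#' @param ... Unused.
#' @export
tidy.factor_alignment <- function(x, ...) {
  tibble(factor_a = seq_along(x$permutation), factor_b = x$permutation,
         sign = x$signs, abs_corr = x$matched_abs_corr)
}
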