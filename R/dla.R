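#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: after sorting, `q_(i) = min_(j >= i) p_(j) * m / j`
#' clipped at 1, mapped back to input order (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @param alpha Significance level for the rejection flags.
#' @return List with `qvalues` and logical `significant` (`q <= alpha`).
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03), alpha = 0.05)
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L)
    return(list(qvalues = numeric(0), significant = logical(0)))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    abort("p-values must lie in (0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  list(qvalues = q, significant = q <= alpha)
}

#' Differential language analysis: correlate every word with every factor
#'
#' Pearson correlation between each term's relative-frequency column and each
#' factor's scores, with two-sided p-values from the t distribution and
#' Benjamini-Hochberg correction (per-factor families by default). Terms with
#' constant columns are emitted with `r = 0` and flagged degenerate, excluded
#' from the FDR family. Frequency tiers (low / moderate / frequent) are
#' corpus-frequency terciles.
#'
#' @param M A `user_term_matrix`.
#' @param scores Score tibble aligned with `M`'s users.
#' @param alpha FDR level.
#' @param family `"per_factor"` (default) or `"global"` BH family.
#' @return A tibble of class `dla_result`: one row per (term, factor) with
#'   `term`, `factor`, `r`, `p`, `q`, `freq_tier`, `significant`,
#'   `degenerate`.
#' @export
correlate_words <- function(M, scores, alpha = 0.05,
                            family = c("per_factor", "global")) {
  family <- match.arg(family)
  stopifnot(inherits(M, "user_term_matrix"))
  sm <- score_matrix(scores)
  if (!identical(as.character(M$users), sm$users))
    abort("row users of the matrix and the scores are not aligned")
  X <- M$rel_freq
  Fm <- sm$F
  n <- nrow(X)
  sds <- apply(X, 2L, sd)
  degenerate <- !is.finite(sds) | sds < 1e-12
  r <- suppressWarnings(cor(X, Fm))
  r[degenerate, ] <- 0
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  tiers <- cut(rank(M$corpus_term_freq, ties.method = "first"),
               breaks = quantile(rank(M$corpus_term_freq, ties.method = "first"),
                                 c(0, 1 / 3, 2 / 3, 1)),
               labels = c("low", "moderate", "frequent"),
               include.lowest = TRUE)

  k <- ncol(Fm)
  res <- tibble(
    term = rep(M$vocabulary$terms, k),
    factor = rep(seq_len(k), each = ncol(X)),
    r = as.numeric(r),
    p = as.numeric(p),
    q = NA_real_,
    freq_tier = rep(as.character(tiers), k),
    significant = FALSE,
    degenerate = rep(degenerate, k)
  )
  if (family == "per_factor") {
    for (f in seq_len(k)) {
      idx <- which(res$factor == f & !res$degenerate)
      if (length(idx)) {
        adj <- bh_fdr(res$p[idx], alpha)
        res$q[idx] <- adj$qvalues
        res$significant[idx] <- adj$significant
      }
    }
  } else {
    idx <- which(!res$degenerate)
    adj <- bh_fdr(res$p[idx], alpha)
    res$q[idx] <- adj$qvalues
    res$significant[idx] <- adj$significant
  }
  res$p[res$degenerate] <- NA_real_
  attr(res, "alpha") <- alpha
  attr(res, "family") <- family
  class(res) <- c("dla_result", class(res))
  res
}

#' Correlate factor scores with an outcomes table
#'
#' Pearson correlations between every factor and every numeric column of the
#' outcomes table over the inner join of users, missing values dropped
#' pairwise, with Benjamini-Hochberg correction across the whole
#' factor-by-outcome family.
#'
#' @param scores Score tibble (`user_id`, `f1`..`fk`).
#' @param table Tibble with `user_id` and numeric outcome columns.
#' @return Tibble with `factor`, `outcome`, `r`, `p`, `q`, `n`.
#' @export
correlate_scores_with_table <- function(scores, table) {
  stopifnot("user_id" %in% names(table))
  joined <- dplyr::inner_join(scores, table, by = "user_id")
  if (nrow(joined) < 3) abort("fewer than 3 users overlap between scores and table")
  fac_cols <- setdiff(names(scores), "user_id")
  out_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "user_id")
  grid <- tidyr::expand_grid(factor = seq_along(fac_cols), outcome = out_cols)
  rows <- purrr::pmap(grid, function(factor, outcome) {
    x <- joined[[fac_cols[factor]]]
    y <- joined[[outcome]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(tibble(factor = factor, outcome = outcome, r = NA_real_,
                    p = NA_real_, n = n))
    ct <- stats::cor.test(x[ok], y[ok])
    tibble(factor = factor, outcome = outcome,
           r = unname(ct$estimate), p = max(ct$p.value, .Machine$double.xmin),
           n = n)
  })
  res <- dplyr::bind_rows(rows)
  ok <- !is.na(res$p)
  res$q <- NA_real_
  if (any(ok)) res$q[ok] <- bh_fdr(res$p[ok])$qvalues
  res
}

#' Top correlated words for a factor
#'
#' Significant rows only, sorted by correlation (descending for
#' `direction = "positive"`, ascending for `"negative"`), deterministic
#' tie-break by term.
#'
#' @param dla A [correlate_words()] result.
#' @param factor Factor index.
#' @param n Maximum number of words.
#' @param direction `"positive"` or `"negative"`.
#' @return Tibble (`term`, `r`, `freq_tier`).
#' @export
top_words <- function(dla, factor, n = 25, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(inherits(dla, "dla_result"))
  if (!factor %in% unique(dla$factor)) abort("factor index out of range")
  f <- factor
  rows <- dla[dla$factor == f & dla$significant & !dla$degenerate, , drop = FALSE]
  ord <- if (direction == "positive") order(-rows$r, rows$term)
         else order(rows$r, rows$term)
  rows <- rows[ord, , drop = FALSE]
  tibble::as_tibble(head(rows[c("term", "r", "freq_tier")], n))
}
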