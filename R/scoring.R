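#' Score users with a fitted factor model
#'
#' Thurstone regression scores: the new matrix (built with the model's
#' vocabulary) is standardized with the model's stored column means and
#' standard deviations, then multiplied by the model's scoring weights.
#' Scoring the fitting matrix reproduces the fitted scores.
#'
#' @param model A `factor_model`.
#' @param M_new A `user_term_matrix` built with the model's vocabulary.
#' @return A score tibble (`user_id`, `f1`..`fk`).
#' @export
score_users <- function(model, M_new) {
  stopifnot(inherits(model, "factor_model"))
  if (!inherits(M_new, "user_term_matrix")) M_new <- as_user_term_matrix(M_new)
  new_terms <- M_new$vocabulary$terms
  if (!identical(new_terms, model$vocabulary$terms)) {
    missing <- setdiff(model$vocabulary$terms, new_terms)
    abort(paste0("vocabulary mismatch between model and new matrix",
                 if (length(missing))
                   paste0("; missing terms: ",
                          paste(head(missing, 10L), collapse = ", "),
                          if (length(missing) > 10L) ", ...")),
          class = "wordtraits_vocab_error")
  }
  if (!identical(M_new$transform, model$transform))
    abort("transform mismatch between model and new matrix")
  std <- sweep(sweep(M_new$rel_freq, 2L, model$col_means, "-"),
               2L, model$col_sds, "/")
  scores_tibble(M_new$users, std %*% model$weights)
}

#' Suggest the number of factors by scree acceleration
#'
#' Computes the eigenvalues of the column correlation matrix and locates the
#' scree elbow by the acceleration (second difference) of the eigenvalue
#' profile: `af_i = (lambda_{i+1} - lambda_i) - (lambda_i - lambda_{i-1})`
#' for `i = 2 .. V-1`; the suggestion is `argmax(af) - 1`, ties broken toward
#' the smaller index.
#'
#' @param M A `user_term_matrix` or numeric matrix with at least 4 columns.
#' @return An integer; attribute `low_confidence` is `TRUE` when the
#'   spectrum carries no curvature (all accelerations equal), and attribute
#'   `eigenvalues` holds the spectrum.
#' @export
suggest_n_factors <- function(M) {
  if (!inherits(M, "user_term_matrix")) M <- as_user_term_matrix(M)
  X <- M$standardized
  if (ncol(X) < 4) abort("need at least 4 observed variables for a scree test")
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  out <- scree_acceleration(ev)
  attr(out, "eigenvalues") <- ev
  out
}

#' @describeIn suggest_n_factors Acceleration rule applied to a given
#'   eigenvalue sequence.
#' @param eigenvalues Non-increasing numeric vector, length at least 4.
#' @export
scree_acceleration <- function(eigenvalues) {
  V <- length(eigenvalues)
  if (V < 4) abort("need at least 4 eigenvalues")
  i <- 2:(V - 1)
  af <- (eigenvalues[i + 1] - eigenvalues[i]) - (eigenvalues[i] - eigenvalues[i - 1])
  best <- which.max(af)                 # first max: ties toward smaller index
  out <- as.integer(i[best] - 1L)
  attr(out, "low_confidence") <- diff(range(af)) < 1e-10
  out
}
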