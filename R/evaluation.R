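#' Cluster user likes with non-negative matrix factorization
#'
#' Restricts the binary user-likes matrix to the most popular items,
#' factorizes it at the requested rank with multiplicative (Lee-Seung,
#' Frobenius) updates from a seeded random start, and derives one binary
#' prediction target per cluster: a user is labelled 1 for cluster c when
#' their user-side weight exceeds that cluster's median user weight (balanced
#' targets by construction).
#'
#' @param likes Triplet tibble (`user_id`, `item_id`, `value`) or sparse
#'   users x items matrix.
#' @param top_items Number of most popular items retained.
#' @param n_clusters Factorization rank.
#' @param seed Seed for the random initialization.
#' @param max_iter,tol Stopping rule on the relative change of the
#'   reconstruction error.
#' @return An object of class `like_clusters`: list with `item_membership`
#'   (items x clusters), `user_weights`, `user_labels` (users x clusters,
#'   0/1 tibble with `user_id`), `item_assignment` (hard argmax cluster per
#'   item), `top_items` (list of item rankings per cluster), `items`,
#'   `users`.
#' @export
cluster_likes <- function(likes, top_items = 10000, n_clusters = 20, seed = 1L,
                          max_iter = 500L, tol = 1e-5) {
  if (n_clusters < 2) abort("n_clusters must be at least 2")
  X <- likes_to_matrix(likes)
  if (nrow(X) == 0L || ncol(X) == 0L) abort("likes matrix is empty")
  pop <- Matrix::colSums(X)
  keep <- order(-pop, colnames(X), method = "radix")[seq_len(min(top_items, ncol(X)))]
  keep <- sort(keep)
  X <- X[, keep, drop = FALSE]
  if (n_clusters > min(dim(X)))
    abort("n_clusters exceeds the matrix dimensions")
  Xd <- as.matrix(X)
  nmf <- withr::with_seed(derive_seed(seed, 17L), {
    nmf_frobenius(Xd, n_clusters, max_iter = max_iter, tol = tol)
  })
  W <- nmf$W; H <- nmf$H
  med <- apply(W, 2L, median)
  labels <- sweep(W, 2L, med, ">") * 1L
  item_membership <- t(H)
  colnames(item_membership) <- paste0("c", seq_len(n_clusters))
  rownames(item_membership) <- colnames(Xd)
  top_items_list <- lapply(seq_len(n_clusters), function(c) {
    ord <- order(-item_membership[, c], rownames(item_membership),
                 method = "radix")
    tibble(item_id = rownames(item_membership)[ord],
           membership = item_membership[ord, c])
  })
  structure(list(
    n_clusters = as.integer(n_clusters),
    item_membership = item_membership,
    user_weights = W,
    user_labels = dplyr::bind_cols(tibble(user_id = rownames(Xd)),
                                   tibble::as_tibble(labels, .name_repair = ~paste0("c", seq_len(n_clusters)))),
    item_assignment = max.col(item_membership, ties.method = "first"),
    top_items = top_items_list,
    items = colnames(Xd), users = rownames(Xd),
    n_iter = nmf$n_iter, rel_err = nmf$rel_err, seed = as.integer(seed)
  ), class = "like_clusters")
}

likes_to_matrix <- function(likes) {
  if (inherits(likes, "Matrix") || is.matrix(likes)) {
    X <- Matrix::Matrix(likes, sparse = TRUE)
    if (is.null(rownames(X))) rownames(X) <- paste0("u", seq_len(nrow(X)))
    if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
    return(X)
  }
  stopifnot(all(c("user_id", "item_id") %in% names(likes)))
  users <- sort(unique(likes$user_id))
  items <- sort(unique(likes$item_id))
  Matrix::sparseMatrix(i = match(likes$user_id, users),
                       j = match(likes$item_id, items),
                       x = 1, dims = c(length(users), length(items)),
                       dimnames = list(users, items))
}

# Multiplicative-update NMF minimizing ||X - W H||_F.
nmf_frobenius <- function(X, k, max_iter = 500L, tol = 1e-5, eps = 1e-10) {
  n <- nrow(X); m <- ncol(X)
  scale0 <- sqrt(mean(X) / k)
  W <- matrix(runif(n * k, 0.1, 1) * scale0, n, k)
  H <- matrix(runif(k * m, 0.1, 1) * scale0, k, m)
  err0 <- sqrt(sum(X^2))
  err_prev <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((X - W %*% H)^2))
      if (is.finite(err_prev) && abs(err_prev - err) < tol * err0) break
      err_prev <- err
    }
  }
  list(W = W, H = H, n_iter = it, rel_err = err_prev / err0)
}

#' Purity of a hard clustering against a planted assignment
#'
#' @param assignment Integer cluster labels from the model.
#' @param truth Planted cluster labels (same length).
#' @return Fraction of elements in the majority true class of their assigned
#'   cluster.
#' @export
cluster_purity <- function(assignment, truth) {
  stopifnot(length(assignment) == length(truth))
  tab <- table(assignment, truth)
  sum(apply(tab, 1L, max)) / length(truth)
}

#' @export
print.like_clusters <- function(x, ...) {
  cat(sprintf("<like_clusters> %d clusters over %d users x %d items (NMF, %d iterations)\n",
              x$n_clusters, length(x$users), length(x$items), x$n_iter))
  invisible(x)
}

ridge_lambda_grid <- function() 10^seq(3, -3, length.out = 13)

#' Cross-validated ridge regression of a continuous outcome
#'
#' For each of `n_splits` random train/test partitions, the ridge penalty is
#' chosen by inner 3-fold cross-validated grid search on the training part
#' and performance is the Pearson correlation between held-out predictions
#' and truth. Deterministic given (data, seed), including split membership.
#'
#' @param features Numeric matrix or data frame of predictors (rows = users).
#' @param outcome Continuous outcome vector, row-aligned with `features`.
#' @param n_splits Number of random splits.
#' @param test_fraction Held-out fraction per split.
#' @param seed Integer seed.
#' @param outcome_name,feature_name Labels recorded in the report.
#' @return A one-row tibble of class `prediction_report`: `outcome`,
#'   `features`, `metric`, `mean`, `sd`, `n_splits`, and a `splits`
#'   list-column of per-split values.
#' @export
evaluate_regression <- function(features, outcome, n_splits = 10,
                                test_fraction = 0.25, seed = 1L,
                                outcome_name = "outcome",
                                feature_name = "features") {
  X <- as.matrix(features)
  y <- as.numeric(outcome)
  stopifnot(nrow(X) == length(y))
  if (sd(y) < 1e-12) abort("outcome is constant; Pearson r undefined")
  if (ncol(X) == 1L) X <- cbind(X, X)   # glmnet needs >= 2 columns
  n <- nrow(X)
  vals <- withr::with_seed(derive_seed(seed, 19L), {
    vapply(seq_len(n_splits), function(s) {
      test_idx <- sample.int(n, max(2L, round(test_fraction * n)))
      tr <- setdiff(seq_len(n), test_idx)
      foldid <- sample(rep_len(1:3, length(tr)))
      cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 0,
                              lambda = ridge_lambda_grid(), foldid = foldid,
                              standardize = TRUE)
      pred <- as.numeric(predict(cv, X[test_idx, , drop = FALSE],
                                 s = "lambda.min"))
      if (sd(pred) < 1e-12) 0 else cor(pred, y[test_idx])
    }, 1)
  })
  report_row(outcome_name, feature_name, "pearson_r", vals)
}

#' Cross-validated logistic classification of binary targets
#'
#' One L2-regularized logistic model per target and split, with the penalty
#' grid-searched by inner 3-fold cross-validation; performance is the area
#' under the ROC curve on the held-out part, averaged over targets and
#' splits. Splits whose training part lacks a class for some target are
#' redrawn for that target (logged); targets that are single-class overall
#' are skipped with a warning.
#'
#' @inheritParams evaluate_regression
#' @param labels 0/1 matrix or data frame, one column per target.
#' @return A one-row `prediction_report` (`metric = "auc"`, `mean` on the
#'   0-100 scale averaged over targets and splits) with attribute
#'   `per_target`: tibble of per-target mean AUC.
#' @export
evaluate_classification <- function(features, labels, n_splits = 10,
                                    test_fraction = 0.25, seed = 1L,
                                    outcome_name = "targets",
                                    feature_name = "features") {
  X <- as.matrix(features)
  if (ncol(X) == 1L) X <- cbind(X, X)
  L <- as.matrix(labels)
  stopifnot(nrow(X) == nrow(L))
  target_names <- colnames(L) %||% paste0("target_", seq_len(ncol(L)))
  usable <- vapply(seq_len(ncol(L)), function(j) length(unique(L[, j])) == 2L, TRUE)
  if (any(!usable))
    warn(sprintf("%d single-class target(s) skipped", sum(!usable)))
  n <- nrow(X)
  auc_mat <- withr::with_seed(derive_seed(seed, 23L), {
    sapply(seq_len(n_splits), function(s) {
      test_idx <- sample.int(n, max(2L, round(test_fraction * n)))
      vapply(seq_len(ncol(L)), function(j) {
        if (!usable[j]) return(NA_real_)
        y <- L[, j]
        tries <- 0L
        repeat {
          tr <- setdiff(seq_len(n), test_idx)
          if (length(unique(y[tr])) == 2L && length(unique(y[test_idx])) == 2L) break
          tries <- tries + 1L
          if (tries > 20L) return(NA_real_)
          message("resampling split: training part lacked a class")
          test_idx <- sample.int(n, max(2L, round(test_fraction * n)))
        }
        foldid <- sample(rep_len(1:3, length(tr)))
        cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 0,
                                family = "binomial",
                                lambda = ridge_lambda_grid(), foldid = foldid)
        pred <- as.numeric(predict(cv, X[test_idx, , drop = FALSE],
                                   s = "lambda.min", type = "link"))
        as.numeric(pROC::auc(pROC::roc(y[test_idx], pred, quiet = TRUE,
                                       direction = "<", levels = c(0, 1))))
      }, 1)
    })
  })
  auc_mat <- matrix(auc_mat, nrow = ncol(L))   # targets x splits
  per_split <- 100 * colMeans(auc_mat, na.rm = TRUE)
  out <- report_row(outcome_name, feature_name, "auc", per_split)
  attr(out, "per_target") <- tibble(
    target = target_names,
    mean_auc = 100 * rowMeans(auc_mat, na.rm = TRUE),
    sd_auc = 100 * apply(auc_mat, 1L, sd, na.rm = TRUE)
  )
  out
}

report_row <- function(outcome, features, metric, vals) {
  out <- tibble(outcome = outcome, features = features, metric = metric,
                mean = mean(vals), sd = sd(vals),
                n_splits = length(vals), splits = list(vals))
  class(out) <- c("prediction_report", class(out))
  out
}

#' Append demographic covariates to a feature matrix
#'
#' Column-binds z-scored age and the 0/1 gender indicator. With `features =
#' NULL` the result is the demographics-only baseline feature set.
#'
#' @param features Numeric matrix/data frame (or tibble with `user_id`), or
#'   `NULL`.
#' @param demographics Tibble with `user_id`, `age`, `gender`.
#' @return Numeric matrix with added `age_z` and `gender` columns; users with
#'   missing demographics are dropped (count messaged).
#' @export
add_covariates <- function(features, demographics) {
  demo <- dplyr::distinct(demographics, .data$user_id, .keep_all = TRUE)
  if (!is.null(features) && is.data.frame(features) && "user_id" %in% names(features)) {
    joined <- dplyr::inner_join(features, demo[c("user_id", "age", "gender")],
                                by = "user_id")
    ids <- joined$user_id
    Xf <- as.matrix(joined[setdiff(names(features), "user_id")])
    age <- joined$age; gender <- joined$gender
  } else {
    if (is.null(features)) {
      ids <- demo$user_id
      Xf <- NULL
    } else {
      Xf <- as.matrix(features)
      stopifnot(nrow(Xf) == nrow(demo))
      ids <- demo$user_id
    }
    age <- demo$age; gender <- demo$gender
  }
  ok <- is.finite(age) & is.finite(gender)
  if (any(!ok)) message(sprintf("%d user(s) dropped for missing demographics", sum(!ok)))
  age_z <- (age[ok] - mean(age[ok])) / sd(age[ok])
  out <- cbind(Xf[ok, , drop = FALSE], age_z = age_z, gender = gender[ok])
  rownames(out) <- ids[ok]
  out
}

#' Residualize factor scores on demographics
#'
#' Replaces each factor column by its residual from an ordinary
#' least-squares fit on an intercept, z-scored age and the gender indicator,
#' removing demographic variance from the scores.
#'
#' @param scores Score tibble (`user_id`, `f1`..`fk`).
#' @param demographics Tibble with `user_id`, `age`, `gender`.
#' @return A score tibble of residualized scores (users present in both
#'   inputs).
#' @export
residualize <- function(scores, demographics) {
  joined <- dplyr::inner_join(scores,
                              dplyr::distinct(demographics, .data$user_id,
                                              .keep_all = TRUE),
                              by = "user_id")
  fac_cols <- setdiff(names(scores), "user_id")
  covs <- list(age_z = as.numeric(scale(joined$age)), gender = joined$gender)
  keep <- vapply(covs, function(v) is.finite(sd(v)) && sd(v) > 1e-12, TRUE)
  if (any(!keep)) warn(sprintf("degenerate covariate(s) dropped: %s",
                               paste(names(covs)[!keep], collapse = ", ")))
  Z <- do.call(cbind, covs[keep])
  Fm <- as.matrix(joined[fac_cols])
  res <- if (is.null(Z) || ncol(Z) == 0L) {
    sweep(Fm, 2L, colMeans(Fm))
  } else {
    stats::lm.fit(cbind(1, Z), Fm)$residuals
  }
  scores_tibble(joined$user_id, res)
}

#' Rank prediction targets by performance
#'
#' Sorts items (outcomes, questionnaire items, like clusters) by their metric
#' value, descending, with a deterministic tie-break by name. All rows must
#' share one metric.
#'
#' @param reports A `prediction_report` (rows bind-able), list of them, or a
#'   tibble with `target`/`outcome` names and a metric column.
#' @param top_n Rows to flag at each end.
#' @return Tibble sorted by metric with columns `name`, `metric`, `value`,
#'   `rank`, `end` (`"top"`, `"bottom"`, or `NA`).
#' @export
rank_targets <- function(reports, top_n = 5) {
  if (inherits(reports, "prediction_report") || is.data.frame(reports))
    reports <- list(reports)
  tab <- dplyr::bind_rows(lapply(reports, function(r) {
    r <- tibble::as_tibble(r)
    if (all(c("outcome", "metric", "mean") %in% names(r)))
      tibble(name = r$outcome, metric = r$metric, value = r$mean)
    else if (all(c("target", "mean_auc") %in% names(r)))
      tibble(name = r$target, metric = "auc", value = r$mean_auc)
    else abort("unrecognized report shape")
  }))
  if (nrow(tab) == 0L) abort("no reports supplied")
  if (length(unique(tab$metric)) > 1L)
    abort("cannot rank reports with mixed metrics")
  tab <- dplyr::arrange(tab, dplyr::desc(.data$value), .data$name)
  tab$rank <- seq_len(nrow(tab))
  tab$end <- NA_character_
  tab$end[seq_len(min(top_n, nrow(tab)))] <- "top"
  bottom <- tail(seq_len(nrow(tab)), min(top_n, nrow(tab)))
  tab$end[bottom] <- ifelse(is.na(tab$end[bottom]), "bottom", tab$end[bottom])
  tab
}
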