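#' Read and write the package's plain-text interchange formats
#'
#' Message corpora are line-delimited JSON records
#' (`{"user_id": ..., "timestamp": ISO-8601, "text": ...}`); outcome tables,
#' demographics and likes triplets are headered CSV; a factor model is a
#' directory of CSV matrices (loadings, factor correlations, residual
#' variances, scoring weights, standardization, scores) plus a JSON manifest.
#'
#' @param corpus Message tibble.
#' @param path,dir File or directory path.
#' @return Readers return the parsed object; writers return the path
#'   invisibly.
#' @name wordtraits-io
NULL

#' @rdname wordtraits-io
#' @export
write_message_corpus <- function(corpus, path) {
  df <- data.frame(
    user_id = corpus$user_id,
    timestamp = format(corpus$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    text = corpus$text,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' @rdname wordtraits-io
#' @export
read_message_corpus <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  tibble(user_id = as.character(df$user_id),
         timestamp = as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                                tz = "UTC"),
         text = as.character(df$text))
}

#' @rdname wordtraits-io
#' @param table Data frame to write (outcomes, demographics, likes triplets).
#' @export
write_table_csv <- function(table, path) {
  readr::write_csv(as.data.frame(table), path)
  invisible(path)
}

#' @rdname wordtraits-io
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname wordtraits-io
#' @param model A `factor_model`.
#' @export
write_factor_model <- function(model, dir) {
  stopifnot(inherits(model, "factor_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  terms <- model$vocabulary$terms
  wcsv <- function(x, name) readr::write_csv(x, file.path(dir, name))
  wcsv(dplyr::bind_cols(tibble(term = terms),
                        tibble::as_tibble(model$loadings)), "loadings.csv")
  wcsv(dplyr::bind_cols(tibble(term = terms),
                        tibble::as_tibble(model$weights, .name_repair = ~colnames(model$loadings))),
       "weights.csv")
  wcsv(tibble::as_tibble(model$phi, .name_repair = ~colnames(model$loadings)), "phi.csv")
  wcsv(tibble(term = terms, psi = model$psi, mean = model$col_means,
              sd = model$col_sds, term_freq = model$vocabulary$term_freq),
       "standardization.csv")
  wcsv(model$scores, "scores.csv")
  jsonlite::write_json(
    list(k = model$k, method = model$method, rotation = model$rotation,
         transform = model$transform, n_users = model$n_users,
         seed = model$seed, loglik = model$loglik, n_iter = model$n_iter,
         converged = model$converged),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname wordtraits-io
#' @export
read_factor_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  rcsv <- function(name) readr::read_csv(file.path(dir, name), show_col_types = FALSE)
  load_tab <- rcsv("loadings.csv")
  std <- rcsv("standardization.csv")
  wts <- rcsv("weights.csv")
  phi <- as.matrix(rcsv("phi.csv"))
  terms <- load_tab$term
  L <- as.matrix(load_tab[-1L])
  rownames(L) <- terms
  W <- as.matrix(wts[-1L])
  rownames(W) <- terms
  dimnames(phi) <- list(colnames(L), colnames(L))
  vocab <- structure(list(terms = terms, term_freq = std$term_freq,
                          stopwords_removed = character(0)),
                     class = "vocabulary")
  scores <- rcsv("scores.csv")
  scores$user_id <- as.character(scores$user_id)
  structure(list(
    loadings = L, psi = std$psi, phi = phi, weights = W, scores = scores,
    rotation = man$rotation, method = man$method, k = as.integer(man$k),
    loglik = man$loglik %||% NA_real_, n_iter = man$n_iter %||% NA_integer_,
    converged = man$converged %||% TRUE, vocabulary = vocab,
    col_means = setNames(std$mean, terms), col_sds = setNames(std$sd, terms),
    transform = man$transform, n_users = man$n_users, seed = man$seed,
    unrotated = NULL
  ), class = "factor_model")
}

#' @rdname wordtraits-io
#' @param utm A `user_term_matrix`.
#' @export
write_user_term_matrix <- function(utm, dir) {
  stopifnot(inherits(utm, "user_term_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- Matrix::summary(utm$counts)
  readr::write_csv(tibble(user_id = utm$users[trip$i],
                          term = utm$vocabulary$terms[trip$j],
                          count = as.integer(trip$x)),
                   file.path(dir, "counts.csv"))
  readr::write_csv(tibble(term = utm$vocabulary$terms,
                          term_freq = utm$vocabulary$term_freq,
                          mean = utm$col_means, sd = utm$col_sds),
                   file.path(dir, "vocabulary.csv"))
  readr::write_csv(tibble(user_id = utm$users), file.path(dir, "users.csv"))
  jsonlite::write_json(list(transform = utm$transform),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname wordtraits-io
#' @export
read_user_term_matrix <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  voc <- readr::read_csv(file.path(dir, "vocabulary.csv"), show_col_types = FALSE)
  users <- as.character(readr::read_csv(file.path(dir, "users.csv"),
                                        show_col_types = FALSE)$user_id)
  trip <- readr::read_csv(file.path(dir, "counts.csv"), show_col_types = FALSE)
  counts <- Matrix::sparseMatrix(i = match(as.character(trip$user_id), users),
                                 j = match(trip$term, voc$term),
                                 x = trip$count,
                                 dims = c(length(users), nrow(voc)),
                                 dimnames = list(users, voc$term))
  vocab <- structure(list(terms = voc$term, term_freq = voc$term_freq,
                          stopwords_removed = character(0)),
                     class = "vocabulary")
  rel <- as.matrix(counts / Matrix::rowSums(counts))
  if (identical(man$transform, "relfreq_sqrt")) rel <- sqrt(rel)
  mu <- setNames(voc$mean, voc$term)
  sds <- setNames(voc$sd, voc$term)
  std <- sweep(sweep(rel, 2L, mu, "-"), 2L, sds, "/")
  structure(list(users = users, vocabulary = vocab,
                 counts = methods::as(counts, "CsparseMatrix"),
                 rel_freq = rel, standardized = std, col_means = mu,
                 col_sds = sds, degenerate_terms = character(0),
                 transform = man$transform, corpus_term_freq = voc$term_freq),
            class = "user_term_matrix")
}

#' @rdname wordtraits-io
#' @param report A `stability_report`.
#' @export
write_stability_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$retest))
    readr::write_csv(report$retest, file.path(dir, "retest.csv"))
  if (!is.null(report$dropout))
    readr::write_csv(report$dropout, file.path(dir, "dropout.csv"))
  jsonlite::write_json(
    list(dropout_mean = report$dropout_mean %||% NA,
         n_runs = report$n_runs %||% NA,
         drop_fraction = report$drop_fraction %||% NA,
         seed = report$seed %||% NA),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
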