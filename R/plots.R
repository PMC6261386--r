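#' Plot the top word correlates per factor
#'
#' Bar chart of the most positively and negatively correlated significant
#' words for each factor, colored by corpus-frequency tier — the tabular
#' counterpart of a differential-language word cloud.
#'
#' @param object A `dla_result`.
#' @param n_words Words per direction and factor.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dla_result <- function(object, n_words = 10, ...) {
  ks <- sort(unique(object$factor))
  rows <- dplyr::bind_rows(lapply(ks, function(f) {
    dplyr::bind_rows(
      dplyr::mutate(top_words(object, f, n_words, "positive"), factor = f),
      dplyr::mutate(top_words(object, f, n_words, "negative"), factor = f)
    )
  }))
  if (nrow(rows) == 0L) abort("no significant words to plot")
  rows <- dplyr::mutate(rows,
                        term = stats::reorder(paste(.data$term, .data$factor),
                                              .data$r))
  ggplot(rows, aes(x = .data$r, y = .data$term, fill = .data$freq_tier)) +
    geom_col() +
    facet_wrap(~factor, scales = "free_y",
               labeller = ggplot2::label_both) +
    scale_fill_manual(values = c(low = "grey60", moderate = "steelblue",
                                 frequent = "firebrick")) +
    ggplot2::scale_y_discrete(labels = function(x) sub(" [0-9]+$", "", x)) +
    labs(x = "Pearson r with factor score", y = NULL, fill = "frequency") +
    theme_minimal()
}

#' Plot retest curves or the dropout pair distribution
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  if (!is.null(object$retest)) {
    ggplot(object$retest,
           aes(x = .data$lag, y = .data$r,
               colour = base::factor(.data$factor))) +
      geom_line() + geom_point() +
      geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      labs(x = "lag (windows)", y = "retest correlation", colour = "factor") +
      theme_minimal()
  } else {
    ggplot(object$dropout, aes(x = .data$mean_abs_corr)) +
      ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
      labs(x = "mean aligned |r| per model pair", y = "pairs") +
      theme_minimal()
  }
}

#' Heatmap of the highest-loading terms
#'
#' @param object A `factor_model`.
#' @param n_terms Terms shown (those with the largest maximum absolute
#'   loading).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factor_model <- function(object, n_terms = 30, ...) {
  td <- tidy(object)
  keep <- td |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(m = max(abs(.data$loading)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    head(n_terms) |>
    dplyr::pull(.data$term)
  ggplot(dplyr::filter(td, .data$term %in% keep),
         aes(x = base::factor(.data$factor), y = .data$term,
             fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue") +
    labs(x = "factor", y = NULL, fill = "loading") +
    theme_minimal()
}

#' Scree plot with the acceleration-suggested elbow
#'
#' @param M A `user_term_matrix` or numeric matrix.
#' @param max_show Eigenvalues displayed.
#' @return A ggplot object; the suggested number of factors is drawn as a
#'   vertical line.
#' @export
plot_scree <- function(M, max_show = 30) {
  kq <- suggest_n_factors(M)
  ev <- attr(kq, "eigenvalues")
  df <- tibble(index = seq_along(ev), eigenvalue = ev)
  ggplot(head(df, max_show), aes(x = .data$index, y = .data$eigenvalue)) +
    geom_line() + geom_point() +
    ggplot2::geom_vline(xintercept = as.integer(kq), linetype = 2,
                        colour = "firebrick") +
    labs(x = "component", y = "eigenvalue",
         title = sprintf("scree acceleration suggests %d factor(s)", kq)) +
    theme_minimal()
}
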