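#' Plot projection histograms for a fitted discriminant
#'
#' Histograms of the discriminant-axis projections of a feature table,
#' faceted by class, with the decision threshold \eqn{\tau} marked — the
#' standard visual check that the two metal classes separate along
#' \eqn{w^*}.
#'
#' @param object An `"lda_fit"`.
#' @param features Labelled feature data frame to project (typically the
#'   training corpus).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lda_fit <- function(object, features, bins = 40, ...) {
  df <- tibble::tibble(
    projection = project_lda(object, features),
    class = as.character(features$label)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$projection)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$tau, linetype = "dashed") +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(
      x = "projection onto the discriminant axis",
      y = "sites",
      title = "Metal-site projections on w*"
    )
}

#' @rdname autoplot.lda_fit
#' @export
autoplot.lda_loo <- function(object, bins = 40, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$projection)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~label, ncol = 1) +
    ggplot2::labs(
      x = "held-out projection",
      y = "sites",
      title = "Leave-one-out projections by true class"
    )
}

#' Plot a kinetic fit over its data
#'
#' @param object A `"kinetic_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(
      x = "time (s)", y = "product per enzyme",
      title = paste("Kinetic fit:", object$kind)
    )
}

#' Bar chart of discriminant feature importance
#'
#' @param importance Tibble from [lda_importance()].
#' @param top_n Number of features to show.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 25) {
  df <- head(importance, top_n)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$feature, abs(.data$weight)),
      y = .data$weight, fill = .data$favored_class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "discriminant weight (standardised scale)",
      fill = "favours", title = "Which features separate the metal classes"
    )
}
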