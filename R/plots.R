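# ggplot2 displays for records, fits and cross-validation results.

#' Plot feature and expression trajectories over the time course
#'
#' Height, distance, width and expression of each gene against day, one facet
#' per variable (free y scales).
#'
#' @param records A records tibble.
#' @return A ggplot object.
#' @export
plot_feature_trends <- function(records) {
  check_records(records)
  long <- tidyr::pivot_longer(
    records,
    cols = c("height", "distance", "width", "expression"),
    names_to = "variable", values_to = "value"
  )
  long$variable <- factor(long$variable, levels = c("height", "distance", "width", "expression"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value, group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL, title = "Peak features and expression over the time course")
}

#' Observed versus fitted expression for a model fit
#'
#' @param object A `pc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pc_fit
#' @export
autoplot.pc_fit <- function(object, ...) {
  d <- tibble(observed = object$y, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "observed expression", y = "fitted expression",
      title = paste0(
        "Model ", object$spec$model_id,
        " (adj R² = ", signif(object$adj_r_squared, 3), ")"
      )
    )
}

#' Per-fold coefficient trajectories of a cross-validation run
#'
#' @param object A `pc_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pc_cv
#' @export
autoplot.pc_cv <- function(object, ...) {
  coefs <- object$coefficients
  long <- tidyr::pivot_longer(coefs, cols = -"fold", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value, colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(long$fold))) +
    ggplot2::labs(
      x = "fold", y = "estimate",
      title = paste0(object$k, "-fold cross-validation (", object$method, ")")
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
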