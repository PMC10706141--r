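#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted texture regressor
#'
#' One row per model term. Estimates are on the normalized (z-score) scale on
#' which the model is fit; the bias appears as term `"(bias)"`.
#'
#' @param x A `texture_lm`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.texture_lm <- function(x, ...) {
  tibble::tibble(
    term = c("(bias)", names(x$weights)),
    estimate = c(x$bias, unname(x$weights))
  )
}

#' @rdname tidy.texture_lm
#' @export
glance.texture_lm <- function(x, ...) {
  tr <- x$training
  tibble::tibble(
    target = x$target_name,
    n = if (is.null(tr)) NA_integer_ else tr$n,
    n_features = length(x$weights),
    nonzero = sum(x$weights != 0),
    lambda = x$lambda,
    cc = if (is.null(tr)) NA_real_ else tr$cc,
    mae = if (is.null(tr)) NA_real_ else tr$mae,
    mse = if (is.null(tr)) NA_real_ else tr$mse
  )
}

#' @rdname tidy.texture_lm
#' @param data Feature table to predict on (for `augment`).
#' @return `augment()` returns `data` plus `.pred` (and `.resid` when the
#'   target column is present).
#' @export
augment.texture_lm <- function(x, data, ...) {
  out <- tibble::as_tibble(data)
  out$.pred <- predict(x, data)
  if (x$target_name %in% names(out)) {
    out$.resid <- out[[x$target_name]] - out$.pred
  }
  out
}

#' Tidy a LASSO path
#'
#' @param x A `lasso_path`.
#' @param ... Unused.
#' @return Tibble with one row per penalty: `lambda`, `nonzero`, `cc`, `mae`,
#'   `mse` (in-sample, original units).
#' @export
tidy.lasso_path <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    tibble::tibble(lambda = m$lambda, nonzero = sum(m$weights != 0),
                   cc = m$training$cc, mae = m$training$mae,
                   mse = m$training$mse)
  }))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predicted against reference values
#'
#' The evaluation scatter: predictions on the vertical axis, DXA-style
#' references on the horizontal, identity line dashed, points colored by the
#' reference value.
#'
#' @param object A `texture_lm`.
#' @param data Feature table with the model's target column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.texture_lm <- function(object, data, ...) {
  aug <- augment(object, data)
  ref <- object$target_name
  ggplot2::ggplot(aug, ggplot2::aes(x = .data[[ref]], y = .data$.pred,
                                    colour = .data[[ref]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(guide = "none") +
    ggplot2::labs(x = sprintf("reference %s", ref),
                  y = sprintf("predicted %s", ref),
                  title = sprintf("Texture regression of %s", ref)) +
    ggplot2::theme_minimal()
}

#' Plot a LASSO path summary
#'
#' In-sample correlation, MAE and nonzero-weight count against the penalty
#' (log-10 axis; the unpenalized fit is drawn at the smallest positive grid
#' point's half).
#'
#' @param object A `lasso_path`.
#' @param ... Unused.
#' @return A ggplot, faceted by metric.
#' @export
autoplot.lasso_path <- function(object, ...) {
  td <- tidy(object)
  pos <- td$lambda[td$lambda > 0]
  floor_lam <- if (length(pos)) min(pos) / 2 else 1e-6
  td$lambda_plot <- ifelse(td$lambda == 0, floor_lam, td$lambda)
  long <- tidyr::pivot_longer(
    td[c("lambda_plot", "cc", "mae", "nonzero")],
    cols = c("cc", "mae", "nonzero"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda_plot, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "penalty lambda (log scale; leftmost point = 0)",
                  y = NULL,
                  title = sprintf("LASSO path for %s", object$target_name)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
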