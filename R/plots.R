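#' Plot the radon budget terms
#'
#' Bar chart of the six measured flux terms plus the solved groundwater
#' flux, with 1-sigma error bars, coloured by role.
#'
#' @param object An [rn_budget()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rn_budget
#' @export
autoplot.rn_budget <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$value,
                                  fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sigma,
                                        ymax = .data$value + .data$sigma),
                           width = 0.25) +
    ggplot2::labs(
      title = paste("Radon budget:", object$lake_id, object$season),
      x = NULL, y = "flux [Bq d⁻¹]", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo draw ensemble
#'
#' Histograms of the groundwater inflow and CH4-input draws with the median
#' and interquartile range marked.
#'
#' @param object A `"gw_mc"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_mc
#' @export
autoplot.gw_mc <- function(object, ...) {
  d <- bind_rows(
    tibble(quantity = "q_gw [cm d⁻¹]", draw = object$q_gw_draws),
    tibble(quantity = "CH₄ input [mg m⁻² d⁻¹]",
           draw = object$ch4_draws)
  )
  q <- d |>
    group_by(.data$quantity) |>
    summarise(median = median(.data$draw),
              p25 = quantile(.data$draw, 0.25, names = FALSE),
              p75 = quantile(.data$draw, 0.75, names = FALSE),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(data = q, ggplot2::aes(xintercept = .data$median)) +
    ggplot2::geom_vline(data = q, ggplot2::aes(xintercept = .data$p25),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = q, ggplot2::aes(xintercept = .data$p75),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(title = paste("Monte-Carlo ensemble:", object$lake_id,
                                object$season),
                  x = NULL, y = "draws") +
    ggplot2::theme_minimal()
}

#' Plot VIP scores of a PLS fit
#'
#' @param object A `"gw_pls"` object.
#' @param ... Unused.
#' @return A ggplot object; the VIP = 1 reference line separates
#'   above-average from below-average predictors.
#' @method autoplot gw_pls
#' @export
autoplot.gw_pls <- function(object, ...) {
  d <- tibble(term = object$var_names, vip = unname(object$vip))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term, .data$vip),
                                  y = .data$vip)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP",
                  title = sprintf("Variable importance (%d component%s)",
                                  object$n_components,
                                  if (object$n_components > 1) "s" else "")) +
    ggplot2::theme_minimal()
}

#' Plot the per-lake CH4 budget
#'
#' Box-style summary of the flux categories across lakes, one panel per
#' season.
#'
#' @param budget_table A tidy budget table from [build_budget_table()].
#' @return A ggplot object.
#' @export
plot_ch4_budget <- function(budget_table) {
  ggplot2::ggplot(budget_table,
                  ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~season) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "CH₄ flux [mg m⁻² d⁻¹]") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot total emission against groundwater inflow with the fitted line
#'
#' @param x A `"gw_ols"` object from [emission_inflow_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_ols
#' @export
autoplot.gw_ols <- function(x, ...) {
  d <- x$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q_gw, y = .data$total_emission)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black") +
    ggplot2::labs(
      x = "groundwater inflow [cm d⁻¹]",
      y = "total CH₄ emission [mg m⁻² d⁻¹]",
      title = sprintf("slope %.2f ± %.2f, R² = %.2f, p = %.3g",
                      x$coefficients$estimate[2], x$coefficients$std_error[2],
                      x$r2, x$p_value)
    ) +
    ggplot2::theme_minimal()
}
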