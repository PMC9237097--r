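#' Tidy a radon budget
#'
#' @param x An [rn_budget()] object.
#' @param ... Unused.
#' @return The budget term table with the solved groundwater flux appended
#'   as a `F_gw` row (role "solved").
#' @method tidy rn_budget
#' @export
tidy.rn_budget <- function(x, ...) {
  bind_rows(
    x$terms,
    tibble(term = "F_gw", role = "solved",
           value = x$f_gw$value, sigma = x$f_gw$sigma)
  ) |>
    mutate(lake_id = x$lake_id, season = x$season, .before = 1)
}

#' @rdname tidy.rn_budget
#' @method glance rn_budget
#' @export
glance.rn_budget <- function(x, ...) {
  tibble(
    lake_id = x$lake_id, season = x$season,
    f_gw = x$f_gw$value, f_gw_sigma = x$f_gw$sigma,
    truncated = x$truncated, k_rn = x$k_rn, tau_d = x$tau_d,
    steady_state_ok = x$steady_state$ok, wind_cv = x$steady_state$cv
  )
}

#' Tidy a Monte-Carlo result
#'
#' @param x A `"gw_mc"` object from [run_mc()].
#' @param ... Unused.
#' @return The median/IQR summary tibble, one row per quantity.
#' @method tidy gw_mc
#' @export
tidy.gw_mc <- function(x, ...) {
  mutate(x$summary, lake_id = x$lake_id, season = x$season, .before = 1)
}

#' @rdname tidy.gw_mc
#' @method glance gw_mc
#' @export
glance.gw_mc <- function(x, ...) {
  tibble(lake_id = x$lake_id, season = x$season, n_iter = x$n_iter,
         seed = x$seed, mode = x$mode, truncated = x$truncated)
}

#' Tidy the emission-inflow regression
#'
#' @param x A `"gw_ols"` object.
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `std_error`).
#' @method tidy gw_ols
#' @export
tidy.gw_ols <- function(x, ...) x$coefficients

#' @rdname tidy.gw_ols
#' @method glance gw_ols
#' @export
glance.gw_ols <- function(x, ...) {
  tibble(r2 = x$r2, f_stat = x$f_stat, df = x$df, p_value = x$p_value, n = x$n)
}

#' Tidy a PLS fit
#'
#' @param x A `"gw_pls"` object.
#' @param ... Unused.
#' @return Per-predictor tibble: `term`, `vip`, and the weight/loading of
#'   each retained component.
#' @method tidy gw_pls
#' @export
tidy.gw_pls <- function(x, ...) {
  a <- x$n_components
  out <- tibble(term = x$var_names, vip = unname(x$vip))
  for (j in seq_len(a)) {
    out[[paste0("weight_c", j)]] <- x$x_weights[, j]
    out[[paste0("loading_c", j)]] <- x$x_loadings[, j]
  }
  arrange(out, desc(.data$vip))
}

#' @rdname tidy.gw_pls
#' @method glance gw_pls
#' @export
glance.gw_pls <- function(x, ...) {
  a <- x$n_components
  tibble(n_components = a, r2y = x$r2y_cum[a], rmse_cv = x$rmse_cv[a],
         n_predictors = length(x$var_names))
}

#' Tidy an all-subsets AIC search
#'
#' @param x An `"aic_subsets"` object.
#' @param ... Unused.
#' @return The full AIC ranking tibble (one row per fitted subset).
#' @method tidy aic_subsets
#' @export
tidy.aic_subsets <- function(x, ...) x$ranking

#' @rdname tidy.aic_subsets
#' @method glance aic_subsets
#' @export
glance.aic_subsets <- function(x, ...) {
  tibble(
    best_terms = paste(x$best$terms, collapse = "+"),
    aic = x$best$aic, adj_r2 = x$best$adj_r2, f_stat = x$best$f_stat,
    df = x$best$df, p_value = x$best$p_value,
    n = x$n, n_subsets = nrow(x$ranking), skipped = x$skipped
  )
}
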