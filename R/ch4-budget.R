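#' Areal CH4 flux carried by a stream
#'
#' Normalises the point-source stream CH4 load by lake area:
#' q * c * 16.04 / A, in mg CH4 m^-2 d^-1.
#'
#' @param q Stream discharge \[m3 d^-1\], non-negative.
#' @param c_ch4 Stream CH4 concentration \[mmol m^-3\] (numerically uM).
#' @param A Lake area \[m2\], positive.
#' @return Flux in mg CH4 m^-2 d^-1.
#' @export
stream_ch4_flux <- function(q, c_ch4, A) {
  if (any(q < 0)) abort("`q` must be >= 0.", class = "lakegw_validation_error")
  if (A <= 0) abort("`A` must be positive.", class = "lakegw_validation_error")
  q * c_ch4 * CH4_MOLAR_MASS / A
}

#' Diffusive CH4 emission from a survey
#'
#' Applies the air-water flux law to the lake-surface CH4 concentration with
#' a wind-weighted CH4 transfer velocity. Emission is floored at zero for the
#' budget ledger; an undersaturated lake (invasion) is reported separately in
#' the `invasion` field rather than as a negative emission.
#'
#' @param survey A [lake_survey()].
#' @param model A [k_model()].
#' @param sample_time Sampling time on the wind time scale (default: last
#'   wind timestamp).
#' @param atm_ch4_ppm Atmospheric CH4 mixing ratio \[ppm\].
#' @return A list with `emission` and `invasion` \[mg CH4 m^-2 d^-1\],
#'   `k_ch4` \[m d^-1\] and `c_eq` \[mmol m^-3\].
#' @export
diffusive_emission <- function(survey, model = k_model(), sample_time = NULL,
                               atm_ch4_ppm = CH4_ATM_PPM) {
  stopifnot(inherits(survey, "lake_survey"))
  if (!nrow(survey$wind)) abort("wind record required.", class = "lakegw_validation_error")
  surf <- dplyr::filter(survey$samples, .data$source == "lake_surface",
                        !is.na(.data$ch4_umol_l))
  if (!nrow(surf)) {
    abort("no lake_surface CH4 measurements.", class = "lakegw_validation_error")
  }
  c_lake <- mean(surf$ch4_umol_l)
  temp <- mean(surf$temp_c, na.rm = TRUE)
  if (is.null(sample_time)) sample_time <- max(survey$wind$timestamp)
  g <- survey$geometry
  # weighting timescale: radon residence time computed from a first-pass k
  height <- survey$wind$height_m[1] %||% 10
  u10 <- wind_to_u10(mean(survey$wind$speed_m_s), height)
  k0 <- k_gas(k600_from_wind(u10, g$area_m2 / 1e6, model), "rn222", temp, u10)
  tau <- residence_time(k0, g$mean_depth_m, survey$flows$q_outlet$value, g$volume_m3)
  k_ch4 <- weighted_k(survey$wind, sample_time, tau, g$area_m2 / 1e6, "ch4",
                      temp, model)
  c_eq <- equilibrium_conc("ch4", temp, atm_ch4_ppm)
  flux_molar <- atmospheric_flux(k_ch4, c_lake, c_eq)   # mmol m^-2 d^-1
  flux <- flux_molar * CH4_MOLAR_MASS
  list(
    emission = max(flux, 0),
    invasion = max(-flux, 0),
    k_ch4 = k_ch4, c_eq = c_eq, c_lake = c_lake
  )
}

#' Scale diffusive emission to total emission via an ebullition fraction
#'
#' Diffusion is assumed to account for a fixed fraction of total atmospheric
#' CH4 emission (default 0.17, a conservative maximum-ebullition choice from
#' a long-term record at nearby mire lakes, where diffusion contributed
#' 17-52% of the ice-free flux). total = diffusive / diff_fraction;
#' ebullition = total - diffusive.
#'
#' @param diffusive Diffusive emission \[mg CH4 m^-2 d^-1\], non-negative.
#' @param diff_fraction Diffusive fraction of total, in (0, 1\].
#' @return A tibble with `diffusive`, `ebullition`, `total`.
#' @examples
#' scale_ebullition(7.6)  # total 44.7, ebullition 37.1
#' @export
scale_ebullition <- function(diffusive, diff_fraction = 0.17) {
  if (diff_fraction <= 0 || diff_fraction > 1) {
    abort("`diff_fraction` must be in (0, 1].", class = "lakegw_validation_error")
  }
  if (any(diffusive < 0)) {
    abort("`diffusive` must be >= 0.", class = "lakegw_validation_error")
  }
  total <- diffusive / diff_fraction
  tibble(diffusive = diffusive, ebullition = total - diffusive, total = total)
}

#' Regression of total CH4 emission on groundwater inflow
#'
#' Ordinary least squares of total emission \[mg CH4 m^-2 d^-1\] on
#' groundwater inflow \[cm d^-1\] across lakes, with exact small-sample
#' inference (t-based standard errors, F test).
#'
#' @param pairs Data frame with columns `q_gw` and `total_emission` (or the
#'   first two numeric columns are used, in that order).
#' @return An object of class `"gw_ols"` wrapping the [stats::lm] fit, with
#'   a `coefficients` tibble (`term`, `estimate`, `std_error`), `r2`,
#'   `f_stat`, `df`, `p_value`.
#' @export
emission_inflow_regression <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("q_gw", "total_emission") %in% names(pairs))) {
    num <- names(pairs)[vapply(pairs, is.numeric, logical(1))]
    stopifnot(length(num) >= 2)
    pairs <- dplyr::rename(pairs, q_gw = !!num[1], total_emission = !!num[2])
  }
  pairs <- dplyr::filter(pairs, complete.cases(pairs[c("q_gw", "total_emission")]))
  if (nrow(pairs) < 3) abort("need >= 3 pairs.", class = "lakegw_validation_error")
  if (sd(pairs$q_gw) == 0) {
    abort("degenerate regressor: q_gw has zero variance.",
          class = "lakegw_validation_error")
  }
  fit <- lm(total_emission ~ q_gw, data = pairs)
  s <- summary(fit)
  structure(list(
    fit = fit,
    coefficients = tibble(
      term = c("intercept", "slope"),
      estimate = unname(coef(fit)[c("(Intercept)", "q_gw")]),
      std_error = unname(s$coefficients[, "Std. Error"])
    ),
    r2 = s$r.squared,
    f_stat = unname(s$fstatistic["value"]),
    df = unname(s$fstatistic["dendf"]),
    p_value = unname(pf(s$fstatistic["value"], s$fstatistic["numdf"],
                        s$fstatistic["dendf"], lower.tail = FALSE)),
    n = nrow(pairs)
  ), class = "gw_ols")
}

#' @export
print.gw_ols <- function(x, ...) {
  cat("<gw_ols> total_emission ~ q_gw, n =", x$n, "\n")
  cat(sprintf("  slope %.3g +/- %.3g; intercept %.3g +/- %.3g\n",
              x$coefficients$estimate[2], x$coefficients$std_error[2],
              x$coefficients$estimate[1], x$coefficients$std_error[1]))
  cat(sprintf("  R2 = %.3f, F = %.2f, df = %d, p = %.4g\n",
              x$r2, x$f_stat, x$df, x$p_value))
  invisible(x)
}

#' Assemble the per-lake CH4 budget table
#'
#' Combines groundwater CH4 inputs (with their Monte-Carlo IQR), stream
#' inputs and exports, and atmospheric emissions into one tidy table per
#' lake-season, one row per flux category, and adds the order-of-magnitude
#' ratio of groundwater input to total emission.
#'
#' @param components A data frame with one row per lake-season and columns
#'   `lake_id`, `season`, `gw_input`, `gw_p25`, `gw_p75`, `inlet_input`,
#'   `outlet_export`, `diffusive_emission`, `ebullition_estimate`,
#'   `total_emission` (all mg CH4 m^-2 d^-1).
#' @return A tidy tibble: `lake_id`, `season`, `category`, `value`, `p25`,
#'   `p75`, plus a `gw_to_emission_ratio` column repeated per lake-season.
#' @export
build_budget_table <- function(components) {
  components <- as_tibble(components)
  if (!nrow(components)) {
    return(tibble(lake_id = character(), season = character(),
                  category = character(), value = numeric(),
                  p25 = numeric(), p75 = numeric(),
                  gw_to_emission_ratio = numeric()))
  }
  components |>
    mutate(gw_to_emission_ratio = .data$gw_input / .data$total_emission) |>
    tidyr::pivot_longer(
      cols = c("gw_input", "inlet_input", "outlet_export",
               "diffusive_emission", "ebullition_estimate", "total_emission"),
      names_to = "category", values_to = "value"
    ) |>
    mutate(
      p25 = ifelse(.data$category == "gw_input", .data$gw_p25, NA_real_),
      p75 = ifelse(.data$category == "gw_input", .data$gw_p75, NA_real_)
    ) |>
    select(dplyr::all_of(c("lake_id", "season", "category", "value",
                           "p25", "p75", "gw_to_emission_ratio")))
}
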