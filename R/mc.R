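#' Draw a radon-flux ensemble from its uncertainty
#'
#' Draws from Normal(value, sigma) truncated at zero by resampling
#' (negative groundwater radon flux is unphysical under the no-loss
#' assumption). Fully reproducible under `seed`; `sigma = 0` yields a
#' constant ensemble.
#'
#' @param f_gw An [uv()] in Bq d^-1.
#' @param n Number of draws (>= 1).
#' @param seed Integer RNG seed.
#' @return Numeric vector of `n` non-negative draws.
#' @export
draw_fgw <- function(f_gw, n = 1000, seed) {
  f_gw <- as_uv(f_gw)
  if (n < 1) abort("`n` must be >= 1.", class = "lakegw_validation_error")
  if (f_gw$sigma == 0) return(rep(f_gw$value, n))
  withr_seed(seed)
  draws <- rnorm(n, f_gw$value, f_gw$sigma)
  while (any(draws < 0)) {
    neg <- draws < 0
    draws[neg] <- rnorm(sum(neg), f_gw$value, f_gw$sigma)
  }
  draws
}

# seed the RNG, restoring the caller's RNG state when the caller exits
withr_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    do.call("on.exit",
            list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
                 add = TRUE),
            envir = parent.frame())
  }
  set.seed(seed)
}

#' Convert radon-flux draws to groundwater inflow draws
#'
#' Each flux draw is divided by a groundwater radon endmember concentration
#' sampled with replacement from the measured endmember set, then normalised
#' by lake area and expressed in cm d^-1.
#'
#' @param f_draws Radon flux draws \[Bq d^-1\].
#' @param endmembers Endmember tibble with positive `rn_bq_m3`.
#' @param A Lake area \[m2\].
#' @param seed Integer RNG seed for the endmember resampling.
#' @return Inflow draws \[cm d^-1\], same length as `f_draws`.
#' @export
inflow_from_draws <- function(f_draws, endmembers, A, seed) {
  if (is.null(endmembers) || nrow(endmembers) < 1L) {
    abort("endmember set is empty.", class = "lakegw_validation_error")
  }
  if (any(endmembers$rn_bq_m3 <= 0)) {
    abort("endmember rn must be > 0.", class = "lakegw_validation_error")
  }
  withr_seed(seed)
  idx <- sample.int(nrow(endmembers), length(f_draws), replace = TRUE)
  f_draws / endmembers$rn_bq_m3[idx] / A * 100
}

#' Convert radon-flux draws to groundwater CH4 input draws
#'
#' Each flux draw is divided by a groundwater Rn:CH4 concentration ratio
#' (Bq m^-3 per mmol m^-3) resampled from the endmember set, converted to
#' mass with the CH4 molar mass, and normalised by lake area. In
#' `"independent"` mode (default) the ratio endmember is drawn independently
#' of the inflow endmember; in `"paired"` mode the same endmember sample
#' index stream is used for both conversions (same per-draw seed offset as
#' [inflow_from_draws()]).
#'
#' @param f_draws Radon flux draws \[Bq d^-1\].
#' @param endmembers Endmember tibble with positive `rn_bq_m3` and
#'   `ch4_umol_l`.
#' @param A Lake area \[m2\].
#' @param seed Integer RNG seed.
#' @param mode `"independent"` or `"paired"`.
#' @return CH4 input draws \[mg CH4 m^-2 d^-1\].
#' @export
ch4_from_draws <- function(f_draws, endmembers, A, seed,
                           mode = c("independent", "paired")) {
  mode <- match.arg(mode)
  if (is.null(endmembers) || nrow(endmembers) < 1L) {
    abort("endmember set is empty.", class = "lakegw_validation_error")
  }
  if (any(endmembers$ch4_umol_l <= 0)) {
    abort("endmember ch4 must be > 0 (Rn:CH4 ratio would be infinite).",
          class = "lakegw_validation_error")
  }
  if (any(endmembers$rn_bq_m3 <= 0)) {
    abort("endmember rn must be > 0.", class = "lakegw_validation_error")
  }
  withr_seed(if (mode == "independent") seed + 1L else seed)
  idx <- sample.int(nrow(endmembers), length(f_draws), replace = TRUE)
  ratio <- endmembers$rn_bq_m3[idx] / endmembers$ch4_umol_l[idx]  # Bq per mmol
  f_draws / ratio * CH4_MOLAR_MASS / A
}

#' Median and interquartile range of a draw ensemble
#'
#' Linear-interpolation percentiles (quantile type 7), the convention used
#' for all distributional reporting in the package.
#'
#' @param draws Non-empty numeric vector.
#' @return A tibble with `median`, `p25`, `p75`.
#' @export
summarize_draws <- function(draws) {
  if (!length(draws)) abort("empty draw vector.", class = "lakegw_validation_error")
  q <- quantile(draws, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(median = q[2], p25 = q[1], p75 = q[3])
}

#' Monte-Carlo groundwater inflow and CH4 input for one budget
#'
#' The full endmember-resampling procedure: an ensemble of groundwater radon
#' fluxes is drawn from the solved budget flux and its uncertainty, then
#' converted draw-by-draw to inflow (via the radon endmember) and to CH4
#' input (via the Rn:CH4 ratio endmember), and summarised as median and IQR.
#'
#' The RNG stream is derived from the master seed plus a stable hash of the
#' lake id and season, so per-lake results do not depend on processing order.
#'
#' @param budget An [rn_budget()] result (or a list with `f_gw` [uv()]).
#' @param endmembers Endmember tibble (`rn_bq_m3`, `ch4_umol_l`).
#' @param A Lake area \[m2\].
#' @param n_iter Ensemble size (default 1000).
#' @param seed Master integer seed.
#' @param mode Endmember sampling mode, `"independent"` (default) or
#'   `"paired"`.
#' @return An object of class `"gw_mc"`: list with `q_gw_draws` (cm d^-1),
#'   `ch4_draws` (mg m^-2 d^-1), `summary` tibble (quantity, median, p25,
#'   p75), `n_iter`, `seed`, `lake_id`, `season`.
#' @export
run_mc <- function(budget, endmembers, A, n_iter = 1000, seed,
                   mode = c("independent", "paired")) {
  mode <- match.arg(mode)
  if (n_iter < 1) abort("`n_iter` must be >= 1.", class = "lakegw_validation_error")
  lake_id <- budget$lake_id %||% "lake"
  season <- budget$season %||% "summer"
  s <- stream_seed(seed, paste(lake_id, season))
  f_draws <- draw_fgw(budget$f_gw, n_iter, seed = s)
  q_draws <- inflow_from_draws(f_draws, endmembers, A, seed = s + 101L)
  ch4_draws <- ch4_from_draws(f_draws, endmembers, A, seed = s + 101L, mode = mode)
  summary <- bind_rows(
    dplyr::mutate(summarize_draws(q_draws), quantity = "q_gw_cm_d", .before = 1),
    dplyr::mutate(summarize_draws(ch4_draws), quantity = "ch4_mg_m2_d", .before = 1)
  )
  structure(list(
    q_gw_draws = q_draws, ch4_draws = ch4_draws, summary = summary,
    n_iter = n_iter, seed = seed, mode = mode,
    lake_id = lake_id, season = season,
    truncated = isTRUE(budget$truncated)
  ), class = "gw_mc")
}

# deterministic small-integer stream seed from a master seed and a label,
# so per-lake results do not depend on processing order
stream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' @export
print.gw_mc <- function(x, ...) {
  cat("<gw_mc>", x$lake_id, "|", x$season, "| n_iter =", x$n_iter, "\n")
  print(x$summary)
  invisible(x)
}
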