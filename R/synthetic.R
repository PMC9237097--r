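#' Lognormal endmember distribution from median and IQR anchors
#'
#' Solves lognormal parameters so that the population median and quartiles
#' match the supplied anchors: meanlog = log(median),
#' sdlog = log(p75/p25) / (2 * qnorm(0.75)).
#'
#' @param median,p25,p75 Positive anchors with p25 <= median <= p75.
#' @return A list with `meanlog`, `sdlog`, and the anchors.
#' @export
endmember_dist <- function(median, p25, p75) {
  if (any(c(median, p25, p75) <= 0) || p25 > median || median > p75) {
    abort("need 0 < p25 <= median <= p75.", class = "lakegw_validation_error")
  }
  list(meanlog = log(median), sdlog = log(p75 / p25) / (2 * qnorm(0.75)),
       median = median, p25 = p25, p75 = p75)
}

# default groundwater endmember anchors: radon and CH4 concentration
# distributions typical of active-layer groundwater feeding small
# sub-Arctic mire lakes
DEFAULT_RN_GW <- list(median = 3500, p25 = 2100, p75 = 8800)    # Bq m^-3
DEFAULT_CH4_GW <- list(median = 150, p25 = 49, p75 = 210)       # uM

#' Draw paired groundwater (Rn, CH4) endmember samples
#'
#' Samples correlated lognormal pairs: both concentrations derive from the
#' same active-layer source, so their logs are drawn from a bivariate normal
#' with configurable correlation (default 0.5). `sdlog = 0` (a degenerate
#' distribution) yields all samples equal to the median.
#'
#' @param n Number of endmember samples (default 41).
#' @param seed Integer RNG seed.
#' @param rn Anchor list for radon (see [endmember_dist()]); default median
#'   3500, IQR 2100-8800 Bq m^-3.
#' @param ch4 Anchor list for CH4; default median 150, IQR 49-210 uM.
#' @param corr Log-scale correlation between the pair, in \[-1, 1\].
#' @return An endmember tibble (`source`, `rn_bq_m3`, `ch4_umol_l`, ...).
#' @export
sample_endmembers <- function(n = 41, seed = 1,
                              rn = DEFAULT_RN_GW, ch4 = DEFAULT_CH4_GW,
                              corr = 0.5) {
  if (n < 1) abort("`n` must be >= 1.", class = "lakegw_validation_error")
  dr <- endmember_dist(rn$median, rn$p25, rn$p75)
  dc <- endmember_dist(ch4$median, ch4$p25, ch4$p75)
  stopifnot(abs(corr) <= 1)
  withr_seed(seed)
  z1 <- rnorm(n)
  z2 <- corr * z1 + sqrt(1 - corr^2) * rnorm(n)
  # sdlog = 0 collapses to the median exactly (no exp/log round-trip error)
  rn_v <- if (dr$sdlog > 0) exp(dr$meanlog + dr$sdlog * z1) else rep(dr$median, n)
  ch4_v <- if (dc$sdlog > 0) exp(dc$meanlog + dc$sdlog * z2) else rep(dc$median, n)
  tibble(
    lake_id = "endmember", season = "summer", source = "groundwater",
    rn_bq_m3 = rn_v,
    ch4_umol_l = ch4_v,
    temp_c = 6
  )
}

#' Closed-form steady-state lake radon concentration
#'
#' Inverts the mass balance forward: given all sources and sinks, the
#' equilibrium lake concentration is
#' C = (Q_gw*C_gw + f_diff*A + Q_in*C_in + lambda*V*C_Ra + k*A*C_eq) /
#'     (k*A + Q_out + lambda*V).
#'
#' @param q_gw Groundwater inflow \[m3 d^-1\].
#' @param c_rn_gw Groundwater radon concentration \[Bq m^-3\].
#' @param A,V Lake area \[m2\] and volume \[m3\], positive.
#' @param k_rn Radon transfer velocity \[m d^-1\].
#' @param f_diff Sediment diffusive flux \[Bq m^-2 d^-1\].
#' @param q_inlet,c_rn_inlet Inlet discharge \[m3 d^-1\] and radon \[Bq m^-3\].
#' @param q_outlet Outlet discharge \[m3 d^-1\].
#' @param c_ra_lake Dissolved 226Ra \[Bq m^-3\].
#' @param c_eq_rn Atmospheric-equilibrium radon \[Bq m^-3\].
#' @return Steady-state C_Rn,lake \[Bq m^-3\].
#' @export
forward_steady_state <- function(q_gw, c_rn_gw, A, V, k_rn, f_diff = 0,
                                 q_inlet = 0, c_rn_inlet = 0, q_outlet = 0,
                                 c_ra_lake = 0, c_eq_rn = 0) {
  denom <- k_rn * A + q_outlet + rn_decay_constant() * V
  if (denom <= 0) abort("zero or negative loss denominator.",
                        class = "lakegw_validation_error")
  (q_gw * c_rn_gw + f_diff * A + q_inlet * c_rn_inlet +
     rn_decay_constant() * V * c_ra_lake + k_rn * A * c_eq_rn) / denom
}

#' Default parameters of the synthetic survey generator
#'
#' One place holding the study conditions the generator emulates: a small
#' (5 ha, 2.8 m deep) mire-fringed lake with moderate streams, active-layer
#' groundwater endmembers, and sub-Arctic wind. All values are overridable
#' via the `params` argument of [generate_survey()].
#'
#' @return Named list of generator defaults.
#' @export
synth_defaults <- function() {
  list(
    lake_id = "SYN01", season = "summer",
    area_m2 = 5e4, volume_m3 = 1.4e5,           # h = 2.8 m
    q_gw_m3_d = 1500,                           # true inflow, 3 cm d^-1
    rn_gw = DEFAULT_RN_GW, ch4_gw = DEFAULT_CH4_GW, endmember_corr = 0.5,
    n_endmembers = 41,
    f_diff = 10, f_diff_rel_sigma = 0.3,        # Bq m^-2 d^-1
    q_inlet_m3_d = 3000, q_outlet_m3_d = 8400,  # outlet flushing ~0.06 d^-1
    c_rn_inlet = 520, c_ch4_inlet = 0.02,       # stream medians
    c_ra_lake = 20,                             # Bq m^-3
    c_ch4_lake = 0.19,                          # uM, lake surface
    temp_c = 14,
    wind_mean = 4, wind_sd = 1.5, wind_ar1 = 0.8, wind_days = 14,
    wind_height_m = 10,
    conc_rel_sigma = 0.10, flow_rel_sigma = 0.15,
    n_surface = 5, n_deep = 1, n_stream = 2,
    k_model = "wind_46lakes"
  )
}

#' Generate a complete synthetic survey with known ground truth
#'
#' Builds an AR(1) hourly wind record, derives the radon transfer velocity
#' with the same wind-weighting machinery the inversion uses, solves the
#' forward steady state for the lake radon concentration, and emits noisy
#' observations of every measured quantity (relative noise: 10% on
#' concentrations, 15% on discharges, 30% on the sediment flux, all
#' configurable). With zero observation noise the pipeline recovers the
#' imposed inflow exactly (up to the budget's numerical tolerance).
#'
#' @param params Named list overriding [synth_defaults()].
#' @param seed Integer RNG seed; the same seed reproduces the bundle
#'   byte-identically.
#' @return A list with `survey` (a [lake_survey()]) and `truth` (list:
#'   true inflow in m3 d^-1 and cm d^-1, the true groundwater radon flux,
#'   endmember distribution parameters, the k model and k_rn used).
#' @export
generate_survey <- function(params = list(), seed = 1) {
  p <- modifyList(synth_defaults(), params)
  withr_seed(stream_seed(seed, paste(p$lake_id, p$season)))
  h <- p$volume_m3 / p$area_m2

  # hourly AR(1) wind, truncated at zero
  n_h <- p$wind_days * 24
  innov_sd <- p$wind_sd * sqrt(1 - p$wind_ar1^2)
  u <- numeric(n_h)
  u[1] <- rnorm(1, p$wind_mean, p$wind_sd)
  for (i in 2:n_h) {
    u[i] <- p$wind_mean + p$wind_ar1 * (u[i - 1] - p$wind_mean) +
      rnorm(1, 0, innov_sd)
  }
  wind <- tibble(timestamp = seq_len(n_h), speed_m_s = pmax(u, 0),
                 height_m = p$wind_height_m)
  sample_time <- n_h

  model <- k_model(p$k_model)
  area_km2 <- p$area_m2 / 1e6
  u10 <- wind_to_u10(mean(wind$speed_m_s), p$wind_height_m)
  k_rn <- k_gas(k600_from_wind(u10, area_km2, model), "rn222", p$temp_c, u10)
  tau <- residence_time(k_rn, h, p$q_outlet_m3_d, p$volume_m3)
  for (i in 1:3) {
    k_rn <- weighted_k(wind, sample_time, tau, area_km2, "rn222", p$temp_c, model)
    tau <- residence_time(k_rn, h, p$q_outlet_m3_d, p$volume_m3)
  }

  # the discharging groundwater is characterised by the measured endmember
  # set itself: its empirical median is the effective source concentration,
  # so recovery tests probe the pipeline, not the sampling error of the
  # endmember survey
  endmembers <- sample_endmembers(
    n = p$n_endmembers, seed = stream_seed(seed, paste0(p$lake_id, "-em")),
    rn = p$rn_gw, ch4 = p$ch4_gw, corr = p$endmember_corr
  )
  endmembers$lake_id <- p$lake_id
  endmembers$season <- p$season
  c_rn_gw_eff <- p$c_rn_gw %||% median(endmembers$rn_bq_m3)
  ratio_eff <- median(endmembers$rn_bq_m3 / endmembers$ch4_umol_l)

  c_lake_true <- forward_steady_state(
    q_gw = p$q_gw_m3_d, c_rn_gw = c_rn_gw_eff,
    A = p$area_m2, V = p$volume_m3, k_rn = k_rn, f_diff = p$f_diff,
    q_inlet = p$q_inlet_m3_d, c_rn_inlet = p$c_rn_inlet,
    q_outlet = p$q_outlet_m3_d, c_ra_lake = p$c_ra_lake
  )

  noisy <- function(x, rel) if (rel > 0) x * pmax(1 + rnorm(length(x), 0, rel), 0.01) else x
  cr <- p$conc_rel_sigma
  surface <- tibble(
    lake_id = p$lake_id, season = p$season, source = "lake_surface",
    rn_bq_m3 = noisy(rep(c_lake_true, p$n_surface), cr),
    ch4_umol_l = noisy(rep(p$c_ch4_lake, p$n_surface), cr),
    temp_c = p$temp_c
  )
  deep <- tibble(
    lake_id = p$lake_id, season = p$season, source = "lake_deep",
    rn_bq_m3 = noisy(rep(c_lake_true, p$n_deep), cr),
    ch4_umol_l = noisy(rep(p$c_ch4_lake, p$n_deep), cr),
    temp_c = p$temp_c
  )
  inlet <- tibble(
    lake_id = p$lake_id, season = p$season, source = "inlet",
    rn_bq_m3 = noisy(rep(p$c_rn_inlet, p$n_stream), cr),
    ch4_umol_l = noisy(rep(p$c_ch4_inlet, p$n_stream), cr),
    temp_c = p$temp_c
  )
  outlet <- tibble(
    lake_id = p$lake_id, season = p$season, source = "outlet",
    rn_bq_m3 = noisy(rep(c_lake_true, p$n_stream), cr),
    ch4_umol_l = noisy(rep(p$c_ch4_lake, p$n_stream), cr),
    temp_c = p$temp_c
  )
  samples <- bind_rows(surface, deep, inlet, outlet, endmembers)

  fr <- p$flow_rel_sigma
  flows <- list(
    q_inlet = uv(noisy(p$q_inlet_m3_d, fr), p$q_inlet_m3_d * fr),
    q_outlet = uv(noisy(p$q_outlet_m3_d, fr), p$q_outlet_m3_d * fr)
  )
  f_diff_obs <- uv(noisy(p$f_diff, p$f_diff_rel_sigma),
                   p$f_diff * p$f_diff_rel_sigma)
  geometry <- lake_geometry(p$lake_id, p$area_m2, p$volume_m3, h)
  survey <- lake_survey(
    geometry = geometry, samples = samples, wind = wind, flows = flows,
    f_diff = f_diff_obs,
    c_ra_lake = uv(noisy(p$c_ra_lake, cr), p$c_ra_lake * cr),
    season = p$season, endmembers = endmembers
  )
  truth <- list(
    q_gw_m3_d = p$q_gw_m3_d,
    q_gw_cm_d = p$q_gw_m3_d / p$area_m2 * 100,
    f_gw_bq_d = p$q_gw_m3_d * c_rn_gw_eff,
    c_rn_gw_eff = c_rn_gw_eff,
    ch4_input_mg_m2_d = p$q_gw_m3_d * c_rn_gw_eff / ratio_eff *
      CH4_MOLAR_MASS / p$area_m2,
    c_lake_true = c_lake_true, k_rn = k_rn, tau_d = tau,
    rn_gw = p$rn_gw, ch4_gw = p$ch4_gw, k_model = p$k_model,
    params = p
  )
  list(survey = survey, truth = truth)
}

#' Generate a synthetic spatial-driver dataset
#'
#' Draws catchment and lake covariates in study-like ranges (mean depth
#' around 2.9 m, lake areas 1.8-11.6 ha, the regional precipitation
#' gradient) and produces groundwater inflow as the reference spatial model
#' plus Gaussian noise, floored at 0.05 cm d^-1.
#'
#' @param n_lakes Number of lake-seasons (>= 8; default 24).
#' @param seed Integer RNG seed.
#' @param noise_sd Gaussian noise on inflow \[cm d^-1\] (default 1.5).
#' @return A tibble of covariates (`depth`, `lake_area`, `catchment_area`,
#'   `slope`, `wetzone`, `mire`, `precipitation`) plus the response `q_gw`.
#' @export
generate_driver_dataset <- function(n_lakes = 24, seed = 1, noise_sd = 1.5) {
  if (n_lakes < 8) abort("`n_lakes` must be >= 8.", class = "lakegw_validation_error")
  withr_seed(seed)
  depth <- exp(log(2.9) + rnorm(n_lakes, 0, 0.45))
  covars <- tibble(
    depth = depth,
    lake_area = runif(n_lakes, 1.8, 11.6),
    catchment_area = exp(log(100) + rnorm(n_lakes, 0, 0.7)),
    slope = exp(log(8) + rnorm(n_lakes, 0, 0.5)),
    wetzone = exp(log(10) + rnorm(n_lakes, 0, 0.6)),
    mire = exp(log(8) + rnorm(n_lakes, 0, 0.6)),
    precipitation = runif(n_lakes, 300, 1000)
  )
  q <- reference_mlr_predict(covars$depth, covars$wetzone, covars$slope) +
    rnorm(n_lakes, 0, noise_sd)
  covars$q_gw <- pmax(q, 0.05)
  covars
}
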