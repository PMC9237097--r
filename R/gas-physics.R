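#' Air-water partition coefficient of radon-222
#'
#' Dimensionless water/air partition (Ostwald-type) coefficient of radon,
#' using the Weigel-form temperature dependence
#' k_aw(T) = 0.105 + 0.405 exp(-0.0502 T). The optional salinity correction
#' multiplies by exp(-0.138 S/35); study-type lakes are fresh, so the default
#' S = 0 leaves the temperature form untouched.
#'
#' @param temp Water temperature \[degC\], in \[-2, 40\].
#' @param salinity Salinity \[PSU\], non-negative. Default 0 (freshwater).
#' @return Partition coefficient in (0, 1), decreasing with temperature.
#' @examples
#' rn_air_water_partition(20)  # 0.2534
#' @export
rn_air_water_partition <- function(temp, salinity = 0) {
  if (any(temp < -2 | temp > 40)) {
    abort("`temp` must be within [-2, 40] degC.", class = "lakegw_domain_error")
  }
  if (any(salinity < 0)) abort("`salinity` must be >= 0.", class = "lakegw_domain_error")
  (0.105 + 0.405 * exp(-0.0502 * temp)) * exp(-0.138 * salinity / 35)
}

# Wanninkhof (1992) freshwater Schmidt-number polynomials, Sc = A - B*T + C*T^2 - D*T^3
SCHMIDT_COEFS <- list(
  ch4   = c(A = 1897.8, B = 114.28, C = 3.2902, D = 0.039061),
  rn222 = c(A = 3412.8, B = 224.30, C = 6.7954, D = 0.08300)
)

#' Schmidt number of a dissolved gas in freshwater
#'
#' Third-order polynomial in temperature (freshwater coefficients); valid for
#' 0-35 degC.
#'
#' @param gas `"rn222"` or `"ch4"`.
#' @param temp Water temperature \[degC\], in \[0, 35\]. Vectorised.
#' @return Dimensionless Schmidt number, decreasing with temperature.
#' @examples
#' schmidt_number("ch4", 20)  # ~616
#' @export
schmidt_number <- function(gas = c("rn222", "ch4"), temp) {
  gas <- match.arg(gas)
  if (any(temp < 0 | temp > 35)) {
    abort("`temp` must be within [0, 35] degC.", class = "lakegw_domain_error")
  }
  cf <- SCHMIDT_COEFS[[gas]]
  unname(cf[["A"]] - cf[["B"]] * temp + cf[["C"]] * temp^2 - cf[["D"]] * temp^3)
}

#' Gas-specific transfer velocity from k600
#'
#' k_gas = k600 * (Sc/600)^(-n). The Schmidt exponent follows the standard
#' wind-regime convention: n = 2/3 for smooth surfaces (u10 < 3.7 m s^-1),
#' n = 1/2 for rough surfaces (u10 >= 3.7 m s^-1).
#'
#' @param k600 Transfer velocity at Sc = 600 \[m d^-1\], positive.
#' @param gas `"rn222"` or `"ch4"`.
#' @param temp Water temperature \[degC\].
#' @param u10 Wind speed at 10 m \[m s^-1\]; selects the Schmidt exponent.
#' @return k for the gas at `temp`, in m d^-1.
#' @export
k_gas <- function(k600, gas, temp, u10) {
  if (any(k600 <= 0)) abort("`k600` must be positive.", class = "lakegw_validation_error")
  n <- ifelse(u10 < 3.7, 2 / 3, 1 / 2)
  sc <- schmidt_number(gas, temp)
  k600 * (sc / 600)^(-n)
}

#' Adjust measured wind speed to the 10 m reference height
#'
#' Neutral logarithmic wind profile with a fixed roughness length
#' z0 = 1e-4 m (smooth water): u10 = u_z * log(10/z0) / log(z/z0).
#' Heights at exactly 10 m pass through unchanged.
#'
#' @param speed Wind speed at measurement height \[m s^-1\].
#' @param height Measurement height \[m\], positive.
#' @return Wind speed at 10 m.
#' @export
wind_to_u10 <- function(speed, height = 10) {
  if (height <= 0) abort("`height` must be positive.", class = "lakegw_validation_error")
  z0 <- 1e-4
  speed * log(10 / z0) / log(height / z0)
}

#' Time-weighted effective gas transfer velocity before a sampling time
#'
#' Hourly winds preceding the sampling time are converted to hourly k values
#' and averaged with exponentially decaying weights w(dt) = exp(-dt/tau) over
#' a lookback window of 3*tau, normalised to sum to one. This gives degassing
#' events close to the sampling time more influence on the radon budget than
#' older ones, mirroring the tracer's own forgetting timescale.
#'
#' @param wind A wind tibble with columns `timestamp` (POSIXct or numeric
#'   hours) and `speed_m_s`, plus attribute or column `height_m` (defaults
#'   to 10 m).
#' @param sample_time Sampling time, same scale as `wind$timestamp`.
#' @param tau Weighting e-folding time \[d\], positive.
#' @param lake_area Lake area \[km2\] (for area-aware k models).
#' @param gas `"rn222"` or `"ch4"`.
#' @param temp Water temperature \[degC\].
#' @param model A [k_model()].
#' @return Effective k \[m d^-1\].
#' @export
weighted_k <- function(wind, sample_time, tau, lake_area, gas, temp,
                       model = k_model()) {
  stopifnot(tau > 0)
  t_h <- as.numeric(wind$timestamp)
  if (inherits(wind$timestamp, "POSIXct")) t_h <- t_h / 3600  # hours
  s_h <- as.numeric(sample_time)
  if (inherits(sample_time, "POSIXct")) s_h <- s_h / 3600
  dt_d <- (s_h - t_h) / 24                 # days before sampling
  keep <- dt_d >= 0 & dt_d <= 3 * tau
  if (!any(keep)) {
    abort(sprintf("wind record must cover the %.2f d window before the sample time",
                  3 * tau),
          class = "lakegw_validation_error")
  }
  height <- wind$height_m[1] %||% attr(wind, "height_m") %||% 10
  u10 <- wind_to_u10(wind$speed_m_s[keep], height)
  k_h <- k_gas(k600_from_wind(u10, lake_area, model), gas, temp, u10)
  w <- exp(-dt_d[keep] / tau)
  sum(w * k_h) / sum(w)
}

#' Atmospheric-equilibrium dissolved gas concentration
#'
#' For CH4, the Wiesenburg-Guinasso (1979) atmospheric-equilibrium solubility
#' function at salinity 0 is used, returning mmol m^-3 for a given dry-air
#' mixing ratio. For radon, equilibrium is the air activity concentration
#' times the air-water partition coefficient (with the default air radon of
#' zero the result is zero: air radon is negligible against lake water).
#'
#' @param gas `"rn222"` or `"ch4"`.
#' @param temp Water temperature \[degC\].
#' @param atm_mixing_ratio For CH4: mixing ratio \[ppm\] (default 1.9).
#'   For radon: air activity \[Bq m^-3\] (default 0).
#' @param pressure Total pressure \[atm\].
#' @return Equilibrium concentration: mmol m^-3 (CH4) or Bq m^-3 (rn222).
#' @export
equilibrium_conc <- function(gas = c("ch4", "rn222"), temp,
                             atm_mixing_ratio = NULL, pressure = 1) {
  gas <- match.arg(gas)
  if (gas == "rn222") {
    air <- atm_mixing_ratio %||% 0
    return(air * rn_air_water_partition(temp) * pressure)
  }
  ppm <- atm_mixing_ratio %||% CH4_ATM_PPM
  if (ppm == 0) return(0)
  TK <- temp + 273.15
  # Wiesenburg & Guinasso (1979), atmospheric equilibrium form, S = 0, nmol/L
  lnC <- log(ppm * 1e-6 * pressure) - 415.2807 + 596.8104 * (100 / TK) +
    379.2599 * log(TK / 100) - 62.0757 * (TK / 100)
  exp(lnC) * 1e-3  # nmol/L -> mmol m^-3
}

#' Diffusive gas flux across the air-water interface
#'
#' f_atm = k * (C_lake - C_eq). Positive when the lake is supersaturated
#' (evasion); negative fluxes (invasion) are returned unclamped.
#'
#' @param k Gas transfer velocity \[m d^-1\], positive.
#' @param c_lake Dissolved concentration in the lake (Bq m^-3 or mmol m^-3).
#' @param c_eq Atmospheric-equilibrium concentration, same unit.
#' @return Areal flux in concentration-unit * m d^-1.
#' @examples
#' atmospheric_flux(0.67, 110, 0)  # 73.7 Bq m^-2 d^-1
#' @export
atmospheric_flux <- function(k, c_lake, c_eq = 0) {
  if (any(k <= 0)) abort("`k` must be positive.", class = "lakegw_validation_error")
  k * (c_lake - c_eq)
}
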