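test_that("radon decay constant matches the half-life", {
  lam <- rn_decay_constant()
  expect_equal(lam, 0.18145, tolerance = 1e-4)
  expect_equal(exp(-lam * 3.82), 0.5)
  expect_equal(exp(-lam * 7.64), 0.25)
})

test_that("air-water partition follows the Weigel temperature form", {
  expect_equal(rn_air_water_partition(20), 0.105 + 0.405 * exp(-0.0502 * 20))
  expect_equal(rn_air_water_partition(20), 0.2534, tolerance = 1e-3)
  expect_equal(rn_air_water_partition(0), 0.510, tolerance = 1e-3)
  expect_lt(rn_air_water_partition(25), rn_air_water_partition(5))
  expect_error(rn_air_water_partition(45), class = "lakegw_domain_error")
})

test_that("Schmidt numbers evaluate the freshwater polynomials and decrease with T", {
  # CH4 polynomial at 20 degC, hand-evaluated: 1897.8 - 2285.6 + 1316.08 - 312.488
  expect_equal(schmidt_number("ch4", 20), 615.792, tolerance = 1e-6)
  expect_equal(schmidt_number("rn222", 20),
               3412.8 - 224.30 * 20 + 6.7954 * 400 - 0.08300 * 8000)
  expect_lt(schmidt_number("ch4", 30), schmidt_number("ch4", 10))
  expect_lt(schmidt_number("rn222", 30), schmidt_number("rn222", 10))
  expect_error(schmidt_number("co2", 20))
  expect_error(schmidt_number("ch4", 40), class = "lakegw_domain_error")
})

test_that("k600 models reproduce hand-computed values and unit conversion", {
  cc <- k_model("cole_caraco")
  expect_equal(k600_from_wind(0, 0.05, cc), 2.07 * 0.24, tolerance = 1e-10)
  expect_equal(k600_from_wind(5, 0.05, cc), (2.07 + 0.215 * 5^1.7) * 0.24)
  vp <- k_model("vachon_prairie")
  expect_equal(k600_from_wind(3, 0.05, vp),
               (2.51 + 1.48 * 3 + 0.39 * 3 * log10(0.05)) * 0.24)
})

test_that("evaluations outside the calibration domain warn but still return", {
  expect_warning(k <- k600_from_wind(16, 0.05, k_model("wind_46lakes")),
                 class = "lakegw_domain_warning")
  expect_gt(k, 0)
  expect_warning(k600_from_wind(3, 2000, k_model("wind_46lakes")),
                 class = "lakegw_domain_warning")
})

test_that("k model coefficients are overridable and validated", {
  m <- k_model("wind_46lakes", coefficients = list(a = 3, b = 1, c = 0))
  expect_equal(k600_from_wind(2, 0.05, m), (3 + 2) * 0.24)
  expect_error(k_model("wind_46lakes", coefficients = list(a = Inf)),
               class = "lakegw_validation_error")
  expect_error(k_model("wind_46lakes", wind_range = c(5, 1)),
               class = "lakegw_validation_error")
})

test_that("Schmidt-number scaling of k is exact at the identities", {
  # Sc = 600 -> k unchanged: pick the temperature where Sc_ch4 = 600
  f <- function(t) schmidt_number("ch4", t) - 600
  t600 <- uniroot(f, c(15, 25))$root
  expect_equal(k_gas(1.5, "ch4", t600, u10 = 5), 1.5, tolerance = 1e-6)
  # (150/600)^(-1/2) = 2 at rough-surface exponent; check scaling law directly
  sc <- schmidt_number("ch4", 20)
  expect_equal(k_gas(1.0, "ch4", 20, u10 = 5), (sc / 600)^(-0.5))
  expect_equal(k_gas(1.0, "ch4", 20, u10 = 2), (sc / 600)^(-2 / 3))
  expect_error(k_gas(0, "ch4", 20, 5), class = "lakegw_validation_error")
})

test_that("wind weighting reduces to plain k under constant wind (any model)", {
  wind <- tibble::tibble(timestamp = 1:240, speed_m_s = 6.2, height_m = 10)
  for (nm in c("wind_46lakes", "cole_caraco", "vachon_prairie")) {
    m <- k_model(nm)
    kw <- weighted_k(wind, 240, tau = 2, lake_area = 0.05, gas = "rn222",
                     temp = 15, model = m)
    kc <- k_gas(k600_from_wind(6.2, 0.05, m), "rn222", 15, 6.2)
    expect_equal(kw, kc, tolerance = 1e-12)
  }
})

test_that("two-point wind weighting matches the hand-computed weighted sum", {
  # speeds 2 and 4 m/s one hour apart, tau = 1 d, sampled at the later hour
  wind <- tibble::tibble(timestamp = c(1, 2), speed_m_s = c(2, 4), height_m = 10)
  got <- weighted_k(wind, 2, tau = 1, lake_area = 0.05, gas = "rn222",
                    temp = 15, model = k_model("cole_caraco"))
  sc <- schmidt_number("rn222", 15)
  k2 <- (2.07 + 0.215 * 2^1.7) * 0.24 * (sc / 600)^(-2 / 3)  # u < 3.7
  k4 <- (2.07 + 0.215 * 4^1.7) * 0.24 * (sc / 600)^(-1 / 2)  # u >= 3.7
  w1 <- exp(-(1 / 24) / 1)
  expect_equal(got, (k4 + w1 * k2) / (1 + w1), tolerance = 1e-12)
})

test_that("wind weighting fails loudly without history and collapses to last hour", {
  wind <- tibble::tibble(timestamp = 1:48, speed_m_s = runif(48, 2, 8), height_m = 10)
  expect_error(weighted_k(wind, 500, tau = 0.5, lake_area = 0.05,
                          gas = "rn222", temp = 15),
               class = "lakegw_validation_error")
  # tau -> 0 limit: all weight at the most recent hour
  k_small_tau <- weighted_k(wind, 48, tau = 1e-4, lake_area = 0.05,
                            gas = "rn222", temp = 15)
  u_last <- wind$speed_m_s[48]
  expect_equal(k_small_tau,
               k_gas(k600_from_wind(u_last, 0.05, k_model()), "rn222", 15, u_last))
})

test_that("equilibrium concentrations behave at the limits and the chosen solubility", {
  expect_equal(equilibrium_conc("ch4", 20, 0, 1), 0)
  expect_equal(equilibrium_conc("rn222", 12), 0)  # default air radon ~ 0
  # solubility function evaluated at 20 degC x 1.9 ppm (frozen from the
  # documented atmospheric-equilibrium form, S = 0)
  expect_equal(equilibrium_conc("ch4", 20, 1.9, 1), 0.002873362, tolerance = 1e-5)
  # colder water holds more gas
  expect_gt(equilibrium_conc("ch4", 4, 1.9, 1), equilibrium_conc("ch4", 24, 1.9, 1))
})

test_that("atmospheric flux is the linear evasion law with sign preserved", {
  expect_equal(atmospheric_flux(0.67, 110, 0), 73.7)
  expect_equal(atmospheric_flux(1, 5, 5), 0)
  expect_lt(atmospheric_flux(0.5, 0.001, 0.003), 0)  # invasion not clamped
  # linear in k and in the concentration difference
  expect_equal(atmospheric_flux(2 * 0.67, 110, 0), 2 * atmospheric_flux(0.67, 110, 0))
  expect_equal(atmospheric_flux(0.67, 220, 110), atmospheric_flux(0.67, 110, 0))
})

test_that("wind height adjustment uses the neutral log profile", {
  expect_equal(wind_to_u10(5, 10), 5)
  expect_equal(wind_to_u10(5, 2), 5 * log(10 / 1e-4) / log(2 / 1e-4))
  expect_gt(wind_to_u10(5, 2), 5)   # measured low -> faster at 10 m
  expect_lt(wind_to_u10(5, 30), 5)
})
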