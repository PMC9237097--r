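make_survey <- function(c_lake = 110, q_in = 0, c_in = 520, q_out = 6000,
                        f_diff = 10, c_ra = 20, A = 5e4, V = 1e5) {
  samples <- tibble::tibble(
    lake_id = "T", season = "summer",
    source = c("lake_surface", "inlet", "outlet", "groundwater"),
    rn_bq_m3 = c(c_lake, c_in, c_lake, 3500),
    ch4_umol_l = c(0.2, 0.02, 0.2, 150), temp_c = 12
  )
  wind <- tibble::tibble(timestamp = 1:120, speed_m_s = 4, height_m = 10)
  suppressMessages(lake_survey(
    geometry = lake_geometry("T", A, V, V / A),
    samples = samples, wind = wind,
    flows = list(q_inlet = uv(q_in, 0), q_outlet = uv(q_out, 0)),
    f_diff = uv(f_diff, 0), c_ra_lake = uv(c_ra, 0), season = "summer"
  ))
}

test_that("budget terms reproduce hand-computed products", {
  sv <- make_survey(c_lake = 110, q_in = 0, f_diff = 10, A = 5e4, V = 1e5)
  terms <- suppressMessages(compute_terms(sv, k_rn = 0.67))
  g <- function(nm) terms$value[terms$term == nm]
  expect_equal(g("F_decay"), rn_decay_constant() * 1e5 * 110)     # 1.996e6
  expect_equal(g("F_decay"), 1.996e6, tolerance = 1e-3)
  expect_equal(g("F_inlet"), 0)
  expect_equal(g("F_diff"), 10 * 5e4)
  expect_equal(g("F_atm"), 0.67 * 110 * 5e4)
  expect_equal(g("F_Ra"), rn_decay_constant() * 1e5 * 20)
  expect_true(all(terms$value >= 0))
})

test_that("missing required concentrations abort the budget", {
  sv <- make_survey(q_in = 1000)
  sv$samples <- dplyr::filter(sv$samples, source != "inlet")
  expect_error(suppressMessages(compute_terms(sv, 0.67)), "inlet",
               class = "lakegw_validation_error")
  sv2 <- make_survey()
  sv2$samples$rn_bq_m3[sv2$samples$source == "lake_surface"] <- NA
  sv2$samples$ch4_umol_l[sv2$samples$source == "lake_surface"] <- 0.2
  expect_error(suppressMessages(compute_terms(sv2, 0.67)), "lake_surface",
               class = "lakegw_validation_error")
})

test_that("the steady-state inversion closes the six-term balance", {
  terms <- tibble::tibble(
    term = c("F_diff", "F_inlet", "F_Ra", "F_atm", "F_outlet", "F_decay"),
    role = c("source", "source", "source", "sink", "sink", "sink"),
    value = c(5e5, 0, 3.629e5, 3.685e6, 6.6e5, 1.996e6),
    sigma = 0
  )
  sol <- solve_fgw(terms)
  expect_equal(sol$f_gw$value, 3.685e6 + 6.6e5 + 1.996e6 - 5e5 - 0 - 3.629e5)
  expect_equal(sol$f_gw$value, 5.4781e6, tolerance = 1e-6)
  expect_false(sol$truncated)
  # closure: residual of the balance with the solved flux is ~0
  resid <- sol$f_gw$value + 5e5 + 0 + 3.629e5 - 3.685e6 - 6.6e5 - 1.996e6
  expect_lt(abs(resid) / max(terms$value), 1e-12)

  zero <- dplyr::mutate(terms, value = 0)
  expect_equal(solve_fgw(zero)$f_gw$value, 0)
  expect_false(solve_fgw(zero)$truncated)

  flipped <- dplyr::mutate(terms, value = rev(value))
  sol2 <- solve_fgw(dplyr::mutate(terms, value = c(5e6, 5e6, 5e6, 1e5, 0, 1e5)))
  expect_equal(sol2$f_gw$value, 0)
  expect_true(sol2$truncated)
})

test_that("uncertainty propagates in quadrature and vanishes with exact inputs", {
  sv <- make_survey()
  terms <- suppressMessages(compute_terms(sv, 0.67))
  expect_true(all(terms$sigma == 0))
  sol <- solve_fgw(terms)
  expect_equal(sol$f_gw$sigma, 0)
  terms$sigma <- c(1e4, 0, 2e4, 5e4, 1e4, 3e4)
  s1 <- solve_fgw(terms)$f_gw$sigma
  expect_equal(s1, sqrt(sum(terms$sigma^2)))
  terms$sigma <- 2 * terms$sigma
  expect_equal(solve_fgw(terms)$f_gw$sigma, 2 * s1)
})

test_that("residence time follows the three-loss formula and its limits", {
  expect_equal(residence_time(0.67, 2.8, 0.06 * 1e5, 1e5),
               1 / (rn_decay_constant() + 0.06 + 0.67 / 2.8))
  expect_equal(residence_time(0.67, 2.8, 0.06 * 1e5, 1e5), 2.0801, tolerance = 1e-4)
  # decay-only limit
  expect_equal(residence_time(1e-12, 2.8, 0, 1e5), 1 / rn_decay_constant(),
               tolerance = 1e-6)
  expect_equal(1 / rn_decay_constant(), 5.511, tolerance = 1e-3)
  expect_lt(residence_time(1.34, 2.8, 6000, 1e5),
            residence_time(0.67, 2.8, 6000, 1e5))
  expect_error(residence_time(0, 2.8, 0, 1e5), class = "lakegw_validation_error")
})

test_that("steady-state diagnostics flag unstable wind", {
  const_wind <- tibble::tibble(timestamp = 1:240, speed_m_s = 5)
  expect_true(steady_state_check(2, const_wind)$ok)

  # 5x step change one day before sampling
  step <- tibble::tibble(timestamp = 1:96,
                         speed_m_s = c(rep(2, 72), rep(10, 24)))
  chk <- steady_state_check(1, step, window = 3)
  daily <- c(10, 2, 2)  # hand: most recent day at 10, two days at 2
  expect_false(chk$ok)
  expect_equal(chk$cv, sd(daily) / mean(daily), tolerance = 0.05)

  empty <- tibble::tibble(timestamp = numeric(), speed_m_s = numeric())
  chk0 <- steady_state_check(2, empty)
  expect_false(chk0$ok)
  expect_match(chk0$diagnostic, "insufficient history")
})

test_that("deep samples are excluded from the budget concentration", {
  sv <- make_survey()
  deep <- tibble::tibble(lake_id = "T", season = "summer", source = "lake_deep",
                         rn_bq_m3 = 1e4, ch4_umol_l = 0.2, temp_c = 12)
  sv$samples <- dplyr::bind_rows(sv$samples, deep)
  terms <- suppressMessages(compute_terms(sv, 0.67))
  expect_equal(terms$value[terms$term == "F_decay"],
               rn_decay_constant() * 1e5 * 110)
})

test_that("the full budget wrapper recovers imposed fluxes on synthetic data", {
  gs <- suppressMessages(generate_survey(
    list(conc_rel_sigma = 0, flow_rel_sigma = 0, f_diff_rel_sigma = 0),
    seed = 11
  ))
  b <- suppressMessages(rn_budget(gs$survey))
  expect_s3_class(b, "rn_budget")
  expect_equal(b$f_gw$value, gs$truth$f_gw_bq_d, tolerance = 1e-9)
  expect_false(b$truncated)
  td <- tidy(b)
  expect_equal(nrow(td), 7)
  expect_true("F_gw" %in% td$term)
  expect_equal(glance(b)$tau_d, b$tau_d)
})
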