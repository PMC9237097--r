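test_that("flux draws honour the truncated-normal contract", {
  expect_equal(draw_fgw(uv(5e6, 0), n = 10, seed = 1), rep(5e6, 10))
  d <- draw_fgw(uv(100, 10), n = 1e5, seed = 4)
  expect_equal(mean(d), 100, tolerance = 3 * 10 / sqrt(1e5) / 100)
  d0 <- draw_fgw(uv(0, 50), n = 5000, seed = 9)
  expect_true(all(d0 >= 0))
  expect_error(draw_fgw(uv(1, -1), 10, 1), class = "lakegw_validation_error")
  expect_identical(draw_fgw(uv(100, 10), 100, seed = 7),
                   draw_fgw(uv(100, 10), 100, seed = 7))
})

test_that("single-endmember conversions are exact arithmetic", {
  em <- tibble::tibble(rn_bq_m3 = 3500, ch4_umol_l = 150)
  q <- inflow_from_draws(5.478e6, em, A = 5e4, seed = 1)
  expect_equal(q, 5.478e6 / 3500 / 5e4 * 100)
  expect_equal(q, 3.13, tolerance = 1e-3)
  ch4 <- ch4_from_draws(5.478e6, em, A = 5e4, seed = 1)
  expect_equal(ch4, 5.478e6 / (3500 / 150) * 16.04 / 5e4)
  expect_equal(ch4, 75.3, tolerance = 1e-3)
  # zero flux propagates to zero everywhere
  expect_equal(inflow_from_draws(rep(0, 5), em, 5e4, 1), rep(0, 5))
  # paired and independent modes coincide with one endmember
  expect_equal(ch4_from_draws(rep(1e6, 50), em, 5e4, seed = 3, mode = "paired"),
               ch4_from_draws(rep(1e6, 50), em, 5e4, seed = 3, mode = "independent"))
})

test_that("endmember validation rejects degenerate divisors", {
  expect_error(inflow_from_draws(1, tibble::tibble(rn_bq_m3 = numeric(),
                                                   ch4_umol_l = numeric()),
                                 5e4, 1),
               class = "lakegw_validation_error")
  bad <- tibble::tibble(rn_bq_m3 = c(3500, 0), ch4_umol_l = c(150, 150))
  expect_error(inflow_from_draws(1, bad, 5e4, 1), class = "lakegw_validation_error")
  bad2 <- tibble::tibble(rn_bq_m3 = c(3500, 3500), ch4_umol_l = c(150, 0))
  expect_error(ch4_from_draws(1, bad2, 5e4, 1), class = "lakegw_validation_error")
})

test_that("draw summaries follow the fixed percentile convention", {
  s <- summarize_draws(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$p25, 25.75)
  expect_equal(s$p75, 75.25)
  sc <- summarize_draws(rep(7, 10))
  expect_true(all(unlist(sc) == 7))
  perm <- sample(1:100)
  expect_equal(summarize_draws(perm), s)
  expect_error(summarize_draws(numeric()), class = "lakegw_validation_error")
})

test_that("large-sample Monte-Carlo median matches an independent ratio oracle", {
  em <- sample_endmembers(n = 41, seed = 12)
  f <- uv(5.478e6, 5.478e5)
  draws <- inflow_from_draws(draw_fgw(f, 1e5, seed = 2), em, A = 5e4, seed = 3)
  # oracle: direct simulation of the ratio distribution with plain base R
  set.seed(777)
  fo <- rnorm(1e6, f$value, f$sigma)
  fo[fo < 0] <- abs(rnorm(sum(fo < 0), f$value, f$sigma))  # negligible mass
  co <- sample(em$rn_bq_m3, 1e6, replace = TRUE)
  oracle_median <- median(fo / co / 5e4 * 100)
  expect_equal(median(draws), oracle_median, tolerance = 0.02)
})

test_that("ensemble summaries are stable in n and deterministic under seed", {
  em <- sample_endmembers(n = 41, seed = 21)
  b <- list(f_gw = uv(5e6, 8e5), lake_id = "L1", season = "summer",
            truncated = FALSE)
  mc1 <- run_mc(b, em, A = 5e4, n_iter = 1000, seed = 5)
  mc2 <- run_mc(b, em, A = 5e4, n_iter = 1000, seed = 5)
  expect_identical(mc1$q_gw_draws, mc2$q_gw_draws)
  expect_identical(mc1$summary, mc2$summary)
  expect_equal(length(mc1$ch4_draws), 1000)
  expect_true(all(mc1$q_gw_draws >= 0))
  s <- mc1$summary
  expect_true(all(s$p25 <= s$median & s$median <= s$p75))
  # n = 1000 summaries agree with a 1e5-draw run within Monte-Carlo error
  mc_big <- run_mc(b, em, A = 5e4, n_iter = 1e5, seed = 5)
  q1 <- s$median[s$quantity == "q_gw_cm_d"]
  qb <- mc_big$summary$median[mc_big$summary$quantity == "q_gw_cm_d"]
  expect_equal(q1, qb, tolerance = 0.1)
})

test_that("per-lake seeding is order independent", {
  em <- sample_endmembers(n = 41, seed = 30)
  b1 <- list(f_gw = uv(5e6, 8e5), lake_id = "A", season = "summer", truncated = FALSE)
  b2 <- list(f_gw = uv(3e6, 5e5), lake_id = "B", season = "summer", truncated = FALSE)
  r12 <- list(run_mc(b1, em, 5e4, 500, seed = 9), run_mc(b2, em, 5e4, 500, seed = 9))
  r21 <- list(run_mc(b2, em, 5e4, 500, seed = 9), run_mc(b1, em, 5e4, 500, seed = 9))
  expect_identical(r12[[1]]$q_gw_draws, r21[[2]]$q_gw_draws)
  expect_identical(r12[[2]]$summary, r21[[1]]$summary)
})

test_that("degenerate endmembers with tight sigmas recover truth within 2%", {
  gs <- suppressMessages(generate_survey(list(
    conc_rel_sigma = 0.01, flow_rel_sigma = 0.01, f_diff_rel_sigma = 0.01,
    rn_gw = list(median = 3500, p25 = 3500, p75 = 3500),
    ch4_gw = list(median = 150, p25 = 150, p75 = 150)
  ), seed = 17))
  b <- suppressMessages(rn_budget(gs$survey))
  mc <- run_mc(b, gs$survey$endmembers, gs$survey$geometry$area_m2,
               n_iter = 2000, seed = 17)
  med <- mc$summary$median[mc$summary$quantity == "q_gw_cm_d"]
  expect_equal(med, gs$truth$q_gw_cm_d, tolerance = 0.02)
})
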