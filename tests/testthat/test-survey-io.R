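test_that("a generated survey round-trips through disk exactly", {
  gs <- suppressMessages(generate_survey(seed = 1))
  dir <- withr::local_tempdir()
  cfg <- write_survey(gs$survey, dir)
  sv <- suppressMessages(load_survey(cfg))
  expect_s3_class(sv, "lake_survey")
  expect_equal(nrow(sv$endmembers), 41)
  expect_equal(sv$samples$rn_bq_m3, gs$survey$samples$rn_bq_m3)
  expect_equal(sv$wind$speed_m_s, gs$survey$wind$speed_m_s)
  expect_equal(sv$flows$q_inlet$value, gs$survey$flows$q_inlet$value)
  expect_equal(sv$f_diff$value, gs$survey$f_diff$value)
  expect_equal(sv$geometry$volume_m3, gs$survey$geometry$volume_m3)
})

test_that("config and schema violations are reported by name", {
  gs <- suppressMessages(generate_survey(seed = 2))
  dir <- withr::local_tempdir()
  cfg_path <- write_survey(gs$survey, dir)
  cfg <- yaml::read_yaml(cfg_path)

  # config lacking the wind table
  cfg2 <- cfg; cfg2$wind <- NULL
  p2 <- file.path(dir, "no_wind.yml")
  yaml::write_yaml(cfg2, p2)
  expect_error(load_survey(p2), "wind", class = "lakegw_validation_error")

  # negative radon concentration cites non-negativity and the row
  bad <- readr::read_csv(file.path(dir, "samples.csv"), show_col_types = FALSE)
  bad$rn_bq_m3[3] <- -5
  readr::write_csv(bad, file.path(dir, "samples.csv"))
  expect_error(suppressMessages(load_survey(cfg_path)), "negative rn",
               class = "lakegw_validation_error")

  expect_error(load_survey(file.path(dir, "nope.yml")),
               class = "lakegw_input_error")
})

test_that("per-source summaries use linear-interpolation percentiles", {
  s <- tibble::tibble(
    lake_id = "L", season = "summer", source = "lake_surface",
    rn_bq_m3 = c(1, 2, 3, 4), ch4_umol_l = NA_real_, temp_c = 10
  )
  s$ch4_umol_l[1] <- 0.5  # keep the no-analyte invariant satisfied
  out <- summarize_sources(s)
  rn <- out[out$analyte == "rn_bq_m3", ]
  expect_equal(rn$median, 2.5)
  expect_equal(rn$p25, 1.75)
  expect_equal(rn$p75, 3.25)

  one <- summarize_sources(tibble::tibble(
    lake_id = "L", season = "summer", source = "groundwater",
    rn_bq_m3 = 3500, ch4_umol_l = 150, temp_c = 6
  ))
  expect_true(all(one$median == one$p25 & one$median == one$p75))
})

test_that("generator endmember CH4 distribution matches its calibration anchor", {
  em <- sample_endmembers(n = 1000, seed = 7)
  med <- median(em$ch4_umol_l)
  expect_lt(abs(med - 150) / 150, 0.10)
})

test_that("validation rejects malformed sample tables", {
  base <- tibble::tibble(lake_id = "L", season = "summer", source = "lake_surface",
                         rn_bq_m3 = 100, ch4_umol_l = 0.2, temp_c = 10)
  expect_silent(validate_samples(base))
  expect_error(validate_samples(dplyr::mutate(base, rn_bq_m3 = -1)),
               "negative", class = "lakegw_validation_error")
  expect_error(validate_samples(dplyr::mutate(base, source = "river")),
               "unknown source", class = "lakegw_validation_error")
  expect_error(validate_samples(dplyr::mutate(base, rn_bq_m3 = NA, ch4_umol_l = NA)),
               class = "lakegw_validation_error")
  expect_error(validate_samples(base[, -3]), "source",
               class = "lakegw_validation_error")
})

test_that("write_results is deterministic and always writes metadata", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  tbl <- tibble::tibble(a = c(1.123456789012345, 2), b = c("x", "y"))
  m1 <- write_results(list(mc_summary = tbl), d1, seed = 11)
  m2 <- write_results(list(mc_summary = tbl), d2, seed = 11)
  expect_true(file.exists(file.path(d1, "mc_summary.csv")))
  expect_true(file.exists(file.path(d1, "run_meta.json")))
  expect_identical(readLines(file.path(d1, "mc_summary.csv")),
                   readLines(file.path(d2, "mc_summary.csv")))
  expect_setequal(m1$file, c("mc_summary.csv", "run_meta.json"))

  m0 <- write_results(list(), withr::local_tempdir(), seed = 1)
  expect_equal(nrow(m0), 1)
  expect_equal(m0$kind, "metadata")
})

test_that("below-detection CH4 is replaced by atmospheric equilibrium", {
  gs <- suppressMessages(generate_survey(seed = 5))
  s <- gs$survey$samples
  s$ch4_below_detection <- FALSE
  s$ch4_below_detection[s$source == "lake_surface"][1] <- TRUE
  sv <- suppressMessages(lake_survey(
    geometry = gs$survey$geometry, samples = s, wind = gs$survey$wind,
    flows = gs$survey$flows, f_diff = gs$survey$f_diff,
    c_ra_lake = gs$survey$c_ra_lake, season = gs$survey$season
  ))
  i <- which(sv$samples$source == "lake_surface")[1]
  expect_equal(sv$samples$ch4_umol_l[i],
               equilibrium_conc("ch4", sv$samples$temp_c[i]))
})

test_that("geometry consistency and positivity are enforced", {
  expect_error(lake_geometry("L", -1, 10, 1), class = "lakegw_validation_error")
  expect_warning(lake_geometry("L", 1e4, 1e5, 2),  # V/A = 10 vs h = 2
                 class = "lakegw_consistency_warning")
  g <- lake_geometry("L", 5e4, 1.4e5, 2.8)
  expect_equal(g$mean_depth_m, 2.8)
})
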