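#' Lake geometry and catchment covariates
#'
#' @param lake_id Character scalar.
#' @param area_m2,volume_m3,mean_depth_m Positive lake dimensions.
#' @param covariates Optional named list of catchment covariates
#'   (catchment_area \[ha\], slope \[%\], wetzone \[% cover\], mire
#'   \[% cover\], precipitation \[mm yr^-1\], lake_area \[ha\]).
#'
#' @details A consistency warning is raised when the stated mean depth
#'   disagrees with volume/area by more than 25%.
#' @return An object of class `"lake_geometry"`.
#' @export
lake_geometry <- function(lake_id, area_m2, volume_m3, mean_depth_m,
                          covariates = list()) {
  if (!is.character(lake_id) || length(lake_id) != 1L || !nzchar(lake_id)) {
    abort("`lake_id` must be a non-empty string.", class = "lakegw_validation_error")
  }
  for (nm in c("area_m2", "volume_m3", "mean_depth_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
            class = "lakegw_validation_error")
    }
  }
  implied <- volume_m3 / area_m2
  if (abs(mean_depth_m - implied) / mean_depth_m > 0.25) {
    warn(sprintf(
      "mean depth %.2f m differs from V/A = %.2f m by more than 25%%",
      mean_depth_m, implied
    ), class = "lakegw_consistency_warning")
  }
  structure(list(lake_id = lake_id, area_m2 = area_m2, volume_m3 = volume_m3,
                 mean_depth_m = mean_depth_m, covariates = covariates),
            class = "lake_geometry")
}

SAMPLE_SOURCES <- c("lake_surface", "lake_deep", "inlet", "outlet", "groundwater")
SEASONS <- c("summer", "autumn")

#' Validate a tracer sample table
#'
#' Checks the per-sample schema: recognised `source` and `season` levels,
#' non-negative concentrations, and that every row carries at least one of
#' radon or CH4. Violations raise a validation error listing offending rows.
#'
#' @param samples Data frame with columns `lake_id`, `season`, `source`,
#'   `rn_bq_m3`, `ch4_umol_l`, `temp_c` and optionally `timestamp` and
#'   `ch4_below_detection`.
#' @return The validated samples as a tibble (invisibly usable in pipes).
#' @export
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  required <- c("lake_id", "season", "source", "rn_bq_m3", "ch4_umol_l", "temp_c")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(paste0("samples table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lakegw_validation_error")
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      abort(sprintf("samples: %s in row(s) %s", what,
                    paste(head(rows, 10), collapse = ", ")),
            class = "lakegw_validation_error")
    }
  }
  bad(!samples$source %in% SAMPLE_SOURCES, "unknown source")
  bad(!samples$season %in% SEASONS, "unknown season")
  bad(!is.na(samples$rn_bq_m3) & samples$rn_bq_m3 < 0, "negative rn_bq_m3")
  bad(!is.na(samples$ch4_umol_l) & samples$ch4_umol_l < 0, "negative ch4_umol_l")
  bad(is.na(samples$rn_bq_m3) & is.na(samples$ch4_umol_l),
      "neither rn nor ch4 present")
  samples
}

#' Extract the groundwater endmember set from a sample table
#'
#' Endmembers are groundwater samples with both radon and CH4 measured;
#' radon must be strictly positive because it is used as a divisor in the
#' Monte-Carlo inflow conversion.
#'
#' @param samples A validated samples tibble.
#' @return A tibble of endmembers (columns `rn_bq_m3`, `ch4_umol_l`, ...).
#' @export
endmember_set <- function(samples) {
  em <- dplyr::filter(samples, .data$source == "groundwater",
                      !is.na(.data$rn_bq_m3), !is.na(.data$ch4_umol_l))
  if (nrow(em) < 1L) {
    abort("no complete groundwater endmember samples (need rn and ch4).",
          class = "lakegw_validation_error")
  }
  if (any(em$rn_bq_m3 <= 0)) {
    abort("groundwater endmember rn_bq_m3 must be > 0 (used as divisor).",
          class = "lakegw_validation_error")
  }
  em
}

#' Assemble a survey bundle for one lake and season
#'
#' A survey bundle collects everything the radon budget needs: geometry,
#' tracer samples, hourly wind, stream flows, the sediment diffusive radon
#' flux and the dissolved radium concentration. Missing streams are treated
#' as zero flux and flagged. CH4 values marked below detection are replaced
#' by the atmospheric-equilibrium concentration at the sample temperature.
#'
#' @param geometry A [lake_geometry()].
#' @param samples Samples data frame (see [validate_samples()]).
#' @param wind Tibble with `timestamp`, `speed_m_s` and optionally
#'   `height_m` (m; defaults to 10).
#' @param flows List with `q_inlet` and `q_outlet` as [uv()] (m3 d^-1), or
#'   `NULL` for a lake without mapped streams.
#' @param f_diff Sediment diffusive radon flux \[Bq m^-2 d^-1\] as [uv()].
#' @param c_ra_lake Dissolved 226Ra in lake water \[Bq m^-3\] as [uv()].
#' @param season `"summer"` or `"autumn"`.
#' @param endmembers Optional endmember tibble; defaults to
#'   [endmember_set()] of `samples` when groundwater rows are present.
#' @return An object of class `"lake_survey"`.
#' @export
lake_survey <- function(geometry, samples, wind, flows, f_diff, c_ra_lake,
                        season = c("summer", "autumn"), endmembers = NULL) {
  season <- match.arg(season)
  stopifnot(inherits(geometry, "lake_geometry"))
  samples <- validate_samples(samples)
  if (!any(samples$source == "lake_surface")) {
    abort("survey must contain lake_surface samples.",
          class = "lakegw_validation_error")
  }
  wind <- as_tibble(wind)
  if (!all(c("timestamp", "speed_m_s") %in% names(wind))) {
    abort("wind table must have columns `timestamp` and `speed_m_s`.",
          class = "lakegw_validation_error")
  }
  if (any(wind$speed_m_s < 0)) {
    abort("wind speeds must be non-negative.", class = "lakegw_validation_error")
  }
  if (is.unsorted(as.numeric(wind$timestamp), strictly = TRUE)) {
    abort("wind timestamps must be strictly increasing.",
          class = "lakegw_validation_error")
  }
  stream_missing <- is.null(flows)
  if (stream_missing) {
    inform("no stream flows supplied; inlet/outlet fluxes treated as zero.",
           class = "lakegw_default_note")
    flows <- list(q_inlet = uv(0, 0), q_outlet = uv(0, 0))
  }
  flows$q_inlet <- as_uv(flows$q_inlet)
  flows$q_outlet <- as_uv(flows$q_outlet)
  if (flows$q_inlet$value < 0 || flows$q_outlet$value < 0) {
    abort("stream discharges must be >= 0.", class = "lakegw_validation_error")
  }
  # below-detection CH4 -> atmospheric equilibrium at the sample temperature
  if ("ch4_below_detection" %in% names(samples)) {
    bd <- which(samples$ch4_below_detection %in% TRUE)
    for (i in bd) {
      samples$ch4_umol_l[i] <- equilibrium_conc("ch4", samples$temp_c[i])
    }
    if (length(bd)) {
      inform(sprintf("replaced %d below-detection CH4 value(s) with atmospheric equilibrium.",
                     length(bd)), class = "lakegw_default_note")
    }
  }
  if (is.null(endmembers) && any(samples$source == "groundwater")) {
    endmembers <- endmember_set(samples)
  }
  structure(list(
    geometry = geometry, samples = samples, endmembers = endmembers,
    wind = wind, flows = flows, f_diff = as_uv(f_diff),
    c_ra_lake = as_uv(c_ra_lake), season = season,
    stream_missing = stream_missing
  ), class = "lake_survey")
}

#' @export
print.lake_survey <- function(x, ...) {
  cat("<lake_survey>", x$geometry$lake_id, "|", x$season, "\n")
  cat("  A =", x$geometry$area_m2, "m2, V =", x$geometry$volume_m3,
      "m3, h =", x$geometry$mean_depth_m, "m\n")
  cat("  samples:", nrow(x$samples), "| endmembers:",
      if (is.null(x$endmembers)) 0 else nrow(x$endmembers),
      "| wind hours:", nrow(x$wind), "\n")
  invisible(x)
}

#' Load a survey bundle from a run configuration file
#'
#' The configuration is a single YAML file whose paths are resolved relative
#' to its own directory. Required keys: `lake_id`, `season`, `samples`
#' (CSV path), `wind` (CSV path), `geometry` (CSV path), `f_diff`
#' (`value`/`sigma`), `c_ra_lake` (`value`/`sigma`). Optional: `flows`
#' (CSV path; absent means no mapped streams -> zero flux, flagged),
#' `wind_height_m` (default 10, logged when defaulted).
#'
#' @param config_path Path to the YAML configuration.
#' @return A [lake_survey()].
#' @export
load_survey <- function(config_path) {
  if (!file.exists(config_path)) {
    abort(paste0("config file not found: ", config_path),
          class = "lakegw_input_error")
  }
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  need <- c("lake_id", "season", "samples", "wind", "geometry", "f_diff", "c_ra_lake")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    abort(paste0("config missing key(s): ", paste(miss, collapse = ", ")),
          class = "lakegw_validation_error")
  }
  path_of <- function(p) {
    p2 <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(p2)) {
      abort(paste0("referenced file not found: ", p), class = "lakegw_input_error")
    }
    p2
  }
  read_tbl <- function(p) readr::read_csv(path_of(p), show_col_types = FALSE,
                                          progress = FALSE)
  samples <- validate_samples(read_tbl(cfg$samples))
  samples <- dplyr::filter(samples, .data$season == cfg$season |
                             .data$source == "groundwater")
  wind <- read_tbl(cfg$wind)
  if (is.null(cfg$wind_height_m)) {
    inform("wind_height_m not set; defaulting to 10 m.",
           class = "lakegw_default_note")
    cfg$wind_height_m <- 10
  }
  wind$height_m <- cfg$wind_height_m
  geom_tbl <- read_tbl(cfg$geometry)
  g <- dplyr::filter(geom_tbl, .data$lake_id == cfg$lake_id)
  if (nrow(g) != 1L) {
    abort(paste0("geometry table must have exactly one row for lake ", cfg$lake_id),
          class = "lakegw_validation_error")
  }
  covar_cols <- setdiff(names(g), c("lake_id", "area_m2", "volume_m3", "mean_depth_m"))
  geometry <- lake_geometry(g$lake_id, g$area_m2, g$volume_m3, g$mean_depth_m,
                            covariates = as.list(g[covar_cols]))
  flows <- NULL
  if (!is.null(cfg$flows)) {
    f <- read_tbl(cfg$flows)
    f <- dplyr::filter(f, .data$lake_id == cfg$lake_id, .data$season == cfg$season)
    if (nrow(f) == 1L) {
      flows <- list(q_inlet = uv(f$q_inlet_m3_d, f$q_inlet_sigma),
                    q_outlet = uv(f$q_outlet_m3_d, f$q_outlet_sigma))
    }
  }
  lake_survey(
    geometry = geometry, samples = samples, wind = wind, flows = flows,
    f_diff = uv(cfg$f_diff$value, cfg$f_diff$sigma %||% 0),
    c_ra_lake = uv(cfg$c_ra_lake$value, cfg$c_ra_lake$sigma %||% 0),
    season = cfg$season
  )
}

#' Per-source concentration summaries
#'
#' Median and interquartile range of radon and CH4 by water source, the
#' summary convention used for all distributional reporting. Percentiles use
#' the linear-interpolation convention (R's default type 7).
#'
#' @param x A `lake_survey` or a samples tibble.
#' @return A tibble with one row per source x analyte: `source`, `analyte`,
#'   `n`, `median`, `p25`, `p75`.
#' @export
summarize_sources <- function(x) {
  samples <- if (inherits(x, "lake_survey")) x$samples else as_tibble(x)
  long <- tidyr::pivot_longer(
    samples,
    cols = c("rn_bq_m3", "ch4_umol_l"),
    names_to = "analyte", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  empty <- setdiff(unique(samples$source), unique(long$source))
  if (length(empty)) {
    warn(paste0("source(s) with no measurements omitted: ",
                paste(empty, collapse = ", ")),
         class = "lakegw_summary_warning")
  }
  long |>
    group_by(.data$source, .data$analyte) |>
    summarise(
      n = dplyr::n(),
      median = quantile(.data$value, 0.5, type = 7, names = FALSE),
      p25 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      p75 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}
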