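#' Write pipeline products to a results directory
#'
#' Tables are written as UTF-8 CSV with "." decimal and deterministic file
#' names derived from the element names of `results`; run metadata (seed,
#' config hash, package version) goes to a JSON sidecar. Writing the same
#' inputs twice produces byte-identical tables.
#'
#' @param results A named list of data frames (possibly empty), or a single
#'   data frame (written as `result.csv`).
#' @param out_dir Output directory; created if needed.
#' @param seed Optional integer recorded in the metadata sidecar.
#' @param config_path Optional path whose MD5 hash is recorded.
#' @return A tibble manifest: `file`, `rows`, `kind`.
#' @export
write_results <- function(results, out_dir, seed = NULL, config_path = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir),
          class = "lakegw_io_error")
  }
  if (is.data.frame(results)) results <- list(result = results)
  if (is.null(names(results)) && length(results)) {
    names(results) <- paste0("result_", seq_along(results))
  }
  manifest <- purrr::imap(results, function(tbl, nm) {
    stopifnot(is.data.frame(tbl))
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, f, progress = FALSE)
    tibble(file = basename(f), rows = nrow(tbl), kind = "table")
  }) |> bind_rows()
  if (!nrow(manifest)) manifest <- tibble(file = character(), rows = integer(),
                                          kind = character())
  meta <- list(
    package = "lakegw",
    version = as.character(utils::packageVersion("lakegw")),
    seed = seed,
    config_md5 = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else NULL,
    files = manifest$file
  )
  meta_path <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  bind_rows(manifest, tibble(file = "run_meta.json", rows = NA_integer_,
                             kind = "metadata"))
}

#' Write a survey bundle to a directory loadable by [load_survey()]
#'
#' Emits `samples.csv`, `wind.csv`, `flows.csv`, `geometry.csv` and
#' `config.yml`. The written bundle round-trips: loading it back reproduces
#' all numeric fields exactly (CSV doubles use the shortest representation
#' that parses back to the identical binary value).
#'
#' @param survey A [lake_survey()].
#' @param dir Target directory.
#' @return The path to the written `config.yml`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "lake_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- survey$geometry
  geom_tbl <- tibble(lake_id = g$lake_id, area_m2 = g$area_m2,
                     volume_m3 = g$volume_m3, mean_depth_m = g$mean_depth_m)
  if (length(g$covariates)) geom_tbl <- dplyr::bind_cols(geom_tbl, as_tibble(g$covariates))
  readr::write_csv(geom_tbl, file.path(dir, "geometry.csv"), progress = FALSE)
  readr::write_csv(survey$samples, file.path(dir, "samples.csv"), progress = FALSE)
  wind <- survey$wind
  height <- wind$height_m[1] %||% 10
  readr::write_csv(wind[c("timestamp", "speed_m_s")], file.path(dir, "wind.csv"),
                   progress = FALSE)
  flows_tbl <- tibble(
    lake_id = g$lake_id, season = survey$season,
    q_inlet_m3_d = survey$flows$q_inlet$value,
    q_inlet_sigma = survey$flows$q_inlet$sigma,
    q_outlet_m3_d = survey$flows$q_outlet$value,
    q_outlet_sigma = survey$flows$q_outlet$sigma
  )
  readr::write_csv(flows_tbl, file.path(dir, "flows.csv"), progress = FALSE)
  cfg <- list(
    lake_id = g$lake_id, season = survey$season,
    samples = "samples.csv", wind = "wind.csv", flows = "flows.csv",
    geometry = "geometry.csv", wind_height_m = height,
    f_diff = list(value = survey$f_diff$value, sigma = survey$f_diff$sigma),
    c_ra_lake = list(value = survey$c_ra_lake$value, sigma = survey$c_ra_lake$sigma)
  )
  cfg_path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, cfg_path, precision = 17)
  invisible(cfg_path)
}
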