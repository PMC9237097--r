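#' Run the full groundwater-methane pipeline over a set of surveys
#'
#' End-to-end orchestration: for each survey the radon budget is assembled
#' and solved, the Monte-Carlo endmember resampling converts the groundwater
#' radon flux to inflow and CH4-input distributions, the CH4 budget is
#' built (stream loads, diffusive emission, ebullition scaling), and across
#' lakes the summer emission-vs-inflow regression is fitted. Every applied
#' default is surfaced as a logged message; any stage failure aborts with
#' the stage and lake names.
#'
#' @param surveys A list of [lake_survey()] objects, or a character vector
#'   of YAML config paths for [load_survey()].
#' @param seed Master integer seed (required: outputs are citable).
#' @param n_iter Monte-Carlo ensemble size (default 1000).
#' @param model A [k_model()] (default the wind + lake-area model).
#' @param endmember_mode `"independent"` or `"paired"`.
#' @param diff_fraction Diffusive fraction for ebullition scaling (0.17).
#' @param out_dir Optional directory; when given, all tables are written via
#'   [write_results()] and a manifest is attached.
#' @return An object of class `"gw_pipeline"`: list with `budgets` (tidy
#'   term table), `results` (per-lake summary tibble), `mc` (list of
#'   `gw_mc`), `ch4_components`, `budget_table`, `regression` (summer OLS or
#'   NULL), and `manifest` (or NULL).
#' @export
run_pipeline <- function(surveys, seed, n_iter = 1000, model = k_model(),
                         endmember_mode = c("independent", "paired"),
                         diff_fraction = 0.17, out_dir = NULL) {
  endmember_mode <- match.arg(endmember_mode)
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is required for a citable run.", class = "lakegw_validation_error")
  }
  if (n_iter < 1) abort("`n_iter` must be >= 1.", class = "lakegw_validation_error")
  if (is.character(surveys)) surveys <- lapply(surveys, load_survey)
  stopifnot(length(surveys) >= 1,
            all(vapply(surveys, inherits, logical(1), "lake_survey")))

  stage <- function(what, lake, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for lake %s: %s", what, lake,
                    conditionMessage(e)),
            class = "lakegw_stage_error", parent = e)
    })
  }

  budgets <- list(); mcs <- list(); comps <- list()
  for (sv in surveys) {
    id <- sv$geometry$lake_id
    key <- paste(id, sv$season)
    b <- stage("rn_budget", id, rn_budget(sv, model = model))
    mc <- stage("monte_carlo", id, run_mc(
      b, sv$endmembers, sv$geometry$area_m2,
      n_iter = n_iter, seed = seed, mode = endmember_mode
    ))
    if (b$truncated) {
      inform(sprintf("lake %s (%s): no detectable groundwater (F_gw clamped to 0).",
                     id, sv$season), class = "lakegw_flag")
    }
    de <- stage("ch4_budget", id, diffusive_emission(sv, model = model))
    eb <- scale_ebullition(de$emission, diff_fraction)
    inlet_ch4 <- sv$samples$ch4_umol_l[sv$samples$source == "inlet"]
    outlet_ch4 <- sv$samples$ch4_umol_l[sv$samples$source == "outlet"]
    s <- mc$summary
    comps[[key]] <- tibble(
      lake_id = id, season = sv$season,
      gw_input = s$median[s$quantity == "ch4_mg_m2_d"],
      gw_p25 = s$p25[s$quantity == "ch4_mg_m2_d"],
      gw_p75 = s$p75[s$quantity == "ch4_mg_m2_d"],
      inlet_input = stream_ch4_flux(sv$flows$q_inlet$value,
                                    mean(inlet_ch4, na.rm = TRUE) %|NA|% 0,
                                    sv$geometry$area_m2),
      outlet_export = stream_ch4_flux(sv$flows$q_outlet$value,
                                      mean(outlet_ch4, na.rm = TRUE) %|NA|% 0,
                                      sv$geometry$area_m2),
      diffusive_emission = de$emission,
      ebullition_estimate = eb$ebullition,
      total_emission = eb$total,
      q_gw_median = s$median[s$quantity == "q_gw_cm_d"],
      q_gw_p25 = s$p25[s$quantity == "q_gw_cm_d"],
      q_gw_p75 = s$p75[s$quantity == "q_gw_cm_d"],
      truncated = b$truncated,
      tau_d = b$tau_d, k_rn = b$k_rn, steady_state_ok = b$steady_state$ok
    )
    budgets[[key]] <- dplyr::mutate(b$terms, lake_id = id, season = sv$season,
                                    .before = 1)
    mcs[[key]] <- mc
  }
  components <- bind_rows(comps)
  budget_table <- build_budget_table(components)
  summer <- dplyr::filter(components, .data$season == "summer")
  regression <- if (nrow(summer) >= 3 && sd(summer$q_gw_median) > 0) {
    emission_inflow_regression(tibble(q_gw = summer$q_gw_median,
                                      total_emission = summer$total_emission))
  } else NULL

  out <- structure(list(
    budgets = bind_rows(budgets), results = components, mc = mcs,
    ch4_components = components, budget_table = budget_table,
    regression = regression, seed = seed, n_iter = n_iter,
    manifest = NULL
  ), class = "gw_pipeline")

  if (!is.null(out_dir)) {
    tables <- list(
      budget_terms = out$budgets,
      lake_results = components,
      ch4_budget = budget_table
    )
    if (!is.null(regression)) {
      tables$emission_regression <- dplyr::mutate(
        regression$coefficients,
        r2 = regression$r2, f_stat = regression$f_stat,
        df = regression$df, p_value = regression$p_value
      )
    }
    out$manifest <- write_results(tables, out_dir, seed = seed)
  }
  out
}

# NA-coalescing helper for optional stream concentrations
`%|NA|%` <- function(x, y) if (length(x) != 1 || is.na(x)) y else x

#' @export
print.gw_pipeline <- function(x, ...) {
  cat("<gw_pipeline>", nrow(x$results), "lake-season(s); n_iter =", x$n_iter,
      "; seed =", x$seed, "\n")
  print(select(x$results, dplyr::all_of(c(
    "lake_id", "season", "q_gw_median", "gw_input", "total_emission", "truncated"
  ))))
  invisible(x)
}
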