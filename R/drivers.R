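#' Screen predictors for multicollinearity with Spearman correlation
#'
#' All predictor pairs are tested for rank correlation; within each pair
#' whose correlation is significant at `alpha`, the later-listed predictor
#' is dropped. p-values use the exact null distribution for n < 10 and the
#' t approximation otherwise. Constant predictors (undefined rho) are
#' flagged and dropped.
#'
#' @param X Data frame of numeric predictors (>= 4 observations).
#' @param alpha Significance level for the collinearity call (default 0.05).
#' @return A list: `retained` (character), `dropped` (character), `report`
#'   (tibble of all pairs: `var1`, `var2`, `rho`, `p_value`, `collinear`).
#' @export
spearman_filter <- function(X, alpha = 0.05) {
  X <- as_tibble(X)
  stopifnot(all(vapply(X, is.numeric, logical(1))))
  if (nrow(X) < 4) abort("need >= 4 observations.", class = "lakegw_validation_error")
  vars <- names(X)
  constant <- vars[vapply(X, function(v) sd(v) == 0, logical(1))]
  if (length(constant)) {
    warn(paste0("constant predictor(s) dropped (rho undefined): ",
                paste(constant, collapse = ", ")),
         class = "lakegw_driver_warning")
  }
  vars <- setdiff(vars, constant)
  pairs <- if (length(vars) >= 2) utils::combn(vars, 2, simplify = FALSE) else list()
  report <- purrr::map(pairs, function(p) {
    exact <- nrow(X) < 10
    ct <- suppressWarnings(
      cor.test(X[[p[1]]], X[[p[2]]], method = "spearman", exact = exact)
    )
    tibble(var1 = p[1], var2 = p[2], rho = unname(ct$estimate),
           p_value = ct$p.value, collinear = ct$p.value < alpha)
  }) |> bind_rows()
  dropped <- constant
  retained <- vars
  if (nrow(report)) {
    for (i in seq_len(nrow(report))) {
      if (report$collinear[i] &&
          report$var1[i] %in% retained && report$var2[i] %in% retained) {
        retained <- setdiff(retained, report$var2[i])  # later-listed goes
        dropped <- c(dropped, report$var2[i])
      }
    }
  }
  list(retained = retained, dropped = dropped, report = report)
}

#' Exhaustive all-subsets OLS with AIC ranking
#'
#' Fits every non-empty predictor subset by ordinary least squares and ranks
#' the fits by AIC = n*ln(RSS/n) + 2(k+1) (Gaussian form; k slopes plus
#' intercept, the constant part of the likelihood omitted consistently so
#' only differences matter). Ties are broken in favour of fewer terms. Named
#' predictors can be log10-transformed first via `transform_spec`. Subsets
#' leaving fewer than two residual degrees of freedom are skipped with a
#' note.
#'
#' @param X Data frame of numeric predictors (p <= 12).
#' @param y Numeric response.
#' @param transform_spec Optional character vector of predictor names to
#'   log10-transform (values must be positive).
#' @return An object of class `"aic_subsets"`: list with `best` (a list:
#'   `terms`, `coefficients` tibble with 95% CIs, `aic`, `adj_r2`, `f_stat`,
#'   `df`, `p_value`), `ranking` (tibble over all fitted subsets), `n`,
#'   `skipped` (count).
#' @export
all_subsets_aic <- function(X, y, transform_spec = NULL) {
  X <- as_tibble(X)
  stopifnot(all(vapply(X, is.numeric, logical(1))), is.numeric(y),
            nrow(X) == length(y))
  p <- ncol(X)
  if (p > 12) abort("exhaustive search limited to p <= 12.",
                    class = "lakegw_validation_error")
  for (v in transform_spec %||% character()) {
    if (!v %in% names(X)) abort(paste0("unknown predictor in transform_spec: ", v),
                                class = "lakegw_validation_error")
    if (any(X[[v]] <= 0)) abort(paste0("log10 transform needs positive values: ", v),
                                class = "lakegw_domain_error")
    X[[v]] <- log10(X[[v]])
    names(X)[names(X) == v] <- paste0("log10_", v)
  }
  n <- length(y)
  vars <- names(X)
  subsets <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(vars, k, simplify = FALSE)
  }), recursive = FALSE)
  skipped <- 0L
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    terms <- subsets[[i]]
    k <- length(terms)
    if (n <= k + 2) { skipped <- skipped + 1L; next }
    dat <- X[terms]
    dat$.y <- y
    fit <- lm(.y ~ ., data = dat)
    rss <- sum(fit$residuals^2)
    aic <- n * log(rss / n) + 2 * (k + 1)
    s <- summary(fit)
    fstat <- s$fstatistic
    rows[[i]] <- tibble(
      terms = paste(terms, collapse = "+"),
      n_terms = k,
      aic = aic,
      adj_r2 = s$adj.r.squared,
      f_stat = if (is.null(fstat)) NA_real_ else unname(fstat["value"]),
      df = n - k - 1L,
      p_value = if (is.null(fstat)) NA_real_ else {
        unname(pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                  lower.tail = FALSE))
      }
    )
    fits[[i]] <- fit
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) abort("no subset had enough residual degrees of freedom.",
                        class = "lakegw_validation_error")
  if (skipped) {
    inform(sprintf("%d subset(s) skipped (n <= k + 2).", skipped),
           class = "lakegw_default_note")
  }
  ranking <- bind_rows(rows[keep]) |>
    arrange(.data$aic, .data$n_terms) |>
    mutate(rank = row_number())
  best_terms <- strsplit(ranking$terms[1], "+", fixed = TRUE)[[1]]
  best_idx <- which(keep)[match(ranking$terms[1],
                                vapply(rows[keep], function(r) r$terms, character(1)))]
  best_fit <- fits[[best_idx]]
  ci <- confint(best_fit)
  best <- list(
    terms = best_terms,
    coefficients = tibble(
      term = rownames(summary(best_fit)$coefficients),
      estimate = unname(coef(best_fit)),
      std_error = unname(summary(best_fit)$coefficients[, "Std. Error"]),
      conf_low = ci[, 1], conf_high = ci[, 2]
    ),
    aic = ranking$aic[1], adj_r2 = ranking$adj_r2[1],
    f_stat = ranking$f_stat[1], df = ranking$df[1],
    p_value = ranking$p_value[1],
    fit = best_fit
  )
  structure(list(best = best, ranking = ranking, n = n, skipped = skipped,
                 X = X, y = y),
            class = "aic_subsets")
}

#' @export
print.aic_subsets <- function(x, ...) {
  cat("<aic_subsets> n =", x$n, "| subsets ranked:", nrow(x$ranking), "\n")
  cat("  best:", paste(x$best$terms, collapse = " + "),
      sprintf("(AIC %.2f, adj R2 %.3f, p %.3g)\n",
              x$best$aic, x$best$adj_r2, x$best$p_value))
  invisible(x)
}

#' Refit a specific predictor subset from an all-subsets search
#'
#' Convenience for interrogating a non-winning subset (for example the known
#' generating model in recovery studies): returns its OLS coefficient table
#' with 95% confidence intervals.
#'
#' @param x An `"aic_subsets"` object.
#' @param terms Character vector of (possibly transformed) predictor names.
#' @return A coefficient tibble (`term`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`).
#' @export
subset_coefficients <- function(x, terms) {
  stopifnot(inherits(x, "aic_subsets"))
  miss <- setdiff(terms, names(x$X))
  if (length(miss)) abort(paste0("unknown term(s): ", paste(miss, collapse = ", ")),
                          class = "lakegw_validation_error")
  dat <- x$X[terms]
  dat$.y <- x$y
  fit <- lm(.y ~ ., data = dat)
  ci <- confint(fit)
  tibble(
    term = rownames(summary(fit)$coefficients),
    estimate = unname(coef(fit)),
    std_error = unname(summary(fit)$coefficients[, "Std. Error"]),
    conf_low = ci[, 1], conf_high = ci[, 2]
  )
}

#' Reference multiple-regression prediction of groundwater inflow
#'
#' Evaluates the reference spatial model for groundwater inflow from lake
#' and catchment characteristics:
#' Q_gw \[cm d^-1\] = 7.3 + 3.5*depth - 5.7*log10(wetzone) - 0.27*log10(slope).
#'
#' @param depth Mean lake depth \[m\].
#' @param wetzone Wet-area catchment cover \[%\], positive.
#' @param slope Catchment slope \[%\], positive.
#' @return Predicted inflow \[cm d^-1\] (may be negative outside the
#'   calibration range; the synthetic generator floors it).
#' @examples
#' reference_mlr_predict(2.9, 10, 10)  # 11.48
#' @export
reference_mlr_predict <- function(depth, wetzone, slope) {
  if (any(wetzone <= 0) || any(slope <= 0)) {
    abort("`wetzone` and `slope` must be positive (log10 arguments).",
          class = "lakegw_domain_error")
  }
  7.3 + 3.5 * depth - 5.7 * log10(wetzone) - 0.27 * log10(slope)
}

REFERENCE_MLR_COEFS <- c(intercept = 7.3, depth = 3.5,
                         log10_wetzone = -5.7, log10_slope = -0.27)
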