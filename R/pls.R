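#' Partial least squares regression by NIPALS with LOO-CV component choice
#'
#' Single-response PLS (PLS1) with the classical NIPALS deflation scheme.
#' Predictors are standardised internally (zero mean, unit variance); the
#' response is centred. The number of retained components is chosen by
#' leave-one-out cross-validation as the count minimising RMSE_CV (ties go
#' to fewer components). With as many components as the predictor rank, PLS
#' predictions coincide with OLS.
#'
#' @param X Data frame or matrix of numeric predictors, no missing values.
#' @param y Numeric response vector.
#' @param max_components Maximum number of components to extract; truncated
#'   with a warning when it exceeds the predictor rank.
#' @return An object of class `"gw_pls"`: list with `n_components`
#'   (CV-selected), `max_components`, `x_weights`, `x_loadings`,
#'   `y_loadings` (per-component), `scores` (n x A), `vip` (named, at the
#'   selected component count), `r2y_cum` (cumulative, non-decreasing),
#'   `rmse_cv` (per component count), `coefficients` (standardised-scale,
#'   per component count), plus centring/scaling constants for prediction.
#' @export
pls_fit <- function(X, y, max_components = NULL) {
  X <- as.matrix(as_tibble(X))
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) abort("missing values not allowed.",
                                  class = "lakegw_validation_error")
  p <- ncol(X)
  rank_x <- qr(scale(X))$rank
  A <- max_components %||% rank_x
  if (A > rank_x) {
    warn(sprintf("max_components truncated from %d to predictor rank %d.",
                 A, rank_x), class = "lakegw_driver_warning")
    A <- rank_x
  }
  core <- nipals_core(X, y, A)
  # leave-one-out RMSE per component count
  n <- nrow(X)
  err <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    ci <- tryCatch(nipals_core(X[-i, , drop = FALSE], y[-i], A),
                   error = function(e) NULL)
    if (is.null(ci)) next
    for (a in seq_len(min(A, ci$A_eff))) {
      err[i, a] <- y[i] - pls_predict_core(ci, X[i, , drop = FALSE], a)
    }
  }
  rmse_cv <- sqrt(colMeans(err^2, na.rm = TRUE))
  n_comp <- which.min(rmse_cv)  # first minimum -> fewest components on ties
  vip <- vip_scores(core, n_comp)
  structure(c(core, list(
    n_components = n_comp, max_components = A,
    rmse_cv = rmse_cv, vip = vip,
    var_names = colnames(X) %||% paste0("x", seq_len(p))
  )), class = "gw_pls")
}

# NIPALS extraction on standardised X, centred y
nipals_core <- function(X, y, A) {
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  if (any(sx == 0)) abort("constant predictor column.", class = "lakegw_validation_error")
  Xs <- scale(X, center = mx, scale = sx)
  my <- mean(y)
  yr <- y - my
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- Xs
  ss_tot <- sum(yr^2)
  r2 <- numeric(A)
  A_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yr)            # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yr * tt) / tt2
    Xd <- Xd - tt %*% t(pp)
    yr <- yr - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
    r2[a] <- 1 - sum(yr^2) / ss_tot
    A_eff <- a
  }
  # standardised-scale regression coefficient vectors per component count
  B <- matrix(0, p, A_eff)
  for (a in seq_len(A_eff)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    qa <- q[seq_len(a)]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), qa)
  }
  list(
    x_weights = W[, seq_len(A_eff), drop = FALSE],
    x_loadings = P[, seq_len(A_eff), drop = FALSE],
    y_loadings = q[seq_len(A_eff)],
    scores = Tm[, seq_len(A_eff), drop = FALSE],
    r2y_cum = r2[seq_len(A_eff)],
    coefficients = B,
    x_center = mx, x_scale = sx, y_center = my,
    A_eff = A_eff
  )
}

pls_predict_core <- function(core, newX, n_comp) {
  n_comp <- min(n_comp, core$A_eff)
  Xs <- scale(newX, center = core$x_center, scale = core$x_scale)
  drop(Xs %*% core$coefficients[, n_comp]) + core$y_center
}

#' Predict from a fitted PLS model
#'
#' @param object A `"gw_pls"` fit.
#' @param newdata Data frame or matrix with the training predictor columns.
#' @param n_components Component count (default: the CV-selected one).
#' @param ... Unused.
#' @return Numeric predictions on the response scale.
#' @export
predict.gw_pls <- function(object, newdata, n_components = NULL, ...) {
  newX <- as.matrix(as_tibble(newdata)[, object$var_names, drop = FALSE])
  pls_predict_core(object, newX, n_components %||% object$n_components)
}

# standard VIP over the first n_comp components (weights are unit-norm)
vip_scores <- function(core, n_comp) {
  W <- core$x_weights[, seq_len(n_comp), drop = FALSE]
  ssa <- core$y_loadings[seq_len(n_comp)]^2 *
    colSums(core$scores[, seq_len(n_comp), drop = FALSE]^2)
  p <- nrow(W)
  v <- sqrt(p * drop(W^2 %*% ssa) / sum(ssa))
  names(v) <- rownames(W)
  v
}

#' Variable importance in projection scores
#'
#' Standard VIP over the retained components of a fitted PLS model. The mean
#' of squared VIP scores over predictors is exactly one.
#'
#' @param pls A `"gw_pls"` object.
#' @param n_components Component count (default: the CV-selected one).
#' @return Named numeric vector of VIP scores, one per predictor.
#' @export
vip <- function(pls, n_components = NULL) {
  stopifnot(inherits(pls, "gw_pls"))
  v <- vip_scores(pls, n_components %||% pls$n_components)
  names(v) <- pls$var_names
  v
}

#' @export
print.gw_pls <- function(x, ...) {
  cat("<gw_pls>", length(x$var_names), "predictors;",
      x$A_eff, "components extracted;", x$n_components, "selected by LOO-CV\n")
  cat("  cumulative R2y:", paste(signif(x$r2y_cum, 3), collapse = ", "), "\n")
  cat("  RMSE_CV:", paste(signif(x$rmse_cv, 3), collapse = ", "), "\n")
  invisible(x)
}
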