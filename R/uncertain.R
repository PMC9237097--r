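#' Quantities with one-sigma uncertainty
#'
#' All terms of the radon budget are carried as a value plus a 1-sigma
#' standard uncertainty in the same unit. `uv()` constructs such a quantity;
#' the arithmetic helpers propagate uncertainty to first order assuming
#' independent inputs (no covariances are modelled anywhere in the budget).
#'
#' @param value Numeric scalar, finite.
#' @param sigma Non-negative numeric scalar, same unit as `value`.
#'
#' @return An object of class `"uv"`: a named list with elements `value`
#'   and `sigma`.
#' @examples
#' uv(110, 12)
#' uv_scale(uv(110, 12), 2)
#' @export
uv <- function(value, sigma = 0) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    abort("`value` must be a single finite number.", class = "lakegw_validation_error")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number.", class = "lakegw_validation_error")
  }
  structure(list(value = as.numeric(value), sigma = as.numeric(sigma)), class = "uv")
}

#' @export
print.uv <- function(x, ...) {
  cat(format(x$value), "±", format(x$sigma), "\n")
  invisible(x)
}

is_uv <- function(x) inherits(x, "uv")

as_uv <- function(x) {
  if (is_uv(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(uv(x, 0))
  if (is.numeric(x) && length(x) == 2L) return(uv(x[[1L]], x[[2L]]))
  abort("Cannot interpret input as an uncertain value.", class = "lakegw_validation_error")
}

#' @rdname uv
#' @param x,y Objects of class `"uv"` (plain numerics are promoted with
#'   `sigma = 0`).
#' @param k A known (exact) numeric multiplier.
#' @export
uv_scale <- function(x, k) {
  x <- as_uv(x)
  uv(x$value * k, abs(k) * x$sigma)
}

#' @rdname uv
#' @export
uv_add <- function(x, y) {
  x <- as_uv(x); y <- as_uv(y)
  uv(x$value + y$value, sqrt(x$sigma^2 + y$sigma^2))
}

#' @rdname uv
#' @export
uv_sub <- function(x, y) {
  x <- as_uv(x); y <- as_uv(y)
  uv(x$value - y$value, sqrt(x$sigma^2 + y$sigma^2))
}

#' @rdname uv
#' @export
uv_mul <- function(x, y) {
  x <- as_uv(x); y <- as_uv(y)
  # first-order: var = (y dX)^2 + (x dY)^2; exact when either sigma is 0
  uv(x$value * y$value, sqrt((y$value * x$sigma)^2 + (x$value * y$sigma)^2))
}

#' Sum a list of independent uncertain values
#'
#' @param xs List of `"uv"` objects (or numerics).
#' @param signs Optional numeric vector of +1/-1 applied per element.
#' @return A `"uv"` with quadrature-combined sigma.
#' @export
uv_sum <- function(xs, signs = NULL) {
  xs <- lapply(xs, as_uv)
  if (is.null(signs)) signs <- rep(1, length(xs))
  stopifnot(length(signs) == length(xs))
  v <- sum(purrr::map2_dbl(xs, signs, ~ .y * .x$value))
  s <- sqrt(sum(purrr::map_dbl(xs, ~ .x$sigma^2)))
  uv(v, s)
}

#' @export
format.uv <- function(x, ...) paste0(format(x$value, ...), " ± ", format(x$sigma, ...))
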