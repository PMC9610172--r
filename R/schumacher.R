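#' Schumacher height-diameter function
#'
#' Predicts total tree height from diameter at breast height using the
#' Schumacher model \deqn{h = 1.3 + e^{\beta_0 + \beta_1 / dbh}}{h = 1.3 +
#' exp(beta0 + beta1/dbh)}, the base curve from which the ADA and GADA
#' projection forms are derived. For an increasing height-diameter curve
#' `beta1` is negative; the asymptotic height as `dbh` grows is
#' `1.3 + exp(beta0)`.
#'
#' @param dbh Diameter at breast height (cm), positive; vectorized.
#' @param beta0 Intercept parameter (dimensionless).
#' @param beta1 Scale parameter of the reciprocal-diameter term (cm).
#' @return Predicted height(s) in m, always > 1.3.
#' @examples
#' schumacher_height(40, beta0 = 3.5, beta1 = -25)
#' @seealso [ada_project()], [gada_project()], [fit_plot_height_model()]
#' @export
schumacher_height <- function(dbh, beta0, beta1) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("`dbh` must be positive and finite", call. = FALSE)
  }
  1.3 + exp(beta0 + beta1 / dbh)
}

#' Schumacher ADA height projection
#'
#' Projects an observed height `H1` at diameter `D1` to the height expected
#' at diameter `D2` along the Schumacher curve through the observed state
#' (algebraic difference approach, one free site-specific parameter):
#' \deqn{H_2 = 1.3 + (H_1 - 1.3)\,\frac{e^{-\beta_1/D_2}}{e^{-\beta_1/D_1}}}
#' The projection is self-referencing (`D2 = D1` returns `H1`) and path
#' invariant (projecting via an intermediate diameter equals projecting
#' directly).
#'
#' @param H1 Observed height (m), > 1.3; vectorized.
#' @param D1,D2 Observed and target diameters (cm), positive.
#' @param beta1 ADA parameter (cm); positive for an increasing curve (the
#'   sign of the base-curve slope is absorbed by the minus in the exponent).
#' @return Projected height(s) at `D2` in m.
#' @examples
#' ada_project(H1 = 15, D1 = 25, D2 = 40, beta1 = 23.02)
#' @export
ada_project <- function(H1, D1, D2, beta1) {
  check_projection_state(H1, D1, D2)
  1.3 + (H1 - 1.3) * exp(-beta1 / D2) / exp(-beta1 / D1)
}

#' Site variable of the Schumacher GADA form
#'
#' Solves the Schumacher GADA curve for its site-specific variable `X0`
#' given an observed state (`H1`, `D1`):
#' \deqn{X_0 = \frac{\ln(H_1 - 1.3) - \beta_0 / D_1}{1 + \beta_1 / D_1}}
#' `X0` indexes the curve of the family passing through the observation;
#' it is invariant along that curve.
#'
#' @inheritParams ada_project
#' @param beta0,beta1 GADA fixed parameters.
#' @return The site variable `X0` (dimensionless).
#' @export
gada_x0 <- function(H1, D1, beta0, beta1) {
  if (any(!is.finite(H1)) || any(H1 <= 1.3)) {
    stop("`H1` must exceed breast height 1.3 m", call. = FALSE)
  }
  if (any(D1 <= 0)) stop("diameters must be positive", call. = FALSE)
  denom <- 1 + beta1 / D1
  if (any(abs(denom) < 1e-12)) {
    stop("singular site variable: 1 + beta1/D1 = 0", call. = FALSE)
  }
  (log(H1 - 1.3) - beta0 / D1) / denom
}

#' Schumacher GADA height projection
#'
#' Projects (`H1`, `D1`) to diameter `D2` along the generalized algebraic
#' difference (GADA) curve family
#' \deqn{H_2 = 1.3 + e^{X_0 + (\beta_0 + \beta_1 X_0)/D_2}}
#' where the site variable `X0` is recovered from the observed state by
#' [gada_x0()]. Both the asymptote and the shape vary with site, unlike the
#' ADA form where only one parameter is site-specific.
#'
#' @inheritParams gada_x0
#' @param D2 Target diameter (cm), positive.
#' @return Projected height(s) at `D2` in m.
#' @examples
#' gada_project(H1 = 15, D1 = 25, D2 = 40, beta0 = 534.60, beta1 = -144.44)
#' @export
gada_project <- function(H1, D1, D2, beta0, beta1) {
  check_projection_state(H1, D1, D2)
  x0 <- gada_x0(H1, D1, beta0, beta1)
  1.3 + exp(x0 + (beta0 + beta1 * x0) / D2)
}

check_projection_state <- function(H1, D1, D2) {
  if (any(!is.finite(H1)) || any(H1 <= 1.3)) {
    stop("`H1` must exceed breast height 1.3 m", call. = FALSE)
  }
  if (any(!is.finite(D1)) || any(!is.finite(D2)) || any(D1 <= 0) || any(D2 <= 0)) {
    stop("diameters must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Goodness-of-fit statistics for a fitted curve
#'
#' Computes the adjusted coefficient of determination, the root mean square
#' error and the relative error in predictions used throughout the package:
#' \deqn{R^2_{adj} = 1 - \frac{(n-1)\sum(y_i-\hat y_i)^2}{(n-p)\sum(y_i-\bar y)^2}}
#' \deqn{RMSE = \sqrt{\frac{\sum(y_i-\hat y_i)^2}{n-p}}}
#' \deqn{RE = 100\, RMSE / \bar y}
#' with `n` observations and `p` fitted parameters.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length as `y`.
#' @param p Number of parameters used to fit the model.
#' @return An object of class `fit_statistics`: a list with elements
#'   `r2_adj`, `rmse`, `re` (percent), `n`, `p` and `residuals`.
#' @examples
#' fit_statistics(c(10, 12, 14, 16), c(11, 11, 15, 15), p = 2)
#' @export
fit_statistics <- function(y, yhat, p) {
  if (length(y) != length(yhat)) {
    stop("`y` and `yhat` must have equal length", call. = FALSE)
  }
  n <- length(y)
  if (n <= p) {
    stop("degrees of freedom exhausted: n <= p", call. = FALSE)
  }
  res <- y - yhat
  sse <- sum(res^2)
  ybar <- mean(y)
  sst <- sum((y - ybar)^2)
  r2_adj <- if (sst == 0) {
    if (sse == 0) 1 else -Inf
  } else {
    1 - ((n - 1) * sse) / ((n - p) * sst)
  }
  rmse <- sqrt(sse / (n - p))
  if (ybar == 0) {
    stop("relative error undefined: mean of `y` is zero", call. = FALSE)
  }
  structure(
    list(r2_adj = r2_adj, rmse = rmse, re = 100 * rmse / ybar,
         n = n, p = p, residuals = res),
    class = "fit_statistics"
  )
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf("Fit statistics (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  adj. R-squared: %.4f\n  RMSE: %.4f\n  RE: %.2f%%\n",
              x$r2_adj, x$rmse, x$re))
  invisible(x)
}
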