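#' Fit a Schumacher difference model to growth pairs
#'
#' Estimates the fixed (marginal) parameters of the ADA or GADA projection
#' form by nonlinear least squares on the observed second heights: the
#' model predicts `H2` from the observed state (`H1`, `D1`) and the target
#' diameter `D2`, so plot- and tree-level heterogeneity is largely absorbed
#' by conditioning on the initial state. ADA has one free parameter
#' (`beta1`; the base-curve intercept cancels in the ratio), GADA two
#' (`beta0`, `beta1`).
#'
#' ADA is a one-dimensional least-squares problem and is solved by a
#' deterministic log-spaced grid scan over `beta1` followed by
#' [stats::optimize()] refinement. GADA is fitted by multi-start
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]); the best converged start by
#' residual sum of squares wins.
#'
#' An optional two-stage refinement (`random_refine = TRUE`, ADA only)
#' re-fits `beta1` per unit for units with at least `min_unit_pairs` pairs
#' and shrinks each unit estimate toward the pooled one with a prior weight
#' of `shrink_weight` pseudo-pairs, giving unit-level curves without a full
#' mixed-model machinery.
#'
#' @param pairs Data frame of growth pairs with columns `D1`, `D2`, `H1`,
#'   `H2` and (for the refinement) `unit_id`, e.g. from [growth_pairs()].
#' @param model `"ADA"` or `"GADA"`.
#' @param weights Optional nonnegative case weights for the least squares.
#' @param random_refine Compute shrunken per-unit `beta1` estimates (ADA).
#' @param min_unit_pairs,shrink_weight Refinement controls.
#' @return An object of class `difference_model_fit`: a list with `model`,
#'   `params` (named vector), `stats` ([fit_statistics] on the `H2`
#'   predictions, `p` = 1 for ADA, 2 for GADA), `n`, `unit`, `criterion`
#'   (metadata copied from `pairs` attributes when present) and, with
#'   refinement, `unit_effects`.
#' @examples
#' d1 <- runif(50, 15, 40); d2 <- d1 + runif(50, 2, 8)
#' h1 <- 1.3 + exp(3.2 - 20 / d1)
#' pairs <- data.frame(D1 = d1, D2 = d2, H1 = h1,
#'                     H2 = ada_project(h1, d1, d2, 20))
#' fit_difference_model(pairs, "ADA")$params
#' @export
fit_difference_model <- function(pairs, model = c("ADA", "GADA"),
                                 weights = NULL, random_refine = FALSE,
                                 min_unit_pairs = 3, shrink_weight = 4) {
  model <- match.arg(model)
  pairs <- as.data.frame(pairs)
  need <- c("D1", "D2", "H1", "H2")
  if (!all(need %in% names(pairs))) {
    stop("pairs need columns D1, D2, H1, H2", call. = FALSE)
  }
  ok <- stats::complete.cases(pairs[need])
  pairs <- pairs[ok, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 growth pairs", call. = FALSE)
  if (any(pairs$H1 <= 1.3) || any(pairs$H2 <= 1.3)) {
    stop("heights must exceed 1.3 m", call. = FALSE)
  }
  if (any(pairs$D2 < pairs$D1)) {
    stop("growth pairs must satisfy D2 >= D1", call. = FALSE)
  }
  if (all(pairs$D2 == pairs$D1)) {
    stop("unidentifiable: all pairs have D2 = D1", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0))
    weights
  }

  if (model == "ADA") {
    params <- fit_ada_beta1(pairs, w)
    yhat <- ada_project(pairs$H1, pairs$D1, pairs$D2, params[["beta1"]])
    p <- 1L
  } else {
    params <- fit_gada_params(pairs, w)
    yhat <- gada_project(pairs$H1, pairs$D1, pairs$D2,
                         params[["beta0"]], params[["beta1"]])
    p <- 2L
  }
  fit <- structure(
    list(model = model, params = params,
         stats = fit_statistics(pairs$H2, yhat, p = p), n = n,
         unit = attr(pairs, "unit"), criterion = attr(pairs, "criterion")),
    class = "difference_model_fit")

  if (random_refine) {
    if (model != "ADA") {
      warning("random_refine is implemented for ADA only; skipped",
              call. = FALSE)
    } else if (!"unit_id" %in% names(pairs)) {
      warning("random_refine needs a unit_id column; skipped", call. = FALSE)
    } else {
      pooled <- params[["beta1"]]
      eff <- lapply(split(pairs, pairs$unit_id), function(sub) {
        if (nrow(sub) < min_unit_pairs || all(sub$D2 == sub$D1)) return(NULL)
        b_u <- fit_ada_beta1(sub, rep(1, nrow(sub)))[["beta1"]]
        data.frame(unit_id = sub$unit_id[1], n = nrow(sub),
                   beta1_unit = b_u,
                   beta1_shrunk = (nrow(sub) * b_u + shrink_weight * pooled) /
                     (nrow(sub) + shrink_weight),
                   stringsAsFactors = FALSE)
      })
      eff <- do.call(rbind, eff[!vapply(eff, is.null, TRUE)])
      rownames(eff) <- NULL
      fit$unit_effects <- eff
    }
  }
  fit
}

# 1-D weighted SSE minimisation for the ADA parameter, deterministic
fit_ada_beta1 <- function(pairs, w) {
  sse <- function(b1) {
    pred <- 1.3 + (pairs$H1 - 1.3) * exp(-b1 / pairs$D2) / exp(-b1 / pairs$D1)
    sum(w * (pairs$H2 - pred)^2)
  }
  grid <- exp(seq(log(0.2), log(800), length.out = 120))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  # widen once if the optimum sits on the scan boundary
  if (i == 1L || i == length(grid)) {
    opt2 <- stats::optimize(sse, lower = grid[1] / 100,
                            upper = grid[length(grid)] * 10, tol = 1e-10)
    if (opt2$objective < opt$objective) opt <- opt2
  }
  c(beta1 = opt$minimum)
}

# multi-start Levenberg-Marquardt for the GADA pair (beta0, beta1)
fit_gada_params <- function(pairs, w) {
  df <- data.frame(H1 = pairs$H1, D1 = pairs$D1, D2 = pairs$D2,
                   H2 = pairs$H2)
  starts <- expand.grid(beta0 = c(50, 150, 350, 600, 900),
                        beta1 = c(-250, -150, -90, -40, 25))
  starts <- rbind(starts, data.frame(beta0 = 3, beta1 = 20))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nlsLM(
        H2 ~ 1.3 + exp(((log(H1 - 1.3) - beta0 / D1) / (1 + beta1 / D1)) +
                         (beta0 + beta1 *
                            ((log(H1 - 1.3) - beta0 / D1) /
                               (1 + beta1 / D1))) / D2),
        data = df, weights = w,
        start = list(beta0 = starts$beta0[j], beta1 = starts$beta1[j]),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL, warning = function(w2) NULL)
    if (is.null(res)) next
    cf <- stats::coef(res)
    if (any(abs(1 + cf[["beta1"]] / df$D1) < 1e-8)) next
    rss <- sum(w * stats::residuals(res)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(rss = rss, coef = cf)
    }
  }
  if (is.null(best)) {
    stop("GADA fit failed to converge from any start; check data spread",
         call. = FALSE)
  }
  c(beta0 = unname(best$coef[["beta0"]]),
    beta1 = unname(best$coef[["beta1"]]))
}

#' @export
print.difference_model_fit <- function(x, ...) {
  lab <- paste0(
    "<difference_model_fit> Schumacher ", x$model,
    if (!is.null(x$unit)) paste0(", unit ", x$unit) else "",
    if (!is.null(x$criterion)) paste0(", ", x$criterion) else "")
  cat(lab, "\n")
  cat("  params:", paste(names(x$params),
                         sprintf("%.4g", x$params), collapse = ", "), "\n")
  cat(sprintf("  n = %d, adj.R2 = %.3f, RMSE = %.3f\n",
              x$n, x$stats$r2_adj, x$stats$rmse))
  invisible(x)
}

#' Fit a plot-specific Schumacher height-diameter model
#'
#' Least-squares fit of the base curve `h = 1.3 + exp(beta0 + beta1/dbh)`
#' to the live, height-measured trees of one plot, all species pooled.
#' Starting values come from the exact linearisation
#' `log(h - 1.3) ~ 1/dbh`; the nonlinear fit is then refined with
#' [stats::nls()] (port) and falls back to Levenberg-Marquardt if needed.
#'
#' @param trees Data frame with columns `dbh`, `h` and optionally `status`
#'   (only `"live"` rows are used); e.g. one inventory of a [plot_series].
#' @param min_trees Minimum number of usable trees (default 4).
#' @return An object of class `plot_hd_fit`: a list with `params`
#'   (`beta0`, `beta1`), `stats` ([fit_statistics], `p = 2`) and `n`.
#' @export
fit_plot_height_model <- function(trees, min_trees = 4) {
  trees <- as.data.frame(trees)
  if (!all(c("dbh", "h") %in% names(trees))) {
    stop("trees need columns dbh, h", call. = FALSE)
  }
  if ("status" %in% names(trees)) trees <- trees[trees$status == "live", ]
  use <- trees[!is.na(trees$dbh) & !is.na(trees$h) & trees$h > 1.3 &
                 trees$dbh > 0, , drop = FALSE]
  if (nrow(use) < min_trees) {
    stop("insufficient data: ", nrow(use), " usable trees (< ", min_trees,
         ")", call. = FALSE)
  }
  if (stats::sd(use$dbh) == 0) {
    stop("unidentifiable: all trees share one dbh", call. = FALSE)
  }
  lin <- stats::lm(log(h - 1.3) ~ I(1 / dbh), data = use)
  start <- list(beta0 = unname(stats::coef(lin)[1]),
                beta1 = unname(stats::coef(lin)[2]))
  fit <- tryCatch(
    stats::nls(h ~ 1.3 + exp(beta0 + beta1 / dbh), data = use,
               start = start, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(h ~ 1.3 + exp(beta0 + beta1 / dbh), data = use,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    stop("height-diameter fit failed to converge", call. = FALSE)
  }
  cf <- stats::coef(fit)
  params <- c(beta0 = unname(cf[["beta0"]]), beta1 = unname(cf[["beta1"]]))
  yhat <- schumacher_height(use$dbh, params[["beta0"]], params[["beta1"]])
  structure(list(params = params,
                 stats = fit_statistics(use$h, yhat, p = 2),
                 n = nrow(use)),
            class = "plot_hd_fit")
}

#' @export
print.plot_hd_fit <- function(x, ...) {
  cat(sprintf(
    "<plot_hd_fit> beta0 = %.4g, beta1 = %.4g (n = %d, adj.R2 = %.3f)\n",
    x$params[["beta0"]], x$params[["beta1"]], x$n, x$stats$r2_adj))
  invisible(x)
}
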