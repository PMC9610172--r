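#' Species-mixture stratum of a plot
#'
#' Assigns conifer proportions to the four mixture levels used in the
#' evaluation: `[0, 0.25]`, `(0.25, 0.5]`, `(0.5, 0.75]`, `(0.75, 1]`
#' (closed upper bounds; the first interval is closed at 0).
#'
#' @param conifer_prop Numeric vector of conifer proportions in `[0, 1]`.
#' @return Factor with levels `"0-0.25"`, `"0.26-0.5"`, `"0.51-0.75"`,
#'   `"0.76-1"`.
#' @export
mixture_stratum <- function(conifer_prop) {
  if (any(conifer_prop < 0 | conifer_prop > 1, na.rm = TRUE)) {
    stop("conifer_prop must lie in [0, 1]", call. = FALSE)
  }
  cut(conifer_prop, breaks = c(-0.001, 0.25, 0.5, 0.75, 1),
      labels = c("0-0.25", "0.26-0.5", "0.51-0.75", "0.76-1"))
}

apply_transform <- function(x, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (transform == "sqrt") {
    if (any(x < 0, na.rm = TRUE)) {
      stop("sqrt transform needs nonnegative response", call. = FALSE)
    }
    sqrt(x)
  } else x
}

join_sf_response <- function(sf, response) {
  sf <- as.data.frame(sf)
  response <- as.data.frame(response)
  stopifnot(all(c("plot_id", "period", "value") %in% names(sf)))
  resp_col <- setdiff(names(response), c("plot_id", "period"))[1]
  merged <- merge(sf, response[, c("plot_id", "period", resp_col)],
                  by = c("plot_id", "period"))
  names(merged)[names(merged) == resp_col] <- "response"
  merged
}

#' Pearson correlation between site form and a response
#'
#' For every (method, model, criterion) site-form variant present in the
#' table, pairs the SF values with a per plot-period response (typically
#' PAI or SDI), applies the transform (default square root), and runs the
#' two-sided Pearson correlation test.
#'
#' @param sf Site-form table from [site_form_table()] (columns `plot_id`,
#'   `period`, `method`, `model`, `criterion`, `value`).
#' @param response Data frame with `plot_id`, `period` and one response
#'   column.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return Data frame with one row per variant: `method`, `model`,
#'   `criterion`, `n`, `r_pearson`, `p_value`.
#' @export
correlate_sf_response <- function(sf, response,
                                  transform = c("sqrt", "none")) {
  merged <- join_sf_response(sf, response)
  merged$response <- apply_transform(merged$response, transform)
  out <- lapply(split(merged, merged[c("method", "model", "criterion")],
                      drop = TRUE), function(sub) {
    if (nrow(sub) < 3) {
      stop("fewer than 3 pairs for variant ",
           paste(sub$method[1], sub$model[1], sub$criterion[1]),
           call. = FALSE)
    }
    if (stats::sd(sub$value) == 0 || stats::sd(sub$response) == 0) {
      stop("undefined correlation: zero variance in variant ",
           paste(sub$method[1], sub$model[1], sub$criterion[1]),
           call. = FALSE)
    }
    ct <- stats::cor.test(sub$value, sub$response, method = "pearson")
    data.frame(method = sub$method[1], model = sub$model[1],
               criterion = sub$criterion[1], n = nrow(sub),
               r_pearson = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$model, res$criterion), ]
}

#' Linear regression of a response on site form
#'
#' Ordinary least squares of the (transformed) response on each SF variant,
#' with the goodness-of-fit statistics computed at `p = 2` parameters, a
#' Shapiro-Wilk normality test on the residuals, and significance flags
#' for both coefficients at `alpha`.
#'
#' @inheritParams correlate_sf_response
#' @param alpha Significance level for the `ns` flags (default 0.05).
#' @return Data frame with one row per variant: `method`, `model`,
#'   `criterion`, `n`, `intercept`, `slope`, `intercept_ns`, `slope_ns`,
#'   `r2_adj`, `rmse`, `shapiro_w`, `shapiro_p`.
#' @export
regress_sf_response <- function(sf, response,
                                transform = c("sqrt", "none"),
                                alpha = 0.05) {
  merged <- join_sf_response(sf, response)
  merged$response <- apply_transform(merged$response, transform)
  out <- lapply(split(merged, merged[c("method", "model", "criterion")],
                      drop = TRUE), function(sub) {
    if (nrow(sub) < 3) {
      stop("fewer than 3 pairs for variant ",
           paste(sub$method[1], sub$model[1], sub$criterion[1]),
           call. = FALSE)
    }
    if (stats::sd(sub$value) == 0) {
      stop("singular design: SF constant in variant ",
           paste(sub$method[1], sub$model[1], sub$criterion[1]),
           call. = FALSE)
    }
    fit <- stats::lm(response ~ value, data = sub)
    cf <- summary(fit)$coefficients
    res <- stats::residuals(fit)
    st <- fit_statistics(sub$response, stats::fitted(fit), p = 2)
    sw <- if (length(res) >= 3 && stats::sd(res) > 0) {
      r <- if (length(res) > 5000) res[seq_len(5000)] else res
      stats::shapiro.test(r)
    } else list(statistic = NA_real_, p.value = NA_real_)
    data.frame(method = sub$method[1], model = sub$model[1],
               criterion = sub$criterion[1], n = nrow(sub),
               intercept = cf[1, 1], slope = cf[2, 1],
               intercept_ns = cf[1, 4] > alpha,
               slope_ns = cf[2, 4] > alpha,
               r2_adj = st$r2_adj, rmse = st$rmse,
               shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$model, res$criterion), ]
}

#' Mixture-stratified SF-response correlations
#'
#' Splits the plot-periods by conifer-proportion stratum (see
#' [mixture_stratum()]) and computes [correlate_sf_response()] within each
#' stratum. Strata with too few pairs (or no plots) yield rows with
#' `available = FALSE` rather than an error.
#'
#' @inheritParams correlate_sf_response
#' @param mixture Data frame with `plot_id`, `period`, `conifer_prop`.
#' @return Data frame with one row per stratum x variant: `stratum`,
#'   `method`, `model`, `criterion`, `n`, `r_pearson`, `p_value`,
#'   `available`.
#' @export
stratified_correlations <- function(sf, response, mixture,
                                    transform = c("sqrt", "none")) {
  mixture <- as.data.frame(mixture)
  stopifnot(all(c("plot_id", "period", "conifer_prop") %in% names(mixture)))
  mixture$stratum <- mixture_stratum(mixture$conifer_prop)
  sf <- merge(as.data.frame(sf),
              mixture[, c("plot_id", "period", "stratum")],
              by = c("plot_id", "period"))
  out <- list()
  for (lev in levels(mixture$stratum)) {
    sub <- sf[!is.na(sf$stratum) & sf$stratum == lev, , drop = FALSE]
    variants <- unique(as.data.frame(sf)[c("method", "model", "criterion")])
    res <- tryCatch(
      correlate_sf_response(sub, response, transform),
      error = function(e) NULL)
    if (is.null(res)) {
      res <- cbind(variants,
                   data.frame(n = 0L, r_pearson = NA_real_,
                              p_value = NA_real_))
      res$available <- FALSE
    } else {
      res$available <- TRUE
    }
    res$stratum <- lev
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  res <- res[, c("stratum", "method", "model", "criterion", "n",
                 "r_pearson", "p_value", "available")]
  rownames(res) <- NULL
  res
}
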