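# project an observed (H, D) state to d_ref under a fitted difference model
project_with_fit <- function(H, D, d_ref, fit) {
  stopifnot(inherits(fit, "difference_model_fit"))
  if (fit$model == "ADA") {
    ada_project(H, D, d_ref, fit$params[["beta1"]])
  } else {
    gada_project(H, D, d_ref, fit$params[["beta0"]], fit$params[["beta1"]])
  }
}

sf_record <- function(plot_id, inventory, method, model, criterion, d_ref,
                      value) {
  data.frame(plot_id = plot_id, inventory = inventory, method = method,
             model = model, criterion = criterion, d_ref = d_ref,
             value = value, stringsAsFactors = FALSE)
}

#' Site form from dominant-tree height-diameter pairs (SF_H-D)
#'
#' Estimates the site form as the mean height of the dominant trees at the
#' reference diameter: each dominant's observed (H, D) pair at the chosen
#' inventory is projected individually to `d_ref` along the fitted ADA or
#' GADA curve through that pair, and the projected heights are averaged.
#' Projecting each tree and then averaging differs from projecting the mean
#' pair (see [site_form_mhmd()]) because the projection is nonlinear in D.
#'
#' @param series A [plot_series].
#' @param inventory Inventory index at which the dominants' states are read.
#' @param fit A [fit_difference_model()] result fitted on dominant-tree
#'   pairs; its `criterion` field selects the dominant definition.
#' @param d_ref Reference diameter (cm); the study uses 40.
#' @param per_ha Dominants per hectare.
#' @return One-row data frame: `plot_id`, `inventory`, `method`, `model`,
#'   `criterion`, `d_ref`, `value` (m).
#' @export
site_form_hd <- function(series, inventory, fit, d_ref = 40, per_ha = 100) {
  stopifnot(inherits(series, "plot_series"),
            inherits(fit, "difference_model_fit"))
  criterion <- fit$criterion %||% "tallest"
  summ <- dominant_summary(select_dominants(series, criterion, per_ha),
                           series)
  pr <- summ$pairs[summ$pairs$inventory == inventory, ]
  if (!nrow(pr)) {
    stop("no dominant observations at inventory ", inventory, call. = FALSE)
  }
  proj <- tryCatch(project_with_fit(pr$H, pr$D, d_ref, fit),
                   error = function(e) {
                     stop("projection failed for plot ", series$plot_id,
                          " (trees ", paste(pr$tree_id, collapse = ","),
                          "): ", conditionMessage(e), call. = FALSE)
                   })
  sf_record(series$plot_id, inventory, "SF_H-D", fit$model, criterion,
            d_ref, mean(proj))
}

#' Site form from plot-mean dominant state (SF_MH-MD)
#'
#' Estimates the site form as the expected mean dominant height at a
#' reference mean diameter: the single plot-level pair (MH, MD) at the
#' chosen inventory is projected to `d_ref` along the fitted curve.
#'
#' @param summary A [dominant_summary()] result.
#' @param inventory Inventory index.
#' @param fit A [fit_difference_model()] result fitted on plot-mean pairs.
#' @inheritParams site_form_hd
#' @return One-row data frame as in [site_form_hd()], `method` `"SF_MH-MD"`.
#' @export
site_form_mhmd <- function(summary, inventory, fit, d_ref = 40) {
  stopifnot(inherits(summary, "dominant_summary"),
            inherits(fit, "difference_model_fit"))
  row <- summary$summary[summary$summary$inventory == inventory, ]
  if (!nrow(row)) {
    stop("no dominant summary at inventory ", inventory, call. = FALSE)
  }
  if (row$MD <= 0 || row$MH <= 1.3) {
    stop("mean dominant state out of domain (MD <= 0 or MH <= 1.3)",
         call. = FALSE)
  }
  value <- project_with_fit(row$MH, row$MD, d_ref, fit)
  sf_record(summary$plot_id, inventory, "SF_MH-MD", fit$model,
            summary$criterion, d_ref, value)
}

#' Site form from the plot height-diameter model (SF_h-dbh)
#'
#' Estimates the site form as the expected tree height at the reference
#' diameter under the plot's own Schumacher height-diameter curve, fitted
#' to all species.
#'
#' @param plot_fit A [fit_plot_height_model()] result.
#' @inheritParams site_form_hd
#' @param plot_id,inventory Labels carried into the output record.
#' @return One-row data frame as in [site_form_hd()], `method`
#'   `"SF_h-dbh"`, `model` `"plot-h-dbh"`, `criterion` `"all"`.
#' @export
site_form_hdbh <- function(plot_fit, d_ref = 40, plot_id = NA_character_,
                           inventory = NA_integer_) {
  stopifnot(inherits(plot_fit, "plot_hd_fit"))
  value <- schumacher_height(d_ref, plot_fit$params[["beta0"]],
                             plot_fit$params[["beta1"]])
  sf_record(plot_id, inventory, "SF_h-dbh", "plot-h-dbh", "all", d_ref,
            value)
}

#' All nine site-form estimates per plot and inventory period
#'
#' For every plot-period (consecutive inventory pair), computes the full
#' set of nine site-form variants at the start inventory of the period:
#' four SF_H-D (ADA/GADA x tallest/thickest dominants), four SF_MH-MD
#' (same grid on the plot-mean state) and one SF_h-dbh from the plot's own
#' height-diameter model. The eight difference models are fitted once on
#' the pooled growth pairs of the whole inventory; the h-dbh model is
#' fitted per plot and period-start inventory.
#'
#' @param inventory A [forest_inventory] with linked remeasurements.
#' @param d_ref Reference diameter (cm).
#' @param per_ha Dominants per hectare.
#' @param fits Optional pre-computed list of difference-model fits as
#'   returned by [fit_all_difference_models()]; fitted internally if `NULL`.
#' @return A data frame with one row per plot-period-variant: `plot_id`,
#'   `period` (start inventory index), `inventory`, `method`, `model`,
#'   `criterion`, `d_ref`, `value`. Attribute `failures` records variants
#'   that could not be computed (with reasons); attribute `fits` carries
#'   the fitted models.
#' @export
site_form_table <- function(inventory, d_ref = 40, per_ha = 100,
                            fits = NULL) {
  stopifnot(inherits(inventory, "forest_inventory"))
  if (is.null(fits)) {
    fits <- fit_all_difference_models(inventory, per_ha = per_ha)
  }
  out <- list()
  failures <- list()
  note_fail <- function(pid, period, variant, msg) {
    failures[[length(failures) + 1L]] <<- data.frame(
      plot_id = pid, period = period, variant = variant, reason = msg,
      stringsAsFactors = FALSE)
  }
  for (pid in inventory$plots$plot_id) {
    series <- plot_series(inventory, pid)
    if (series$n_inventories < 2) next
    summaries <- list()
    for (crit in c("tallest", "thickest")) {
      summaries[[crit]] <- tryCatch(
        dominant_summary(select_dominants(series, crit, per_ha), series),
        error = function(e) NULL)
    }
    for (k in seq_len(series$n_inventories - 1)) {
      for (crit in c("tallest", "thickest")) {
        for (mod in c("ADA", "GADA")) {
          fit_t <- fits$tree[[crit]][[mod]]
          if (is.null(fit_t)) {
            note_fail(pid, k, paste("SF_H-D", mod, crit), "model fit failed")
          } else {
            rec <- tryCatch(
              site_form_hd(series, k, fit_t, d_ref, per_ha),
              error = function(e) conditionMessage(e))
            if (is.character(rec)) {
              note_fail(pid, k, paste("SF_H-D", mod, crit), rec)
            } else {
              rec$period <- k
              out[[length(out) + 1L]] <- rec
            }
          }
          fit_m <- fits$plot_mean[[crit]][[mod]]
          if (is.null(fit_m) || is.null(summaries[[crit]])) {
            note_fail(pid, k, paste("SF_MH-MD", mod, crit),
                      "model fit or dominant set unavailable")
          } else {
            rec <- tryCatch(
              site_form_mhmd(summaries[[crit]], k, fit_m, d_ref),
              error = function(e) conditionMessage(e))
            if (is.character(rec)) {
              note_fail(pid, k, paste("SF_MH-MD", mod, crit), rec)
            } else {
              rec$period <- k
              out[[length(out) + 1L]] <- rec
            }
          }
        }
      }
      rec <- tryCatch({
        pf <- fit_plot_height_model(
          series$trees[series$trees$inventory == k, ])
        site_form_hdbh(pf, d_ref, plot_id = pid, inventory = k)
      }, error = function(e) conditionMessage(e))
      if (is.character(rec)) {
        note_fail(pid, k, "SF_h-dbh", rec)
      } else {
        rec$period <- k
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    sf_record(character(), integer(), character(), character(),
              character(), numeric(), numeric())
  if (nrow(res)) {
    res <- res[, c("plot_id", "period", "inventory", "method", "model",
                   "criterion", "d_ref", "value")]
  }
  rownames(res) <- NULL
  attr(res, "failures") <- if (length(failures)) do.call(rbind, failures)
    else data.frame(plot_id = character(), period = integer(),
                    variant = character(), reason = character(),
                    stringsAsFactors = FALSE)
  attr(res, "fits") <- fits
  res
}

#' Fit the eight pooled difference models of the site-form pipeline
#'
#' Fits Schumacher ADA and GADA on dominant-tree and plot-mean growth
#' pairs under both dominant definitions (2 models x 2 units x 2
#' criteria).
#'
#' @inheritParams site_form_table
#' @return A nested list `fits$<unit>[[criterion]][[model]]` where unit is
#'   `tree` or `plot_mean`; entries are `difference_model_fit` objects or
#'   `NULL` when a fit failed (with a warning).
#' @export
fit_all_difference_models <- function(inventory, per_ha = 100) {
  fits <- list(tree = list(), plot_mean = list())
  for (crit in c("tallest", "thickest")) {
    for (unit in c("tree", "plot-mean")) {
      pairs <- suppressWarnings(
        growth_pairs(inventory, crit, unit, per_ha))
      slot <- if (unit == "tree") "tree" else "plot_mean"
      for (mod in c("ADA", "GADA")) {
        fits[[slot]][[crit]][[mod]] <- tryCatch(
          fit_difference_model(pairs, mod),
          error = function(e) {
            warning(sprintf("%s/%s/%s fit failed: %s", mod, unit, crit,
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
      }
    }
  }
  fits
}

#' Relative-error profile across diameter classes
#'
#' Bins prediction errors into diameter classes centred on a grid and
#' computes the relative error (RE, percent of the class mean response) in
#' each class. The reference diameter is then selected as the smallest
#' grid diameter whose RE is within `plateau_tol` of the minimum RE — an
#' algorithmic encoding of choosing the diameter where the error curve
#' flattens out.
#'
#' @param observed,predicted Observed and predicted heights (m).
#' @param diameter Diameter (cm) of each observation, used for binning.
#' @param grid Candidate reference diameters (cm).
#' @param class_width Width of each diameter class (cm).
#' @param plateau_tol Fractional tolerance above the minimum RE (default
#'   0.05 = 5 percent).
#' @param p Parameter count used in the class-wise RMSE denominator.
#' @return An object of class `ref_diameter_profile`: a data frame with
#'   columns `d`, `n`, `re`, plus attribute `selected` (cm). Classes with
#'   too few observations get `NA` RE and are excluded from selection with
#'   a warning.
#' @export
reference_diameter_profile <- function(observed, predicted, diameter,
                                       grid = seq(10, 60, by = 5),
                                       class_width = 5, plateau_tol = 0.05,
                                       p = 2) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(diameter))
  if (!length(grid)) stop("empty candidate grid", call. = FALSE)
  if (!length(observed)) stop("no observations", call. = FALSE)
  re <- rep(NA_real_, length(grid))
  n <- integer(length(grid))
  for (i in seq_along(grid)) {
    in_class <- abs(diameter - grid[i]) <= class_width / 2
    n[i] <- sum(in_class)
    if (n[i] > p) {
      re[i] <- fit_statistics(observed[in_class], predicted[in_class],
                              p = p)$re
    }
  }
  if (all(is.na(re))) {
    stop("no diameter class has enough observations", call. = FALSE)
  }
  if (any(is.na(re))) {
    warning("class(es) at d = ", paste(grid[is.na(re)], collapse = ", "),
            " have too few observations; excluded from selection",
            call. = FALSE)
  }
  re_min <- min(re, na.rm = TRUE)
  ok <- !is.na(re) & re <= re_min * (1 + plateau_tol) + 1e-12
  selected <- min(grid[ok])
  structure(data.frame(d = grid, n = n, re = re),
            selected = selected, class = c("ref_diameter_profile",
                                           "data.frame"))
}

#' @export
print.ref_diameter_profile <- function(x, ...) {
  cat("<ref_diameter_profile> selected reference diameter:",
      attr(x, "selected"), "cm\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Height-diameter curves by site-form class
#'
#' Partitions plots into equal-width classes of their SF_h-dbh value and
#' fits one pooled Schumacher height-diameter curve per class, giving the
#' family of class curves used to visualise how the height-diameter
#' relationship shifts with site quality. If all plots share one SF value
#' the pooled fit is replicated across classes.
#'
#' @param sf Data frame with columns `plot_id` and `value` (one SF_h-dbh
#'   estimate per plot).
#' @param trees Tree table with columns `plot_id`, `dbh`, `h` (and
#'   optionally `status`).
#' @param n_classes Number of equal-width SF classes.
#' @return Data frame with one row per class: `class`, `lower`, `upper`,
#'   `n_plots`, `n_trees`, `beta0`, `beta1`.
#' @export
sf_class_curves <- function(sf, trees, n_classes = 3) {
  sf <- as.data.frame(sf)
  stopifnot(all(c("plot_id", "value") %in% names(sf)))
  if (nrow(sf) < n_classes) {
    stop("need at least ", n_classes, " plots", call. = FALSE)
  }
  rng <- range(sf$value)
  if (diff(rng) == 0) {
    pooled <- fit_plot_height_model(trees[trees$plot_id %in% sf$plot_id, ])
    out <- data.frame(class = seq_len(n_classes), lower = rng[1],
                      upper = rng[2], n_plots = nrow(sf),
                      n_trees = pooled$n,
                      beta0 = pooled$params[["beta0"]],
                      beta1 = pooled$params[["beta1"]])
    return(out)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_classes + 1)
  cls <- cut(sf$value, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  out <- list()
  for (k in seq_len(n_classes)) {
    pids <- sf$plot_id[cls == k]
    sub <- trees[trees$plot_id %in% pids, , drop = FALSE]
    if ("status" %in% names(sub)) sub <- sub[sub$status == "live", ]
    n_use <- sum(!is.na(sub$dbh) & !is.na(sub$h) & sub$h > 1.3)
    if (n_use < 4) {
      stop("insufficient data in SF class ", k, ": ", n_use, " trees",
           call. = FALSE)
    }
    fit <- fit_plot_height_model(sub)
    out[[k]] <- data.frame(class = k, lower = breaks[k],
                           upper = breaks[k + 1], n_plots = length(pids),
                           n_trees = fit$n,
                           beta0 = fit$params[["beta0"]],
                           beta1 = fit$params[["beta1"]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
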