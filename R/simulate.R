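#' Configuration for the synthetic stand generator
#'
#' Defines the study conditions emulated by [generate_forest()]: 2500 m^2
#' permanent plots, a 7.5 cm diameter censoring threshold, two to three
#' inventories five years apart, right-skewed diameter distributions,
#' plot-level site effects shifting the Schumacher height-diameter curve,
#' conifer proportions spanning the whole mixture range, and diameter
#' growth (hence volume increment) positively coupled to the site effect.
#'
#' @param n_plots Number of plots.
#' @param area_m2 Plot area (m^2).
#' @param n_inventories Number of inventories per plot (>= 2).
#' @param period_years Years between inventories.
#' @param start_year Calendar year of the first inventory.
#' @param trees_per_plot Mean trees per plot (Poisson, truncated at
#'   `min_trees`).
#' @param min_trees Lower truncation of the tree count.
#' @param dbh_shape,dbh_scale Weibull shape (< 2 for right skew) and scale
#'   (cm) of the diameter distribution, left-truncated at `dbh_min`.
#' @param dbh_min Censoring threshold (cm).
#' @param beta0_mean,beta1_true Population Schumacher parameters; the
#'   asymptotic height is `1.3 + exp(beta0_mean + site effect)`.
#' @param site_effect_sd Standard deviation of the plot-level additive
#'   offset on `beta0` (the generator's ground-truth site quality).
#' @param height_noise_sd Measurement/tree-level height noise (m).
#' @param inc_mean Mean diameter increment per period (cm) on an average
#'   site.
#' @param inc_cv Coefficient of variation of the Gamma increment.
#' @param pai_coupling Strength of the site-growth link: the mean
#'   increment is `inc_mean * exp(pai_coupling * site_effect)`; 0 gives
#'   the decoupled (null) configuration.
#' @param conifer_shape1,conifer_shape2 Beta parameters of the per-plot
#'   conifer proportion.
#' @param mortality_rate Per-period probability that a live tree dies
#'   (default 0; dead trees keep their last diameter and lose height
#'   measurement).
#' @param seed Integer seed; every stochastic draw flows from this one
#'   generator state.
#' @return A classed list of settings, validated.
#' @export
synthetic_config <- function(n_plots = 100, area_m2 = 2500,
                             n_inventories = 2, period_years = 5,
                             start_year = 2007, trees_per_plot = 40,
                             min_trees = 8, dbh_shape = 1.3,
                             dbh_scale = 13, dbh_min = 7.5,
                             beta0_mean = 3.3, beta1_true = -22,
                             site_effect_sd = 0.15,
                             height_noise_sd = 1.5, inc_mean = 1.8,
                             inc_cv = 0.5, pai_coupling = 1,
                             conifer_shape1 = 1.1, conifer_shape2 = 1.1,
                             mortality_rate = 0, seed = 1L) {
  cfg <- list(n_plots = n_plots, area_m2 = area_m2,
              n_inventories = n_inventories, period_years = period_years,
              start_year = start_year, trees_per_plot = trees_per_plot,
              min_trees = min_trees, dbh_shape = dbh_shape,
              dbh_scale = dbh_scale, dbh_min = dbh_min,
              beta0_mean = beta0_mean, beta1_true = beta1_true,
              site_effect_sd = site_effect_sd,
              height_noise_sd = height_noise_sd, inc_mean = inc_mean,
              inc_cv = inc_cv, pai_coupling = pai_coupling,
              conifer_shape1 = conifer_shape1,
              conifer_shape2 = conifer_shape2,
              mortality_rate = mortality_rate, seed = as.integer(seed))
  if (cfg$n_inventories < 2) stop("n_inventories must be >= 2", call. = FALSE)
  if (cfg$site_effect_sd < 0 || cfg$height_noise_sd < 0 || cfg$inc_cv < 0) {
    stop("standard deviations must be nonnegative", call. = FALSE)
  }
  if (cfg$mortality_rate < 0 || cfg$mortality_rate >= 1) {
    stop("mortality_rate must be in [0, 1)", call. = FALSE)
  }
  # mass above the censoring threshold must be non-negligible
  tail_mass <- exp(-(cfg$dbh_min / cfg$dbh_scale)^cfg$dbh_shape)
  if (tail_mass < 1e-6) {
    stop("infeasible dbh distribution: almost no mass above ", cfg$dbh_min,
         " cm", call. = FALSE)
  }
  if (cfg$beta1_true >= 0) {
    stop("beta1_true must be negative for an increasing curve", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# species pools; per-plot sampling weights make species richness vary
conifer_pool <- c("PIDU", "PICO", "PIAR", "PITE", "JUDE")
broadleaf_pool <- c("QUSI", "QUDU", "QUCR", "ARXA", "ALAC", "FRUH", "PRSE")

#' Default group-level volume coefficients shipped with the generator
#'
#' Synthetic group-level coefficient sets (one per species group) in the
#' form required by [tree_volume()]; stand volumes from these fall in the
#' range observed in temperate pine-oak inventories.
#'
#' @return A [volume_coefficients] table with the two fallback rows.
#' @export
default_volume_coefficients <- function() {
  volume_coefficients(data.frame(
    species_code = c("conifer", "broadleaf"),
    a0 = c(7.5e-5, 6.0e-5), a1 = c(1.90, 1.92), a2 = c(1.00, 1.02),
    a3 = c(2.0e-5, 4.0e-5), stringsAsFactors = FALSE))
}

# Weibull left-truncated at dbh_min via inverse CDF
rtrunc_weibull <- function(n, shape, scale, lower) {
  p_lo <- stats::pweibull(lower, shape, scale)
  u <- stats::runif(n, p_lo, 1)
  stats::qweibull(u, shape, scale)
}

#' Generate a synthetic multi-inventory forest dataset
#'
#' Simulates linked permanent-plot inventories with known ground truth.
#' Each plot draws a site effect `s ~ N(0, site_effect_sd)` shifting its
#' true Schumacher curve `h = 1.3 + exp(beta0_mean + s + beta1_true/dbh)`;
#' initial diameters come from a left-truncated Weibull; diameter
#' increments per period are Gamma with mean
#' `inc_mean * exp(pai_coupling * s)` (so better sites grow faster and
#' PAI couples positively to the site effect); measured heights follow the
#' plot's true curve plus Gaussian noise. Species are drawn from conifer
#' and broadleaf pools to match a per-plot Beta conifer proportion.
#' Output is deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_forest`: a list with `inventory`
#'   (a [forest_inventory]), `truth` (per-plot `plot_id`, `site_effect`,
#'   `beta0_true`, `beta1_true`, `conifer_prop`, `mean_increment`),
#'   `coefs` (the volume coefficient table) and `config`.
#' @export
generate_forest <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rows <- list()
  truth <- list()
  for (i in seq_len(config$n_plots)) {
    pid <- sprintf("P%03d", i)
    s <- stats::rnorm(1, 0, config$site_effect_sd)
    p_con <- stats::rbeta(1, config$conifer_shape1, config$conifer_shape2)
    n_tr <- max(config$min_trees, stats::rpois(1, config$trees_per_plot))
    is_con <- stats::runif(n_tr) < p_con
    w_con <- stats::rexp(length(conifer_pool))
    w_bl <- stats::rexp(length(broadleaf_pool))
    spp <- character(n_tr)
    if (any(is_con)) {
      spp[is_con] <- sample(conifer_pool, sum(is_con), replace = TRUE,
                            prob = w_con)
    }
    if (any(!is_con)) {
      spp[!is_con] <- sample(broadleaf_pool, sum(!is_con), replace = TRUE,
                             prob = w_bl)
    }
    dbh <- rtrunc_weibull(n_tr, config$dbh_shape, config$dbh_scale,
                          config$dbh_min)
    mean_inc <- config$inc_mean * exp(config$pai_coupling * s)
    shape_g <- 1 / config$inc_cv^2
    alive <- rep(TRUE, n_tr)
    b0 <- config$beta0_mean + s
    for (k in seq_len(config$n_inventories)) {
      if (k > 1) {
        inc <- stats::rgamma(n_tr, shape = shape_g,
                             scale = mean_inc / shape_g)
        dbh <- dbh + ifelse(alive, inc, 0)
        if (config$mortality_rate > 0) {
          dies <- alive & stats::runif(n_tr) < config$mortality_rate
          alive <- alive & !dies
        }
      }
      h_true <- 1.3 + exp(b0 + config$beta1_true / dbh)
      h <- pmax(1.31, h_true + stats::rnorm(n_tr, 0, config$height_noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = pid, tree_id = sprintf("T%04d", seq_len(n_tr)),
        species_code = spp,
        species_group = ifelse(is_con, "conifer", "broadleaf"),
        dbh = dbh, h = ifelse(alive, h, NA_real_),
        status = ifelse(alive, "live", "dead"), inventory = k,
        year = config$start_year + (k - 1) * config$period_years,
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(
      plot_id = pid, site_effect = s, beta0_true = b0,
      beta1_true = config$beta1_true, conifer_prop = mean(is_con),
      mean_increment = mean_inc, stringsAsFactors = FALSE)
  }
  trees <- do.call(rbind, rows)
  inv <- forest_inventory(trees, area_m2 = config$area_m2,
                          period_years = config$period_years)
  structure(list(inventory = inv, truth = do.call(rbind, truth),
                 coefs = default_volume_coefficients(), config = config),
            class = "synthetic_forest")
}

#' @export
print.synthetic_forest <- function(x, ...) {
  cat(sprintf(
    "<synthetic_forest> %d plots, seed %d, coupling %.2f\n",
    x$config$n_plots, x$config$seed, x$config$pai_coupling))
  print(x$inventory)
  invisible(x)
}

#' Recovery of the generator's site signal by the site-form estimates
#'
#' Joins the generator's ground-truth site effects with a site-form table
#' and reports, per SF variant, the Pearson and Spearman correlation
#' between the true site effect and the plot's SF value (averaged over
#' periods when several are present).
#'
#' @param truth Truth table from [generate_forest()] (`plot_id`,
#'   `site_effect`).
#' @param sf A [site_form_table()] result.
#' @return Data frame: `method`, `model`, `criterion`, `n`, `pearson`,
#'   `spearman`.
#' @export
truth_alignment <- function(truth, sf) {
  truth <- as.data.frame(truth)
  sf <- as.data.frame(sf)
  stopifnot(all(c("plot_id", "site_effect") %in% names(truth)))
  if (!all(sf$plot_id %in% truth$plot_id)) {
    stop("site-form table references plot_id(s) absent from truth",
         call. = FALSE)
  }
  out <- lapply(split(sf, sf[c("method", "model", "criterion")],
                      drop = TRUE), function(sub) {
    per_plot <- tapply(sub$value, sub$plot_id, mean)
    s <- truth$site_effect[match(names(per_plot), truth$plot_id)]
    data.frame(method = sub$method[1], model = sub$model[1],
               criterion = sub$criterion[1], n = length(per_plot),
               pearson = stats::cor(s, as.numeric(per_plot)),
               spearman = stats::cor(s, as.numeric(per_plot),
                                     method = "spearman"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$model, res$criterion), ]
}
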