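# a difference-model fit object with known parameters, for projection tests
stub_fit <- function(model, params, criterion = "tallest",
                     unit = "tree") {
  structure(list(model = model, params = params, criterion = criterion,
                 unit = unit,
                 stats = NULL, n = NA_integer_),
            class = "difference_model_fit")
}

test_that("SF_H-D is the mean of per-tree projections and honours identities", {
  fit <- stub_fit("ADA", c(beta1 = 23.02))
  # single dominant at (15 m, 25 cm) projected to 40 cm: the scalar oracle
  one <- rbind(tree_row("A", "t1", 25, 15, 1, 2007),
               tree_row("A", "t1", 28, 16.5, 2, 2012))
  ser <- plot_series(make_inventory(one), "A")
  rec <- site_form_hd(ser, 1, fit, d_ref = 40)
  expect_equal(rec$value, 20.6502, tolerance = 1e-4)
  expect_equal(rec$method, "SF_H-D")

  # dominants already at the reference diameter: SF equals their MH
  at_ref <- rbind(tree_row("A", "t1", 40, 19, 1, 2007),
                  tree_row("A", "t1", 43, 20, 2, 2012),
                  tree_row("A", "t2", 40, 23, 1, 2007),
                  tree_row("A", "t2", 44, 24, 2, 2012))
  ser2 <- plot_series(make_inventory(at_ref), "A")
  expect_equal(site_form_hd(ser2, 1, fit, d_ref = 40)$value, 21)

  # 25-tree plot equals a brute-force loop over independent projections
  trees <- make_curve_plot(n = 30, noise_sd = 0.6, seed = 12)
  ser3 <- plot_series(make_inventory(trees), "P001")
  rec3 <- site_form_hd(ser3, 1, fit, d_ref = 40)
  dom <- select_dominants(ser3, "tallest")
  sub <- trees[trees$inventory == 1 & trees$tree_id %in% dom$tree_ids, ]
  acc <- 0
  for (i in seq_len(nrow(sub))) {
    acc <- acc + ada_project(sub$h[i], sub$dbh[i], 40, 23.02)
  }
  expect_equal(rec3$value, acc / nrow(sub), tolerance = 1e-12)
})

test_that("SF_MH-MD projects the plot-mean state", {
  fit <- stub_fit("ADA", c(beta1 = 43.34), unit = "plot-mean")
  trees <- rbind(tree_row("A", "t1", 20, 16, 1, 2007),
                 tree_row("A", "t1", 23, 17, 2, 2012),
                 tree_row("A", "t2", 30, 20, 1, 2007),
                 tree_row("A", "t2", 33, 21, 2, 2012))
  ser <- plot_series(make_inventory(trees), "A")
  summ <- dominant_summary(select_dominants(ser, "tallest"), ser)
  # MH = 18, MD = 25: frozen oracle 1.3 + 16.7 exp(43.34 (1/25 - 1/40))
  rec <- site_form_mhmd(summ, 1, fit, d_ref = 40)
  expect_equal(rec$value, 33.2915, tolerance = 1e-4)
  # MD = d_ref returns MH unchanged
  rec2 <- site_form_mhmd(summ, 1, fit, d_ref = 25)
  expect_equal(rec2$value, 18)
})

test_that("projecting the mean differs from averaging projections unless dominants are identical", {
  fit <- stub_fit("ADA", c(beta1 = 43.34))
  fitm <- stub_fit("ADA", c(beta1 = 43.34), unit = "plot-mean")
  hetero <- rbind(tree_row("A", "t1", 15, 10, 1, 2007),
                  tree_row("A", "t1", 18, 11, 2, 2012),
                  tree_row("A", "t2", 35, 24, 1, 2007),
                  tree_row("A", "t2", 38, 25, 2, 2012))
  ser <- plot_series(make_inventory(hetero), "A")
  summ <- dominant_summary(select_dominants(ser, "tallest"), ser)
  v_tree <- site_form_hd(ser, 1, fit, d_ref = 40)$value
  v_mean <- site_form_mhmd(summ, 1, fitm, d_ref = 40)$value
  expect_gt(abs(v_tree - v_mean), 0.1)   # Jensen gap on heterogeneous sizes

  homo <- rbind(tree_row("A", "t1", 25, 15, 1, 2007),
                tree_row("A", "t1", 28, 16, 2, 2012),
                tree_row("A", "t2", 25, 15, 1, 2007),
                tree_row("A", "t2", 28, 16, 2, 2012))
  ser2 <- plot_series(make_inventory(homo), "A")
  summ2 <- dominant_summary(select_dominants(ser2, "tallest"), ser2)
  expect_equal(site_form_hd(ser2, 1, fit, d_ref = 40)$value,
               site_form_mhmd(summ2, 1, fitm, d_ref = 40)$value,
               tolerance = 1e-12)
})

test_that("SF_h-dbh evaluates the plot curve at the reference diameter", {
  mk_fit <- function(beta0, beta1) {
    dbh <- seq(8, 55, length.out = 15)
    fit_plot_height_model(
      data.frame(dbh = dbh, h = 1.3 + exp(beta0 + beta1 / dbh)))
  }
  f1 <- mk_fit(3.5, -25)
  expect_equal(site_form_hdbh(f1, d_ref = 40)$value, 19.0244,
               tolerance = 1e-4)
  # monotone in the site-driven intercept
  f_hi <- mk_fit(3.7, -25)
  expect_gt(site_form_hdbh(f_hi, 40)$value, site_form_hdbh(f1, 40)$value)
  # identical parameters give identical SF
  expect_equal(site_form_hdbh(mk_fit(3.5, -25), 40)$value,
               site_form_hdbh(f1, 40)$value)
})

test_that("relative-error profile selects the plateau diameter", {
  # perfect predictions: RE is zero everywhere, smallest grid point wins
  d <- rep(seq(10, 60, by = 5), each = 8)
  obs <- rep(20, length(d))
  prof <- reference_diameter_profile(obs, obs, d)
  expect_true(all(prof$re == 0))
  expect_equal(attr(prof, "selected"), 10)

  # error decreasing with diameter, flat from 40 cm on: selects 40
  grid <- seq(10, 60, by = 5)
  amp <- c(2, 1.7, 1.4, 1.1, 0.9, 0.7, rep(0.5, 5))  # flat from 40
  d <- rep(grid, each = 10)
  err <- rep(amp, each = 10) * rep(c(1, -1), length.out = length(d))
  prof2 <- reference_diameter_profile(20 + err, rep(20, length(d)), d)
  expect_equal(attr(prof2, "selected"), 40)

  # a single candidate class selects itself
  prof3 <- reference_diameter_profile(c(19, 21, 20, 20.5), rep(20, 4),
                                      rep(30, 4), grid = 30)
  expect_equal(attr(prof3, "selected"), 30)

  # empty classes are excluded with a warning
  d4 <- rep(c(10, 15), each = 10)
  expect_warning(
    prof4 <- reference_diameter_profile(rnorm(20, 20), rep(20, 20), d4,
                                        grid = c(10, 15, 60)),
    "too few")
  expect_true(is.na(prof4$re[prof4$d == 60]))
})

test_that("SF-class curves partition plots and preserve the site gradient", {
  # nine plots on a noiseless gradient of the curve intercept
  beta0s <- seq(3.0, 3.6, length.out = 9)
  trees <- list(); sf <- list()
  for (i in seq_along(beta0s)) {
    pid <- sprintf("P%02d", i)
    dbh <- seq(8, 55, length.out = 15)
    trees[[i]] <- data.frame(plot_id = pid, dbh = dbh,
                             h = 1.3 + exp(beta0s[i] - 24 / dbh))
    sf[[i]] <- data.frame(plot_id = pid,
                          value = 1.3 + exp(beta0s[i] - 24 / 40))
  }
  trees <- do.call(rbind, trees); sf <- do.call(rbind, sf)
  curves <- sf_class_curves(sf, trees, n_classes = 3)
  expect_equal(nrow(curves), 3)
  expect_equal(sum(curves$n_plots), 9)
  expect_true(all(curves$n_plots >= 1))
  at_ref <- 1.3 + exp(curves$beta0 + curves$beta1 / 40)
  expect_true(all(diff(at_ref) > 0))   # class curves ordered, no crossing

  # single class equals the pooled fit on the union
  c1 <- sf_class_curves(sf, trees, n_classes = 1)
  pooled <- fit_plot_height_model(trees)
  expect_equal(c1$beta0, pooled$params[["beta0"]])
  expect_equal(c1$beta1, pooled$params[["beta1"]])

  # all plots identical: every class curve identical
  sf_const <- sf; sf_const$value <- 20
  c_const <- sf_class_curves(sf_const, trees, n_classes = 3)
  expect_equal(length(unique(c_const$beta0)), 1)
})

test_that("every complete plot-period yields exactly nine SF records, invariant to labels and order", {
  f <- generate_forest(synthetic_config(n_plots = 12, trees_per_plot = 35,
                                        height_noise_sd = 1, seed = 77))
  sf <- site_form_table(f$inventory)
  counts <- table(paste(sf$plot_id, sf$period))
  expect_true(all(counts == 9))
  expect_equal(nrow(sf), 9 * 12)
  expect_setequal(unique(sf$method), c("SF_H-D", "SF_MH-MD", "SF_h-dbh"))

  # shuffle rows and relabel tree ids: identical SF values under the same
  # fitted models (the estimators themselves are label- and order-free)
  set.seed(3)
  inv <- f$inventory
  fits <- attr(sf, "fits")
  trees2 <- inv$trees
  relabel <- function(id) paste0("X", id)
  trees2$tree_id <- relabel(trees2$tree_id)
  trees2 <- trees2[sample(nrow(trees2)), ]
  inv2 <- forest_inventory(trees2, inv$plots,
                           period_years = inv$period_years)
  sf2 <- site_form_table(inv2, fits = fits)
  key <- function(x) {
    x <- x[x$method %in% c("SF_H-D", "SF_MH-MD"), ]
    x[order(x$plot_id, x$period, x$method, x$model, x$criterion), "value"]
  }
  expect_equal(key(sf2), key(sf), tolerance = 1e-10)
})

test_that("SF_h-dbh tracks the generator's site effect on low-noise stands", {
  f <- generate_forest(synthetic_config(n_plots = 40, trees_per_plot = 40,
                                        height_noise_sd = 2, seed = 5))
  dat <- sf_and_pai(f)
  s <- f$truth$site_effect[match(dat$plot_id, f$truth$plot_id)]
  expect_gte(cor(s, dat$sf, method = "spearman"), 0.8)
})
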