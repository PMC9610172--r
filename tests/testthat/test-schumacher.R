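test_that("base curve evaluates correctly and approaches its asymptote", {
  # frozen scalar oracle: 1.3 + exp(3.5 - 25/40)
  expect_equal(schumacher_height(40, 3.5, -25), 19.0244, tolerance = 1e-4)
  # beta1 = 0: constant 1.3 + exp(beta0) for any dbh
  expect_equal(schumacher_height(c(5, 50, 500), 2, 0),
               rep(1.3 + exp(2), 3))
  # asymptote as dbh grows
  expect_equal(schumacher_height(1e9, 3.5, -25), 1.3 + exp(3.5),
               tolerance = 1e-6)
  expect_error(schumacher_height(0, 3, -20), "positive")
  expect_error(schumacher_height(-5, 3, -20), "positive")
})

test_that("ADA projection matches its scalar oracle and domain checks", {
  # frozen: 1.3 + 13.7 * exp(23.02 * (1/25 - 1/40))
  expect_equal(ada_project(15, 25, 40, 23.02), 20.6502, tolerance = 1e-4)
  expect_equal(ada_project(15, 25, 25, 23.02), 15)        # self-referencing
  expect_error(ada_project(1.2, 25, 40, 23.02), "1.3")
  expect_error(ada_project(15, -1, 40, 23.02), "positive")
})

test_that("GADA projection matches its scalar oracle and its site variable is curve-invariant", {
  h2 <- gada_project(15, 25, 40, 534.60, -144.44)
  expect_equal(h2, 23.6963, tolerance = 1e-3)
  expect_equal(gada_project(15, 25, 25, 534.60, -144.44), 15)
  # X0 recomputed from the projected state equals X0 from the initial state
  x0a <- gada_x0(15, 25, 534.60, -144.44)
  x0b <- gada_x0(h2, 40, 534.60, -144.44)
  expect_equal(x0a, x0b, tolerance = 1e-9)
  # singular site variable at beta1 = -D1
  expect_error(gada_x0(15, 25, 534.60, -25), "singular")
})

test_that("projections are self-referencing and path-invariant over random draws", {
  set.seed(101)
  d <- draw_projection_states(500)
  expect_lt(max(abs(ada_project(d$H1, d$D1, d$D1, d$b1_ada) - d$H1)), 1e-9)
  expect_lt(max(abs(gada_project(d$H1, d$D1, d$D1, d$b0_g, d$b1_g) - d$H1)),
            1e-9)
  two_step_a <- ada_project(ada_project(d$H1, d$D1, d$D2, d$b1_ada),
                            d$D2, d$D3, d$b1_ada)
  expect_lt(max(abs(two_step_a - ada_project(d$H1, d$D1, d$D3, d$b1_ada))),
            1e-9)
  two_step_g <- gada_project(gada_project(d$H1, d$D1, d$D2, d$b0_g, d$b1_g),
                             d$D2, d$D3, d$b0_g, d$b1_g)
  expect_lt(max(abs(two_step_g -
                      gada_project(d$H1, d$D1, d$D3, d$b0_g, d$b1_g))),
            1e-9)
})

test_that("curve families preserve the order of starting heights (no crossing)", {
  d2_grid <- seq(10, 80, by = 2)
  for (h_pair in list(c(10, 12), c(14, 14.01), c(5, 30))) {
    a_lo <- ada_project(h_pair[1], 25, d2_grid, 43.34)
    a_hi <- ada_project(h_pair[2], 25, d2_grid, 43.34)
    expect_true(all(a_hi > a_lo))
    g_lo <- gada_project(h_pair[1], 25, d2_grid, 347.70, -91.35)
    g_hi <- gada_project(h_pair[2], 25, d2_grid, 347.70, -91.35)
    expect_true(all(g_hi > g_lo))
  }
})

test_that("fit statistics match the hand-worked example and a brute-force oracle", {
  st <- fit_statistics(c(10, 12, 14, 16), c(11, 11, 15, 15), p = 2)
  expect_equal(st$rmse, sqrt(2), tolerance = 1e-12)
  expect_equal(st$r2_adj, 0.70, tolerance = 1e-12)
  expect_equal(st$re, 100 * sqrt(2) / 13, tolerance = 1e-12)

  perfect <- fit_statistics(1:10, 1:10, p = 2)
  expect_equal(perfect$r2_adj, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$re, 0)

  # predicting the mean with p = 1 gives adjusted R-squared exactly 0
  y <- c(2, 4, 9, 5)
  expect_equal(fit_statistics(y, rep(mean(y), 4), p = 1)$r2_adj, 0)

  set.seed(33)
  for (rep in 1:10) {
    y <- rnorm(50, 20, 5)
    yhat <- y + rnorm(50)
    p <- sample(1:3, 1)
    bf <- bf_fit_stats(y, yhat, p)
    st <- fit_statistics(y, yhat, p)
    expect_equal(st$r2_adj, bf$r2_adj, tolerance = 1e-12)
    expect_equal(st$rmse, bf$rmse, tolerance = 1e-12)
    expect_equal(st$re, bf$re, tolerance = 1e-12)
  }

  expect_error(fit_statistics(1:3, 1:3, p = 3), "degrees of freedom")
  expect_error(fit_statistics(c(-1, 0, 1), c(-1, 0, 1), p = 1),
               "relative error")
})

test_that("noiseless difference-model fits recover the generating parameters", {
  set.seed(55)
  pairs_a <- sim_ada_pairs(60, beta1 = 23.02, noise_sd = 0)
  fit_a <- fit_difference_model(pairs_a, "ADA")
  expect_equal(fit_a$params[["beta1"]], 23.02, tolerance = 1e-6)
  expect_equal(fit_a$stats$rmse, 0, tolerance = 1e-6)

  pairs_g <- sim_gada_pairs(80, beta0 = 534.60, beta1 = -144.44,
                            noise_sd = 0)
  fit_g <- fit_difference_model(pairs_g, "GADA")
  expect_equal(fit_g$params[["beta0"]], 534.60, tolerance = 1e-4)
  expect_equal(fit_g$params[["beta1"]], -144.44, tolerance = 1e-4)
})

test_that("degenerate growth-pair sets are rejected", {
  d <- data.frame(D1 = c(20, 30), D2 = c(20, 30), H1 = c(10, 15),
                  H2 = c(10, 15))
  expect_error(fit_difference_model(d, "ADA"), "unidentifiable")
  expect_error(fit_difference_model(d[1, ], "ADA"), "at least 2")
  bad <- data.frame(D1 = c(20, 30), D2 = c(25, 28), H1 = c(10, 15),
                    H2 = c(11, 14))
  expect_error(fit_difference_model(bad, "ADA"), "D2 >= D1")
})

test_that("estimation bias of the ADA parameter shrinks with the pair count", {
  set.seed(77)
  truth <- 23.02
  mean_abs_err <- vapply(c(50, 400, 2000), function(n) {
    errs <- vapply(1:6, function(i) {
      fit <- fit_difference_model(sim_ada_pairs(n, truth, 0.86), "ADA")
      abs(fit$params[["beta1"]] - truth)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mean_abs_err[3], mean_abs_err[1])
  expect_lt(mean_abs_err[3], 0.5)   # tight at n = 2000
})

test_that("plot height-diameter model recovers exact curves and flags degenerate designs", {
  dbh <- seq(8, 60, length.out = 20)
  trees <- data.frame(dbh = dbh, h = 1.3 + exp(3.4 - 24 / dbh))
  fit <- fit_plot_height_model(trees)
  expect_equal(fit$params[["beta0"]], 3.4, tolerance = 1e-6)
  expect_equal(fit$params[["beta1"]], -24, tolerance = 1e-5)
  expect_equal(fit$stats$r2_adj, 1, tolerance = 1e-9)

  same_d <- data.frame(dbh = rep(20, 10), h = rnorm(10, 15, 1))
  expect_error(fit_plot_height_model(same_d), "unidentifiable")
  expect_error(fit_plot_height_model(trees[1:3, ]), "insufficient")
})

test_that("per-plot fits on noisy stands land in a moderate explained-variance band", {
  # tree-level height scatter keeps plot-level h-dbh fits well below the
  # precision of dominant-trajectory models
  f <- generate_forest(synthetic_config(n_plots = 25, trees_per_plot = 60,
                                        height_noise_sd = 2.86, seed = 31))
  r2 <- c()
  for (pid in f$inventory$plots$plot_id) {
    ser <- plot_series(f$inventory, pid)
    fit <- tryCatch(
      fit_plot_height_model(ser$trees[ser$trees$inventory == 1, ]),
      error = function(e) NULL)
    if (!is.null(fit)) r2 <- c(r2, fit$stats$r2_adj)
  }
  expect_gt(mean(r2), 0.4)
  expect_lt(mean(r2), 0.8)
})

test_that("two-stage refinement yields shrunken unit-level parameters", {
  set.seed(91)
  pairs <- sim_ada_pairs(120, 23.02, 0.5)
  pairs$unit_id <- rep(sprintf("u%02d", 1:20), each = 6)
  fit <- fit_difference_model(pairs, "ADA", random_refine = TRUE)
  eff <- fit$unit_effects
  expect_equal(nrow(eff), 20)
  pooled <- fit$params[["beta1"]]
  # shrinkage pulls every unit estimate toward the pooled value
  expect_true(all(abs(eff$beta1_shrunk - pooled) <=
                    abs(eff$beta1_unit - pooled) + 1e-9))
})
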