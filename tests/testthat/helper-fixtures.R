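# Small deterministic fixtures and the frozen recovery-simulation designs.

# one tree row
tree_row <- function(plot_id, tree_id, dbh, h, inventory, year,
                     species_code = "PIDU", species_group = "conifer",
                     status = "live") {
  data.frame(plot_id = plot_id, tree_id = tree_id,
             species_code = species_code, species_group = species_group,
             dbh = dbh, h = h, status = status, inventory = inventory,
             year = year, stringsAsFactors = FALSE)
}

# a clean two-inventory plot with n trees on a known Schumacher curve
make_curve_plot <- function(n = 25, plot_id = "P001", beta0 = 3.3,
                            beta1 = -22, dbh = NULL, growth = 3,
                            noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dbh)) dbh <- seq(8, 55, length.out = n)
  n <- length(dbh)
  rows <- list()
  for (k in 1:2) {
    d <- dbh + (k - 1) * growth
    h <- 1.3 + exp(beta0 + beta1 / d)
    if (noise_sd > 0) h <- pmax(1.31, h + rnorm(n, 0, noise_sd))
    rows[[k]] <- tree_row(plot_id, sprintf("T%03d", seq_len(n)), d, h,
                          k, 2007 + (k - 1) * 5)
  }
  do.call(rbind, rows)
}

make_inventory <- function(trees, area_m2 = 2500, period_years = 5) {
  forest_inventory(trees, area_m2 = area_m2, period_years = period_years)
}

# frozen simulation design for ADA parameter recovery
sim_ada_pairs <- function(n, beta1, noise_sd) {
  D1 <- runif(n, 12, 70)
  D2 <- D1 + runif(n, 2, 12)
  H1 <- 1.3 + exp(3.3 + rnorm(n, 0, 0.15) + (-beta1) / D1)
  H2 <- ada_project(H1, D1, D2, beta1) + rnorm(n, 0, noise_sd)
  data.frame(D1 = D1, D2 = D2, H1 = H1, H2 = pmax(H2, 1.35))
}

# frozen simulation design for GADA parameter recovery: states drawn in the
# observable (H, D) space, the site variable implied by the true curve family
sim_gada_pairs <- function(n, beta0, beta1, noise_sd) {
  D1 <- runif(n, 12, 70)
  D2 <- D1 + runif(n, 2, 12)
  H1 <- runif(n, 6, 40)
  H2 <- gada_project(H1, D1, D2, beta0, beta1) + rnorm(n, 0, noise_sd)
  data.frame(D1 = D1, D2 = D2, H1 = H1, H2 = pmax(H2, 1.35))
}

# volume table proportional to diameter: severs the height and diameter-design
# channels between SF and PAI, making the decoupled configuration a true null
null_volume_coefficients <- function() {
  volume_coefficients(data.frame(
    species_code = c("conifer", "broadleaf"),
    a0 = 0.01, a1 = 1, a2 = 0, a3 = 0, stringsAsFactors = FALSE))
}

# SF_h-dbh values and PAI per plot for a generated forest (first period)
sf_and_pai <- function(forest, coefs = forest$coefs, d_ref = 40) {
  inv <- forest$inventory
  out <- list()
  for (pid in inv$plots$plot_id) {
    ser <- plot_series(inv, pid)
    fit <- tryCatch(
      fit_plot_height_model(ser$trees[ser$trees$inventory == 1, ]),
      error = function(e) NULL)
    if (is.null(fit)) next
    out[[length(out) + 1L]] <- data.frame(
      plot_id = pid, sf = site_form_hdbh(fit, d_ref)$value,
      pai = compute_pai(ser, 1, coefs), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# random projection states restricted to the models' domain: the GADA site
# variable is undefined near 1 + beta1/D = 0 and its exponent must stay in
# floating-point range, so draws are filtered to valid, finite states
draw_projection_states <- function(n) {
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- 4 * n
    d <- data.frame(H1 = runif(m, 2, 45), D1 = runif(m, 8, 90),
                    D2 = runif(m, 8, 90), D3 = runif(m, 8, 90),
                    b1_ada = runif(m, 0.5, 300), b0_g = runif(m, 50, 1000),
                    b1_g = -runif(m, 30, 300))
    den_ok <- abs(1 + d$b1_g / d$D1) > 0.15 &
      abs(1 + d$b1_g / d$D2) > 0.15 & abs(1 + d$b1_g / d$D3) > 0.15
    d <- d[den_ok, ]
    h2 <- suppressWarnings(gada_project(d$H1, d$D1, d$D2, d$b0_g, d$b1_g))
    h3 <- suppressWarnings(gada_project(d$H1, d$D1, d$D3, d$b0_g, d$b1_g))
    a2 <- ada_project(d$H1, d$D1, d$D2, d$b1_ada)
    a3 <- ada_project(d$H1, d$D1, d$D3, d$b1_ada)
    in_range <- function(h) is.finite(h) & h > 1.31 & h < 100
    fin <- in_range(h2) & in_range(h3) & in_range(a2) & in_range(a3)
    out <- rbind(out, d[fin, ])
  }
  out[seq_len(n), ]
}
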