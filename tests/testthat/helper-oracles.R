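# Brute-force oracles, written independently of the package implementation
# (explicit loops and textbook formulas) so agreement is a genuine check.

bf_fit_stats <- function(y, yhat, p) {
  n <- length(y)
  sse <- 0
  for (i in seq_len(n)) sse <- sse + (y[i] - yhat[i])^2
  ybar <- sum(y) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (y[i] - ybar)^2
  list(r2_adj = 1 - ((n - 1) * sse) / ((n - p) * sst),
       rmse = sqrt(sse / (n - p)),
       re = sqrt(sse / (n - p)) / ybar * 100)
}

bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

bf_ols <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n; ybar <- sum(y) / n
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  c(intercept = ybar - slope * xbar, slope = slope)
}

bf_dq <- function(dbh) {
  s <- 0
  for (d in dbh) s <- s + d * d
  sqrt(s / length(dbh))
}

bf_sdi <- function(N, Dq) N * exp(1.605 * (log(Dq) - log(25.4)))

bf_ivi <- function(trees) {
  sp <- sort(unique(trees$species_code))
  n_tot <- nrow(trees)
  g_tree <- pi * (trees$dbh / 200)^2
  g_tot <- sum(g_tree)
  occ <- sapply(sp, function(s)
    length(unique(trees$plot_id[trees$species_code == s])))
  data.frame(
    species_code = sp,
    ivi = sapply(sp, function(s) {
      sum(trees$species_code == s) / n_tot
    }) + sapply(sp, function(s) {
      sum(g_tree[trees$species_code == s]) / g_tot
    }) + occ / sum(occ),
    row.names = NULL, stringsAsFactors = FALSE)
}

# PAI by explicit per-tree loop over survivor trees
bf_pai <- function(trees1, trees2, area_m2, period_years, vol_fun) {
  total <- 0
  for (i in seq_len(nrow(trees1))) {
    id <- trees1$tree_id[i]
    j <- which(trees2$tree_id == id)
    if (!length(j)) next
    if (trees1$status[i] != "live" || trees2$status[j] != "live") next
    if (is.na(trees1$h[i]) || is.na(trees2$h[j])) next
    v1 <- vol_fun(trees1$dbh[i], trees1$h[i])
    v2 <- vol_fun(trees2$dbh[j], trees2$h[j])
    total <- total + (v2 - v1) / period_years
  }
  total * 10000 / area_m2
}
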