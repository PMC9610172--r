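#' Volume coefficient table
#'
#' Validates a species-keyed table of volume equation coefficients for
#' [tree_volume()]. Lookup must be total: the table must contain fallback
#' rows keyed by species group (`"conifer"` and `"broadleaf"`) so every
#' tree resolves to a coefficient set even when its species code is absent.
#'
#' @param coefs Data frame with columns `species_code`, `a0`, `a1`, `a2`,
#'   `a3`; `species_code` may also hold the group names used as fallback.
#' @return The validated data frame, classed `volume_coefficients`.
#' @export
volume_coefficients <- function(coefs) {
  coefs <- as.data.frame(coefs)
  need <- c("species_code", "a0", "a1", "a2", "a3")
  if (!all(need %in% names(coefs))) {
    stop("coefficient table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  coefs$species_code <- as.character(coefs$species_code)
  if (anyDuplicated(coefs$species_code)) {
    stop("duplicate species_code in coefficient table", call. = FALSE)
  }
  if (!all(c("conifer", "broadleaf") %in% coefs$species_code)) {
    stop("coefficient table must contain group fallback rows ",
         "'conifer' and 'broadleaf'", call. = FALSE)
  }
  structure(coefs[need], class = c("volume_coefficients", "data.frame"))
}

#' Look up volume coefficients for trees
#'
#' @param coefs A [volume_coefficients] table.
#' @param species_code,species_group Character vectors (recycled to the
#'   longer one); species-level rows win, otherwise the group fallback.
#' @return Data frame of `a0`..`a3`, one row per tree.
#' @export
lookup_volume_coefficients <- function(coefs, species_code, species_group) {
  coefs <- volume_coefficients(coefs)
  n <- max(length(species_code), length(species_group))
  species_code <- rep_len(as.character(species_code), n)
  species_group <- rep_len(as.character(species_group), n)
  i <- match(species_code, coefs$species_code)
  fallback <- match(species_group, coefs$species_code)
  i[is.na(i)] <- fallback[is.na(i)]
  if (anyNA(i)) {
    stop("no coefficients for group(s): ",
         paste(unique(species_group[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  coefs[i, c("a0", "a1", "a2", "a3"), drop = FALSE]
}

#' Individual tree volume
#'
#' Total tree volume (stem plus branches) from the two-term allometric
#' equation \deqn{v = a_0\,dbh^{a_1} h^{a_2} + a_3\,dbh^2} with
#' region-and-species-specific coefficients.
#'
#' @param dbh Diameter at breast height (cm), positive; vectorized.
#' @param h Total height (m), positive; vectorized.
#' @param coef Coefficients: a list/one-row data frame/named vector with
#'   `a0`, `a1`, `a2`, `a3`, or a data frame with one row per tree.
#' @return Volume(s) in cubic metres.
#' @examples
#' tree_volume(40, 20, c(a0 = 8e-5, a1 = 2, a2 = 1, a3 = 0))
#' @export
tree_volume <- function(dbh, h, coef) {
  if (any(dbh <= 0) || any(h <= 0)) {
    stop("`dbh` and `h` must be positive", call. = FALSE)
  }
  cf <- as.data.frame(as.list(coef)[c("a0", "a1", "a2", "a3")])
  v <- cf$a0 * dbh^cf$a1 * h^cf$a2 + cf$a3 * dbh^2
  if (any(v < 0)) {
    stop("negative volume; check coefficient signs", call. = FALSE)
  }
  v
}

#' Reineke's stand density index
#'
#' \deqn{SDI = N\,(D_q / 25.4)^{1.605}} normalises trees per hectare to a
#' quadratic mean diameter of 25.4 cm (10 in) with Reineke's self-thinning
#' exponent.
#'
#' @param N Trees per hectare (>= 0).
#' @param Dq Quadratic mean diameter (cm), positive.
#' @return SDI value(s).
#' @examples
#' compute_sdi(800, 20)
#' @export
compute_sdi <- function(N, Dq) {
  if (any(N < 0)) stop("`N` must be nonnegative", call. = FALSE)
  if (any(Dq <= 0)) stop("`Dq` must be positive", call. = FALSE)
  N * (Dq / 25.4)^1.605
}

#' Stand-level summary of one plot inventory
#'
#' Per-hectare stand attributes from the live trees of a single plot
#' inventory: species count S, stem density N (ha^-1), basal area G
#' (m^2 ha^-1), quadratic mean diameter Dq (cm), stand volume V
#' (m^3 ha^-1, via [tree_volume()]; trees without height are skipped with
#' a count), Reineke SDI and the proportion of coniferous individuals.
#'
#' @param trees Tree table of one plot inventory (columns `species_code`,
#'   `species_group`, `dbh`, `h`, optionally `status`).
#' @param area_m2 Plot area (m^2).
#' @param coefs A [volume_coefficients] table.
#' @return One-row data frame: `S`, `N`, `G`, `Dq`, `V`, `SDI`,
#'   `conifer_prop`, `n_trees`, `n_no_height`.
#' @export
stand_summary <- function(trees, area_m2, coefs) {
  trees <- as.data.frame(trees)
  if ("status" %in% names(trees)) trees <- trees[trees$status == "live", ]
  if (!nrow(trees)) stop("empty plot inventory", call. = FALSE)
  expand <- 10000 / area_m2
  n <- nrow(trees)
  N <- n * expand
  G <- sum(pi * (trees$dbh / 200)^2) * expand
  Dq <- sqrt(sum(trees$dbh^2) / n)
  with_h <- !is.na(trees$h)
  cf <- lookup_volume_coefficients(coefs, trees$species_code[with_h],
                                   trees$species_group[with_h])
  V <- sum(tree_volume(trees$dbh[with_h], trees$h[with_h], cf)) * expand
  data.frame(
    S = length(unique(trees$species_code)), N = N, G = G, Dq = Dq, V = V,
    SDI = compute_sdi(N, Dq),
    conifer_prop = mean(trees$species_group == "conifer"),
    n_trees = n, n_no_height = sum(!with_h))
}

#' Stand metrics for every plot and inventory
#'
#' @param inventory A [forest_inventory].
#' @param coefs A [volume_coefficients] table.
#' @return Data frame with one row per plot-inventory: `plot_id`,
#'   `inventory`, `year` plus the [stand_summary()] columns.
#' @export
stand_summary_table <- function(inventory, coefs) {
  stopifnot(inherits(inventory, "forest_inventory"))
  out <- list()
  for (pid in inventory$plots$plot_id) {
    series <- plot_series(inventory, pid)
    for (k in sort(unique(series$trees$inventory))) {
      sub <- series$trees[series$trees$inventory == k, ]
      row <- stand_summary(sub, series$area_m2, coefs)
      out[[length(out) + 1L]] <- cbind(
        data.frame(plot_id = pid, inventory = k, year = sub$year[1],
                   stringsAsFactors = FALSE), row)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Periodic annual increment of stand volume
#'
#' Volume increment per hectare and year over one remeasurement period:
#' per surviving tree (alive and present at both inventories, so neither
#' mortality nor ingrowth contributes), the volume difference is divided by
#' the period length, expanded to one hectare and summed over the plot.
#'
#' @param series A [plot_series].
#' @param period Index of the period (pair of inventories `period` and
#'   `period + 1`).
#' @param coefs A [volume_coefficients] table.
#' @return PAI in m^3 ha^-1 yr^-1 (scalar). Trees lacking height at either
#'   inventory are skipped.
#' @export
compute_pai <- function(series, period = 1, coefs) {
  stopifnot(inherits(series, "plot_series"))
  if (series$period_years <= 0) {
    stop("period_years must be positive", call. = FALSE)
  }
  if (period + 1 > series$n_inventories) {
    stop("period ", period, " not available", call. = FALSE)
  }
  a <- series$trees[series$trees$inventory == period, ]
  b <- series$trees[series$trees$inventory == period + 1, ]
  common <- intersect(a$tree_id[a$status == "live"],
                      b$tree_id[b$status == "live"])
  a <- a[match(common, a$tree_id), ]
  b <- b[match(common, b$tree_id), ]
  ok <- !is.na(a$h) & !is.na(b$h)
  a <- a[ok, ]; b <- b[ok, ]
  if (!nrow(a)) return(0)
  cf <- lookup_volume_coefficients(coefs, a$species_code, a$species_group)
  v1 <- tree_volume(a$dbh, a$h, cf)
  v2 <- tree_volume(b$dbh, b$h, cf)
  sum((v2 - v1) / series$period_years) * 10000 / series$area_m2
}

#' PAI for every plot and period
#'
#' @inheritParams stand_summary_table
#' @return Data frame: `plot_id`, `period`, `pai`.
#' @export
pai_table <- function(inventory, coefs) {
  stopifnot(inherits(inventory, "forest_inventory"))
  out <- list()
  for (pid in inventory$plots$plot_id) {
    series <- plot_series(inventory, pid)
    if (series$n_inventories < 2) next
    for (k in seq_len(series$n_inventories - 1)) {
      out[[length(out) + 1L]] <- data.frame(
        plot_id = pid, period = k,
        pai = compute_pai(series, k, coefs), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Importance value index per species
#'
#' For a set of plot inventories (one inventory index across plots), sums
#' each species' relative abundance (share of individuals), relative
#' basal area and relative frequency (share of plot occurrences), so the
#' index totals 3 across species (300 percent).
#'
#' @param trees Tree table covering one inventory of several plots
#'   (columns `plot_id`, `species_code`, `dbh`, optionally `status`).
#' @return Data frame sorted by decreasing IVI: `species_code`,
#'   `rel_abundance`, `rel_basal_area`, `rel_frequency`, `ivi`.
#' @export
importance_value_index <- function(trees) {
  trees <- as.data.frame(trees)
  if ("status" %in% names(trees)) trees <- trees[trees$status == "live", ]
  if (!nrow(trees)) stop("empty tree table", call. = FALSE)
  ab <- tapply(rep(1, nrow(trees)), trees$species_code, sum)
  ba <- tapply(pi * (trees$dbh / 200)^2, trees$species_code, sum)
  occ <- tapply(trees$plot_id, trees$species_code,
                function(p) length(unique(p)))
  sp <- names(ab)
  res <- data.frame(
    species_code = sp,
    rel_abundance = as.numeric(ab / sum(ab)),
    rel_basal_area = as.numeric(ba[sp] / sum(ba)),
    rel_frequency = as.numeric(occ[sp] / sum(occ)),
    stringsAsFactors = FALSE)
  res$ivi <- res$rel_abundance + res$rel_basal_area + res$rel_frequency
  res <- res[order(-res$ivi, res$species_code), ]
  rownames(res) <- NULL
  res
}
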