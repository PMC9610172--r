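#' Select the dominant trees of a plot
#'
#' Dominants are the `per_ha` tallest or thickest trees per hectare,
#' regardless of species, restricted to trees that are present, alive and
#' measured in every inventory of the series (so the set is fixed over the
#' study period). Ranking uses the criterion variable at the first
#' inventory, descending; ties are broken by the other size variable
#' (descending) and then by `tree_id`, so selection is stable under input
#' row order.
#'
#' @param series A [plot_series] with at least two inventories.
#' @param criterion `"tallest"` (rank by height) or `"thickest"` (rank by
#'   dbh).
#' @param per_ha Number of dominant trees per hectare (study value 100).
#' @return An object of class `dominant_set`: a list with `plot_id`,
#'   `criterion`, `tree_ids` (ordered by rank), `quota`
#'   (`round(per_ha * area_m2 / 10000)`), and `shortfall` (`TRUE` when
#'   fewer eligible trees exist than the quota).
#' @export
select_dominants <- function(series, criterion = c("tallest", "thickest"),
                             per_ha = 100) {
  stopifnot(inherits(series, "plot_series"))
  criterion <- match.arg(criterion)
  if (per_ha <= 0) stop("`per_ha` must be positive", call. = FALSE)
  if (series$n_inventories < 2) {
    stop("plot ", series$plot_id, ": need >= 2 inventories", call. = FALSE)
  }
  trees <- series$trees
  quota <- round(per_ha * series$area_m2 / 10000)

  n_inv <- series$n_inventories
  by_tree <- split(trees, trees$tree_id)
  eligible <- vapply(by_tree, function(sub) {
    nrow(sub) == n_inv && all(sub$status == "live") &&
      all(!is.na(sub$dbh)) && all(!is.na(sub$h))
  }, TRUE)
  ids <- names(by_tree)[eligible]
  if (!length(ids)) {
    stop("plot ", series$plot_id,
         ": no re-measured live trees eligible as dominants", call. = FALSE)
  }
  first <- trees[trees$inventory == 1 & trees$tree_id %in% ids, ]
  prim <- if (criterion == "tallest") first$h else first$dbh
  seco <- if (criterion == "tallest") first$dbh else first$h
  ord <- order(-prim, -seco, first$tree_id)
  ranked <- first$tree_id[ord]
  n_take <- min(quota, length(ranked))
  structure(
    list(plot_id = series$plot_id, criterion = criterion,
         tree_ids = ranked[seq_len(n_take)], quota = quota,
         shortfall = length(ranked) < quota),
    class = "dominant_set")
}

#' @export
print.dominant_set <- function(x, ...) {
  cat(sprintf("<dominant_set> plot %s, %s: %d/%d trees%s\n",
              x$plot_id, x$criterion, length(x$tree_ids), x$quota,
              if (x$shortfall) " (shortfall)" else ""))
  invisible(x)
}

#' Summarize a dominant set over the inventories of its plot
#'
#' Collects each dominant tree's diameter-height pair (D, H) at every
#' inventory and the per-inventory arithmetic means: the mean dominant
#' diameter MD (cm) and mean dominant height MH (m) used by the
#' plot-mean site-form estimator.
#'
#' @param dominants A [select_dominants()] result.
#' @param series The [plot_series] the set was selected from.
#' @return An object of class `dominant_summary`: a list with `pairs`
#'   (data frame `inventory`, `year`, `tree_id`, `D`, `H`) and `summary`
#'   (data frame `inventory`, `year`, `n`, `MD`, `MH`).
#' @export
dominant_summary <- function(dominants, series) {
  stopifnot(inherits(dominants, "dominant_set"),
            inherits(series, "plot_series"))
  trees <- series$trees[series$trees$tree_id %in% dominants$tree_ids, ]
  missing_h <- unique(trees$tree_id[is.na(trees$h)])
  if (length(missing_h)) {
    stop("dominant tree(s) missing height: ",
         paste(missing_h, collapse = ", "), call. = FALSE)
  }
  pairs <- data.frame(inventory = trees$inventory, year = trees$year,
                      tree_id = trees$tree_id, D = trees$dbh, H = trees$h,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$inventory, pairs$tree_id), ]
  agg <- do.call(rbind, lapply(split(pairs, pairs$inventory), function(sub) {
    data.frame(inventory = sub$inventory[1], year = sub$year[1],
               n = nrow(sub), MD = mean(sub$D), MH = mean(sub$H))
  }))
  rownames(agg) <- NULL
  structure(list(plot_id = dominants$plot_id,
                 criterion = dominants$criterion,
                 pairs = pairs, summary = agg),
            class = "dominant_summary")
}

#' @export
print.dominant_summary <- function(x, ...) {
  cat(sprintf("<dominant_summary> plot %s (%s)\n", x$plot_id, x$criterion))
  print(x$summary)
  invisible(x)
}

#' Build remeasurement growth pairs for difference-model fitting
#'
#' For every plot of the inventory, selects dominants under `criterion` and
#' emits one observation per consecutive inventory pair: per dominant tree
#' (`unit = "tree"`, state variables D and H) or per plot mean
#' (`unit = "plot-mean"`, state variables MD and MH). Pairs from
#' non-consecutive inventories are never formed; pairs whose diameter
#' decreased are dropped (remeasurement noise) and counted in attribute
#' `n_dropped`.
#'
#' @param inventory A [forest_inventory].
#' @param criterion Dominant-tree definition, `"tallest"` or `"thickest"`.
#' @param unit `"tree"` for per-tree pairs or `"plot-mean"` for MD/MH pairs.
#' @param per_ha Dominants per hectare.
#' @return A data frame with columns `unit_id`, `plot_id`, `period`
#'   (index of the first inventory of the pair), `D1`, `D2`, `H1`, `H2`.
#'   Plots without eligible dominants are skipped with a warning.
#' @export
growth_pairs <- function(inventory, criterion = c("tallest", "thickest"),
                         unit = c("tree", "plot-mean"), per_ha = 100) {
  stopifnot(inherits(inventory, "forest_inventory"))
  criterion <- match.arg(criterion)
  unit <- match.arg(unit)
  out <- list()
  n_dropped <- 0L
  for (pid in inventory$plots$plot_id) {
    series <- plot_series(inventory, pid)
    if (series$n_inventories < 2) next
    summ <- tryCatch(
      dominant_summary(select_dominants(series, criterion, per_ha), series),
      error = function(e) {
        warning("plot ", pid, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(summ)) next
    for (k in seq_len(series$n_inventories - 1)) {
      if (unit == "tree") {
        a <- summ$pairs[summ$pairs$inventory == k, ]
        b <- summ$pairs[summ$pairs$inventory == k + 1, ]
        b <- b[match(a$tree_id, b$tree_id), ]
        rows <- data.frame(
          unit_id = paste(pid, a$tree_id, sep = ":"), plot_id = pid,
          period = k, D1 = a$D, D2 = b$D, H1 = a$H, H2 = b$H,
          stringsAsFactors = FALSE)
      } else {
        a <- summ$summary[summ$summary$inventory == k, ]
        b <- summ$summary[summ$summary$inventory == k + 1, ]
        rows <- data.frame(unit_id = pid, plot_id = pid, period = k,
                           D1 = a$MD, D2 = b$MD, H1 = a$MH, H2 = b$MH,
                           stringsAsFactors = FALSE)
      }
      bad <- rows$D2 < rows$D1 | rows$H1 <= 1.3 | rows$H2 <= 1.3
      n_dropped <- n_dropped + sum(bad)
      out[[length(out) + 1L]] <- rows[!bad, , drop = FALSE]
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(unit_id = character(), plot_id = character(),
               period = integer(), D1 = numeric(), D2 = numeric(),
               H1 = numeric(), H2 = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped") <- n_dropped
  attr(pairs, "criterion") <- criterion
  attr(pairs, "unit") <- unit
  pairs
}
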