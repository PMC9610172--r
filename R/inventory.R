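#' Forest inventory container
#'
#' Bundles a tree-level observation table with plot metadata. The tree table
#' holds one row per tree per inventory with the canonical columns
#' `plot_id`, `tree_id`, `species_code`, `species_group` ("conifer" or
#' "broadleaf"), `dbh` (cm), `h` (m, may be `NA`), `status` ("live" or
#' "dead"), `inventory` (1-based index consistent with year order within the
#' plot) and `year`. Plot metadata holds `plot_id` and `area_m2`.
#'
#' @param trees Tree observation data frame with the canonical columns.
#' @param plots Plot metadata data frame (`plot_id`, `area_m2`); if `NULL`,
#'   every plot is assigned `area_m2`.
#' @param area_m2 Default plot area in square metres (study plots: 2500).
#' @param period_years Interval between consecutive inventories (years).
#' @return An object of class `forest_inventory`: a list with elements
#'   `trees`, `plots` and `period_years`.
#' @export
forest_inventory <- function(trees, plots = NULL, area_m2 = 2500,
                             period_years = 5) {
  required <- c("plot_id", "tree_id", "species_code", "species_group",
                "dbh", "h", "status", "inventory", "year")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols)) {
    stop("tree table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trees <- as.data.frame(trees)[required]
  trees$plot_id <- as.character(trees$plot_id)
  trees$tree_id <- as.character(trees$tree_id)
  bad_group <- !trees$species_group %in% c("conifer", "broadleaf")
  if (any(bad_group)) {
    stop("species_group must be 'conifer' or 'broadleaf'", call. = FALSE)
  }
  if (!all(trees$status %in% c("live", "dead"))) {
    stop("status must be 'live' or 'dead'", call. = FALSE)
  }
  key <- paste(trees$plot_id, trees$tree_id, trees$inventory, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- trees[duplicated(key), c("plot_id", "tree_id", "inventory")]
    stop("duplicate (plot, tree, inventory) key(s), e.g. ",
         paste(unlist(dup[1, ]), collapse = "/"), call. = FALSE)
  }
  live_h <- trees$status == "live" & !is.na(trees$h)
  if (any(trees$h[live_h] <= 1.3)) {
    stop("measured heights of live trees must exceed 1.3 m", call. = FALSE)
  }
  if (is.null(plots)) {
    plots <- data.frame(plot_id = unique(trees$plot_id), area_m2 = area_m2,
                        stringsAsFactors = FALSE)
  }
  plots <- as.data.frame(plots)
  if (!all(c("plot_id", "area_m2") %in% names(plots))) {
    stop("plot table needs columns plot_id, area_m2", call. = FALSE)
  }
  plots$plot_id <- as.character(plots$plot_id)
  if (any(plots$area_m2 <= 0)) stop("area_m2 must be positive", call. = FALSE)
  if (!all(trees$plot_id %in% plots$plot_id)) {
    stop("trees reference plot_id(s) absent from the plot table", call. = FALSE)
  }
  # inventory index must follow year order within each plot
  chk <- unique(trees[, c("plot_id", "inventory", "year")])
  for (pid in unique(chk$plot_id)) {
    sub <- chk[chk$plot_id == pid, ]
    sub <- sub[order(sub$inventory), ]
    if (is.unsorted(sub$year, strictly = TRUE) ||
        anyDuplicated(sub$inventory)) {
      stop("inventory index inconsistent with year ordering in plot ", pid,
           call. = FALSE)
    }
  }
  structure(list(trees = trees, plots = plots, period_years = period_years),
            class = "forest_inventory")
}

#' @export
print.forest_inventory <- function(x, ...) {
  cat(sprintf(
    "<forest_inventory> %d plots, %d tree records, %d inventories, period %g yr\n",
    nrow(x$plots), nrow(x$trees), length(unique(x$trees$inventory)),
    x$period_years))
  invisible(x)
}

default_column_mapping <- function() {
  list(plot_id = "plot_id", tree_id = "tree_id", species_code = "species_code",
       species_group = "species_group", dbh = "dbh", h = "h",
       status = "status", year = "year")
}

#' Read a delimited tree table
#'
#' Reads a CSV/TSV inventory export (one row per tree per inventory),
#' applies the minimum-diameter censoring rule (trees below `dbh_min` are
#' excluded from the analysis set but counted), derives the 1-based
#' inventory index from the year ordering within each plot, and links trees
#' across inventories by `tree_id`. Column names in the file are mapped to
#' the canonical names through `mapping`, so arbitrary inventory exports
#' load without code changes.
#'
#' @param path Path to a delimited text file.
#' @param mapping Named list mapping canonical names (`plot_id`, `tree_id`,
#'   `species_code`, `species_group`, `dbh`, `h`, `status`, `year`) to the
#'   file's column names. Defaults to the canonical names themselves.
#' @param sep Field separator; `NULL` picks `\t` for `.tsv` files and `,`
#'   otherwise.
#' @param dbh_min Minimum diameter at breast height (cm) for inclusion;
#'   the study measured all trees with dbh >= 7.5 cm.
#' @inheritParams forest_inventory
#' @return A [forest_inventory] with attributes `excluded` (the censored
#'   rows), `n_input` (rows read) and `linkage` (trees absent from an
#'   intermediate inventory, flagged non-contiguous but retained).
#' @export
read_tree_table <- function(path, mapping = default_column_mapping(),
                            sep = NULL, dbh_min = 7.5, area_m2 = 2500,
                            period_years = 5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  mapping <- utils::modifyList(default_column_mapping(), as.list(mapping))
  missing_cols <- vapply(mapping, function(col) !col %in% names(raw), TRUE)
  if (any(missing_cols)) {
    stop("input is missing mapped column(s): ",
         paste(unlist(mapping[missing_cols]), collapse = ", "), call. = FALSE)
  }
  trees <- data.frame(
    plot_id = as.character(raw[[mapping$plot_id]]),
    tree_id = as.character(raw[[mapping$tree_id]]),
    species_code = as.character(raw[[mapping$species_code]]),
    species_group = as.character(raw[[mapping$species_group]]),
    dbh = as.numeric(raw[[mapping$dbh]]),
    h = as.numeric(raw[[mapping$h]]),
    status = as.character(raw[[mapping$status]]),
    year = as.integer(raw[[mapping$year]]),
    stringsAsFactors = FALSE
  )
  n_input <- nrow(trees)
  keep <- is.na(trees$dbh) | trees$dbh >= dbh_min
  keep[is.na(trees$dbh)] <- FALSE
  excluded <- trees[!keep, , drop = FALSE]
  trees <- trees[keep, , drop = FALSE]
  stopifnot(nrow(trees) + nrow(excluded) == n_input)
  # inventory index from year order within plot
  trees$inventory <- NA_integer_
  for (pid in unique(trees$plot_id)) {
    idx <- trees$plot_id == pid
    yrs <- sort(unique(trees$year[idx]))
    trees$inventory[idx] <- match(trees$year[idx], yrs)
  }
  inv <- forest_inventory(trees, area_m2 = area_m2,
                          period_years = period_years)
  attr(inv, "excluded") <- excluded
  attr(inv, "n_input") <- n_input
  attr(inv, "linkage") <- flag_noncontiguous(inv$trees)
  inv
}

# trees present at two inventories but absent at one in between
flag_noncontiguous <- function(trees) {
  out <- list()
  for (pid in unique(trees$plot_id)) {
    sub <- trees[trees$plot_id == pid, ]
    n_inv <- max(sub$inventory)
    for (tid in unique(sub$tree_id)) {
      pres <- sort(unique(sub$inventory[sub$tree_id == tid]))
      gaps <- setdiff(seq(min(pres), max(pres)), pres)
      if (length(gaps)) {
        out[[length(out) + 1L]] <- data.frame(
          plot_id = pid, tree_id = tid,
          missing_inventory = paste(gaps, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(plot_id = character(), tree_id = character(),
               missing_inventory = character(), stringsAsFactors = FALSE)
}

#' Write a tree table
#'
#' Writes the canonical tree table of a [forest_inventory] as CSV so that
#' [read_tree_table()] round-trips all analysis-relevant fields.
#'
#' @param inventory A [forest_inventory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(inventory, path) {
  stopifnot(inherits(inventory, "forest_inventory"))
  cols <- c("plot_id", "tree_id", "species_code", "species_group",
            "dbh", "h", "status", "year")
  utils::write.csv(inventory$trees[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Extract the measurement series of one plot
#'
#' @param inventory A [forest_inventory].
#' @param plot_id Plot identifier.
#' @return An object of class `plot_series`: a list with `plot_id`,
#'   `area_m2`, `trees` (this plot's rows), `years`, `n_inventories` and
#'   `period_years`. At least two inventories are required for any site-form
#'   or increment computation, but extraction itself allows one.
#' @export
plot_series <- function(inventory, plot_id) {
  stopifnot(inherits(inventory, "forest_inventory"))
  trees <- inventory$trees[inventory$trees$plot_id == plot_id, , drop = FALSE]
  if (!nrow(trees)) stop("unknown plot_id: ", plot_id, call. = FALSE)
  area <- inventory$plots$area_m2[match(plot_id, inventory$plots$plot_id)]
  structure(
    list(plot_id = plot_id, area_m2 = area, trees = trees,
         years = sort(unique(trees$year)),
         n_inventories = max(trees$inventory),
         period_years = inventory$period_years),
    class = "plot_series")
}

#' @export
print.plot_series <- function(x, ...) {
  cat(sprintf("<plot_series> %s: %d records, inventories %s (%g m2)\n",
              x$plot_id, nrow(x$trees),
              paste(x$years, collapse = ", "), x$area_m2))
  invisible(x)
}

#' Validate a forest inventory or plot series
#'
#' Report-only consistency checks across linked inventories: diameter
#' shrinkage beyond a remeasurement tolerance, status reversals (dead then
#' live), and live trees with missing height measurements.
#'
#' @param x A [forest_inventory] or [plot_series].
#' @param shrink_tol Allowed dbh decrease between inventories (cm) before a
#'   shrinkage warning is reported; defaults to 0.5 cm of caliper noise.
#' @return A data frame with columns `plot_id`, `tree_id`, `check`,
#'   `detail`; zero rows for a clean dataset.
#' @export
validate_series <- function(x, shrink_tol = 0.5) {
  trees <- if (inherits(x, "forest_inventory")) x$trees else x$trees
  out <- list()
  note <- function(pid, tid, check, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      plot_id = pid, tree_id = tid, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  sp <- split(trees, paste(trees$plot_id, trees$tree_id, sep = "\r"))
  for (sub in sp) {
    sub <- sub[order(sub$inventory), ]
    pid <- sub$plot_id[1]; tid <- sub$tree_id[1]
    if (nrow(sub) > 1) {
      dd <- diff(sub$dbh)
      if (any(dd < -shrink_tol, na.rm = TRUE)) {
        note(pid, tid, "dbh_shrinkage",
             sprintf("dbh decreased by %.2f cm", -min(dd, na.rm = TRUE)))
      }
      st <- sub$status
      if (any(st[-length(st)] == "dead" & st[-1] == "live")) {
        note(pid, tid, "status_reversal", "dead followed by live")
      }
    }
    if (any(sub$status == "live" & is.na(sub$h))) {
      note(pid, tid, "missing_height",
           paste("inventory", paste(sub$inventory[sub$status == "live" &
                                                    is.na(sub$h)],
                                    collapse = ";")))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(plot_id = character(), tree_id = character(),
               check = character(), detail = character(),
               stringsAsFactors = FALSE)
}
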