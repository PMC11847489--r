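#' Build an occurrence table
#'
#' Standardizes a data frame of presence records to columns `lon`, `lat`,
#' `year`, `basis`. A `date` column (ISO 8601 or bare year) is parsed to a
#' year when `year` is absent; records with a year but no month/day still
#' count as dated.
#'
#' @param df Data frame with at least `lon` and `lat` columns.
#' @return Data frame of class `occurrence_table`.
#' @export
occurrence_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("lon", "lat") %in% names(df))) {
    stop("occurrence table needs 'lon' and 'lat' columns")
  }
  if (!"year" %in% names(df)) {
    df$year <- if ("date" %in% names(df)) parse_year(df$date) else NA_integer_
  }
  df$year <- suppressWarnings(as.integer(df$year))
  if (!"basis" %in% names(df)) df$basis <- NA_character_
  out <- df[, c("lon", "lat", "year", "basis")]
  class(out) <- c("occurrence_table", "data.frame")
  out
}

parse_year <- function(x) {
  x <- as.character(x)
  y <- rep(NA_integer_, length(x))
  has <- !is.na(x) & grepl("^\\s*\\d{4}", x)
  y[has] <- as.integer(substr(trimws(x[has]), 1L, 4L))
  y
}

#' Read occurrence records from CSV
#'
#' Requires `lon` and `lat` headers; `date` (ISO 8601 or year) and `basis`
#' are optional.
#'
#' @param path CSV file path.
#' @return An `occurrence_table`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("cannot read occurrences: no such file: ", path)
  occurrence_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Record-cleaning configuration
#'
#' @param min_year Oldest acceptable collection year (default 1965).
#' @param range_polygons Optional `niche_region`; records outside it are
#'   dropped as out of the species' recognised range.
#' @param land_polygons Optional `niche_region`; records inside it are
#'   dropped (e.g. marine records plotting on land).
#' @param require_date Drop records with no collection year (default TRUE).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(min_year = 1965, range_polygons = NULL,
                            land_polygons = NULL, require_date = TRUE) {
  stopifnot(min_year >= 0)
  structure(list(min_year = min_year, range_polygons = range_polygons,
                 land_polygons = land_polygons, require_date = require_date),
            class = "cleaning_config")
}

#' Apply record-cleaning filters
#'
#' Each record is checked against every filter; a removed record is
#' attributed to the first failing filter in the order: missing
#' coordinates, collection pre-dating `min_year`, missing date, outside the
#' range polygons, on land. Because the filters are independent predicates
#' the retained set does not depend on this order.
#'
#' @param table An `occurrence_table` (or coercible data frame).
#' @param cfg A [cleaning_config()].
#' @return List with `table` (retained records), `report` (named removal
#'   counts plus `retained`), and `provenance` (per-record outcome label).
#' @export
clean_occurrences <- function(table, cfg = cleaning_config()) {
  table <- occurrence_table(table)
  if (nrow(table) == 0L) stop("occurrence table is empty")
  bad_coord <- is.na(table$lon) | is.na(table$lat) |
    abs(table$lon) > 180 | abs(table$lat) > 90
  no_date <- is.na(table$year)
  pre_date <- !no_date & table$year < cfg$min_year
  out_of_range <- rep(FALSE, nrow(table))
  if (!is.null(cfg$range_polygons)) {
    ok <- !bad_coord
    out_of_range[ok] <- !region_contains(cfg$range_polygons,
                                         table$lon[ok], table$lat[ok])
  }
  on_land <- rep(FALSE, nrow(table))
  if (!is.null(cfg$land_polygons)) {
    ok <- !bad_coord
    on_land[ok] <- region_contains(cfg$land_polygons,
                                   table$lon[ok], table$lat[ok])
  }
  if (!cfg$require_date) no_date[] <- FALSE
  outcome <- rep("retained", nrow(table))
  outcome[on_land] <- "on_land"
  outcome[out_of_range] <- "out_of_range"
  outcome[no_date] <- "no_date"
  outcome[pre_date] <- "pre_date"
  outcome[bad_coord] <- "missing_coords"
  kept <- table[outcome == "retained", , drop = FALSE]
  rownames(kept) <- NULL
  report <- c(missing_coords = sum(outcome == "missing_coords"),
              pre_date = sum(outcome == "pre_date"),
              no_date = sum(outcome == "no_date"),
              out_of_range = sum(outcome == "out_of_range"),
              on_land = sum(outcome == "on_land"),
              retained = nrow(kept))
  if (nrow(kept) == 0L) warning("all occurrence records were removed")
  list(table = kept, report = report, provenance = outcome)
}

#' Keep one record per grid cell
#'
#' The earliest-indexed record in each cell is retained. Records falling
#' outside the grid extent cannot collide and pass through unchanged.
#'
#' @param table An `occurrence_table`.
#' @param grid A `niche_grid`.
#' @return The deduplicated `occurrence_table`.
#' @export
deduplicate <- function(table, grid) {
  table <- occurrence_table(table)
  idx <- cell_index(grid, table$lon, table$lat)
  keep <- !duplicated(idx) | is.na(idx)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spatial-thinning configuration
#'
#' @param min_dist_km Minimum pairwise great-circle distance to enforce
#'   (default 5.5 km, one record per 0.05 degree pixel).
#' @param n_attempts Number of seeded randomized thinning runs; the largest
#'   surviving set is kept (default 10).
#' @param seed RNG seed for tie-breaking.
#' @return A list of class `thin_config`.
#' @export
thin_config <- function(min_dist_km = 5.5, n_attempts = 10, seed = 1) {
  stopifnot(min_dist_km > 0, n_attempts >= 1)
  structure(list(min_dist_km = min_dist_km, n_attempts = as.integer(n_attempts),
                 seed = seed),
            class = "thin_config")
}

#' Thin occurrence records to a minimum pairwise distance
#'
#' Retains a maximal set of records whose pairwise great-circle distances
#' (haversine on the authalic sphere) all reach `min_dist_km`. Small
#' tables (up to 20 records in conflict) are solved exactly by
#' branch-and-bound on the conflict graph; larger tables use a seeded
#' heuristic repeated `n_attempts` times (while a violating pair exists,
#' remove the record with the most neighbours within the radius, random
#' tie-break; the largest surviving set wins). Output always satisfies the
#' distance constraint and never gains records; given the seed the result
#' is reproducible.
#'
#' @param table An `occurrence_table`.
#' @param cfg A [thin_config()].
#' @return The thinned `occurrence_table`.
#' @export
thin <- function(table, cfg = thin_config()) {
  table <- occurrence_table(table)
  n <- nrow(table)
  if (n <= 1L) return(table)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(table$lon[i], table$lat[i], table$lon[j], table$lat[j])
  })
  viol <- d < cfg$min_dist_km
  diag(viol) <- FALSE
  keep_idx <- if (n <= 20L) thin_exact(viol) else
    thin_heuristic(viol, cfg$n_attempts, cfg$seed)
  out <- table[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact maximum independent set on the conflict graph (small n): simple
# branch-and-bound, branching on the highest-degree candidate.
thin_exact <- function(viol) {
  n <- nrow(viol)
  nb <- lapply(seq_len(n), function(i) which(viol[i, ]))
  best <- integer(0)
  rec <- function(cand, cur) {
    if (length(cur) + length(cand) <= length(best)) return()
    if (!length(cand)) {
      if (length(cur) > length(best)) best <<- cur
      return()
    }
    degs <- vapply(cand, function(v) sum(nb[[v]] %in% cand), 0L)
    v <- cand[which.max(degs)]
    rec(setdiff(cand, c(v, nb[[v]])), c(cur, v))
    rec(setdiff(cand, v), cur)
  }
  rec(seq_len(n), integer(0))
  sort(best)
}

thin_heuristic <- function(viol, n_attempts, seed) {
  n <- nrow(viol)
  best <- NULL
  with_seed(seed, {
    for (a in seq_len(n_attempts)) {
      keep <- rep(TRUE, n)
      repeat {
        deg <- rep(0L, n)
        deg[keep] <- rowSums(viol[keep, keep, drop = FALSE])
        if (!any(deg > 0)) break
        cand <- which(deg == max(deg))
        drop <- if (length(cand) == 1L) cand else sample(cand, 1L)
        keep[drop] <- FALSE
      }
      if (is.null(best) || sum(keep) > sum(best)) best <- keep
    }
  })
  which(best)
}
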