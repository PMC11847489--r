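#' Maximum training sensitivity plus specificity threshold
#'
#' Scans all unique pooled scores as candidate thresholds under the rule
#' "score >= t is suitable" (sensitivity over presences, specificity =
#' fraction of background below t) and returns the smallest threshold
#' attaining the maximum of sensitivity + specificity.
#'
#' @param presence_scores,background_scores Training suitability scores.
#' @return List of class `threshold_result`: `threshold`, `sensitivity`,
#'   `specificity`, `degenerate` flag.
#' @export
mtss_threshold <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  m <- length(presence_scores); n <- length(background_scores)
  cp <- tabulate(match(presence_scores, cand), nbins = length(cand))
  cb <- tabulate(match(background_scores, cand), nbins = length(cand))
  sens <- rev(cumsum(rev(cp))) / m            # presences >= t
  spec <- c(0, cumsum(cb)[-length(cand)]) / n # background < t
  tot <- sens + spec
  best <- which(tot == max(tot))[1L]
  structure(list(threshold = cand[best], sensitivity = sens[best],
                 specificity = spec[best],
                 degenerate = length(cand) == 1L),
            class = "threshold_result")
}

#' Binarize a suitability raster
#'
#' Cells at or above the threshold are suitable (1); below, unsuitable
#' (0); equality counts as suitable. Nodata is preserved.
#'
#' @param suitability A `niche_layer` of cloglog values.
#' @param threshold Threshold in `[0,1]` (e.g. the MTSS value).
#' @return A `niche_layer` of 0/1 values with a `threshold` attribute.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(inherits(suitability, "niche_layer"),
            threshold >= 0, threshold <= 1)
  v <- ifelse(suitability$values >= threshold, 1, 0)
  out <- raster_layer(suitability$grid, v,
                      name = paste0(suitability$name, "_binary"))
  attr(out, "threshold") <- threshold
  out
}

#' Classify habitat change between two binary maps
#'
#' Codes: 0 never suitable, 1 lost (contraction: currently suitable, not
#' in the future), 2 gained (expansion), 3 maintained (stable).
#'
#' @param current,future Binary `niche_layer`s on the same grid.
#' @return A `niche_layer` of change codes.
#' @export
change_map <- function(current, future) {
  if (!grids_identical(current$grid, future$grid)) {
    stop("current and future maps are on different grids")
  }
  cv <- current$values; fv <- future$values
  code <- ifelse(cv == 1 & fv == 1, 3,
                 ifelse(cv == 1 & fv == 0, 1,
                        ifelse(cv == 0 & fv == 1, 2, 0)))
  raster_layer(current$grid, code, name = "change")
}

#' Habitat change summary from printed or computed areas
#'
#' Applies the two percentage conventions: each category as a share of the
#' CURRENT suitable area (`100 * category / current`), and total change as
#' `100 * (future - current) / current` (negative = net loss).
#'
#' @param current_km2,future_km2 Total suitable areas.
#' @param maintained_km2,gained_km2,lost_km2 Category areas.
#' @return List of class `change_summary`.
#' @export
change_summary_from_areas <- function(current_km2, future_km2,
                                      maintained_km2, gained_km2,
                                      lost_km2) {
  stopifnot(current_km2 > 0)
  structure(list(
    total_current_km2 = current_km2, total_future_km2 = future_km2,
    maintained_km2 = maintained_km2, gained_km2 = gained_km2,
    lost_km2 = lost_km2,
    pct_maintained = 100 * maintained_km2 / current_km2,
    pct_gained = 100 * gained_km2 / current_km2,
    pct_lost = 100 * lost_km2 / current_km2,
    total_change_pct = 100 * (future_km2 - current_km2) / current_km2),
    class = "change_summary")
}

#' Summarize a change map in km^2 and percent
#'
#' @param cm A change map from [change_map()].
#' @param areas A [cell_areas()] layer on the same grid.
#' @return A `change_summary` (see [change_summary_from_areas()]).
#' @export
change_summary <- function(cm, areas) {
  if (!grids_identical(cm$grid, areas$grid)) stop("grid mismatch")
  a <- areas$values
  tot <- function(code) sum(a[!is.na(cm$values) & cm$values == code])
  maintained <- tot(3); lost <- tot(1); gained <- tot(2)
  change_summary_from_areas(maintained + lost, maintained + gained,
                            maintained, gained, lost)
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(paste0("<change_summary> current %.0f km2 -> future %.0f km2 ",
                     "(%+.1f%%): maintained %.0f (%.1f%%), gained %.0f ",
                     "(%.1f%%), lost %.0f (%.1f%%)\n"),
              x$total_current_km2, x$total_future_km2, x$total_change_pct,
              x$maintained_km2, x$pct_maintained, x$gained_km2,
              x$pct_gained, x$lost_km2, x$pct_lost))
  invisible(x)
}

#' Area-weighted centroid of suitable habitat
#'
#' @param binary A binary `niche_layer`.
#' @param areas A [cell_areas()] layer on the same grid.
#' @return Named numeric `c(lon, lat)`.
#' @export
centroid <- function(binary, areas) {
  if (!grids_identical(binary$grid, areas$grid)) stop("grid mismatch")
  cells <- which(!is.na(binary$values) & binary$values == 1)
  if (!length(cells)) stop("no suitable cells; centroid undefined")
  cc <- cell_centers(binary$grid, cells)
  if (diff(range(cc$lon)) > 180) {
    stop("suitable area spans more than 180 degrees of longitude; ",
         "dateline-crossing centroids are not supported")
  }
  w <- areas$values[cells]
  c(lon = sum(w * cc$lon) / sum(w), lat = sum(w * cc$lat) / sum(w))
}

#' Geodesic centroid shift: distance and initial bearing
#'
#' Distance on the WGS84 ellipsoid; initial bearing clockwise from north,
#' normalized to `[0, 360)`. A zero-distance shift reports bearing 0 by
#' convention.
#'
#' @param from,to Numeric `c(lon, lat)` pairs in degrees.
#' @return List of class `centroid_shift`: `from`, `to`, `distance_km`,
#'   `bearing_deg`.
#' @export
shift <- function(from, to) {
  stopifnot(length(from) == 2L, length(to) == 2L)
  d <- geosphere::distGeo(from, to) / 1000
  b <- if (d == 0) 0 else geosphere::bearing(from, to) %% 360
  structure(list(from = from, to = to, distance_km = d, bearing_deg = b),
            class = "centroid_shift")
}

#' @export
print.centroid_shift <- function(x, ...) {
  cat(sprintf("<centroid_shift> %.1f km at %.1f deg\n", x$distance_km,
              x$bearing_deg))
  invisible(x)
}

#' Protected-area overlap summary from areas
#'
#' Percentages follow the convention that both inside and outside shares
#' are relative to the CURRENT total suitable area; the change entries
#' compare the scenario's inside-area against the current inside-area.
#'
#' @param inside_km2,outside_km2 Scenario suitable area inside/outside the
#'   protected-area polygons.
#' @param current_total_km2 Current total suitable area (> 0).
#' @param current_inside_km2 Optional current inside-area for the change
#'   entries.
#' @return List of class `overlap_summary`.
#' @export
overlap_summary_from_areas <- function(inside_km2, outside_km2,
                                       current_total_km2,
                                       current_inside_km2 = NULL) {
  stopifnot(current_total_km2 > 0)
  out <- list(inside_km2 = inside_km2, outside_km2 = outside_km2,
              pct_inside = 100 * inside_km2 / current_total_km2,
              pct_outside = 100 * outside_km2 / current_total_km2,
              change_inside_km2 = NA_real_, change_inside_pct = NA_real_)
  if (!is.null(current_inside_km2)) {
    out$change_inside_km2 <- inside_km2 - current_inside_km2
    out$change_inside_pct <- if (current_inside_km2 > 0) {
      100 * (inside_km2 - current_inside_km2) / current_inside_km2
    } else NA_real_
  }
  structure(out, class = "overlap_summary")
}

#' Suitable-habitat overlap with protected areas
#'
#' Suitable cells are partitioned by the cell-center-in-polygon rule.
#'
#' @param binary A binary `niche_layer`.
#' @param mpas A `niche_region` of protected-area polygons.
#' @param areas A [cell_areas()] layer.
#' @param current_total_km2 Current total suitable area (percent base).
#' @param current_inside_km2 Optional current inside-area (change base).
#' @return An `overlap_summary` (with `empty_polygons` flag when `mpas`
#'   has no parts).
#' @export
mpa_overlap <- function(binary, mpas, areas, current_total_km2,
                        current_inside_km2 = NULL) {
  if (!grids_identical(binary$grid, areas$grid)) stop("grid mismatch")
  cells <- which(!is.na(binary$values) & binary$values == 1)
  w <- areas$values[cells]
  empty <- length(region_polygons(mpas)$parts) == 0L
  inside <- if (empty || !length(cells)) rep(FALSE, length(cells)) else {
    cc <- cell_centers(binary$grid, cells)
    region_contains(mpas, cc$lon, cc$lat)
  }
  out <- overlap_summary_from_areas(sum(w[inside]), sum(w[!inside]),
                                    current_total_km2, current_inside_km2)
  out$empty_polygons <- empty
  out
}
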