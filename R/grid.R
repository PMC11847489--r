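#' Define a geographic analysis grid
#'
#' All layers of one analysis share a single grid: a regular lon/lat lattice
#' in WGS84. The origin is the outer (north-west) corner of cell (1,1); row
#' index increases southward, column index eastward, and a cell's value
#' refers to its center.
#'
#' @param origin_lon,origin_lat Coordinates (degrees) of the grid's
#'   north-west corner.
#' @param cell_size Cell edge in degrees (default 0.05, roughly 5.5 km).
#' @param n_rows,n_cols Grid dimensions (rows run north to south).
#' @return An object of class `niche_grid`.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size = 0.05,
                      n_rows, n_cols) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat),
            is.numeric(cell_size), length(cell_size) == 1L)
  if (cell_size <= 0) stop("cell_size must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be >= 1")
  }
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
                 crs = "EPSG:4326"),
            class = "niche_grid")
}

#' @export
print.niche_grid <- function(x, ...) {
  cat(sprintf("<niche_grid> %d x %d cells, %.4g deg, NW corner (%.4f, %.4f), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
              x$crs))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

# Longitudes of column centers / latitudes of row centers.
col_centers <- function(grid) {
  grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}
row_centers <- function(grid) {
  grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

#' Cell-center coordinates for linear cell indices
#'
#' Linear indices follow R's column-major matrix order (row varies fastest).
#'
#' @param grid A `niche_grid`.
#' @param cells Integer vector of linear cell indices (default: all cells).
#' @return Data frame with columns `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$n_rows * grid$n_cols)
  row <- ((cells - 1L) %% grid$n_rows) + 1L
  col <- ((cells - 1L) %/% grid$n_rows) + 1L
  data.frame(cell = cells, row = row, col = col,
             lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
             lat = grid$origin_lat - (row - 0.5) * grid$cell_size)
}

#' Linear cell index of lon/lat points
#'
#' Points outside the grid extent map to `NA`.
#'
#' @param grid A `niche_grid`.
#' @param lon,lat Coordinates in degrees.
#' @return Integer vector of linear cell indices.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1
  # points exactly on the south/east outer edge belong to the last cell
  col[lon == grid$origin_lon + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[lat == grid$origin_lat - grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- is.na(col) | is.na(row) | col < 1 | col > grid$n_cols |
    row < 1 | row > grid$n_rows
  idx <- (col - 1) * grid$n_rows + row
  idx[bad] <- NA
  as.integer(idx)
}

#' Per-cell spherical areas in km^2
#'
#' Uses the closed form A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))
#' on the authalic sphere (R = 6371.0088 km). Area depends on the row only.
#'
#' @param grid A `niche_grid`.
#' @return A `niche_layer` named `"cell_area_km2"` whose values are the
#'   per-cell areas (all positive, no nodata).
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "niche_grid"))
  lat_top <- grid$origin_lat - (seq_len(grid$n_rows) - 1L) * grid$cell_size
  lat_bot <- lat_top - grid$cell_size
  band <- EARTH_RADIUS_KM^2 * deg2rad(grid$cell_size) *
    (sin(deg2rad(lat_top)) - sin(deg2rad(lat_bot)))
  if (any(band <= 0)) stop("grid extends beyond a pole; cell areas undefined")
  raster_layer(grid, matrix(band, grid$n_rows, grid$n_cols),
               name = "cell_area_km2")
}
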