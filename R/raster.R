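#' Construct a raster layer
#'
#' A layer is a matrix of values on a [grid_spec()] grid; `NA` encodes
#' nodata, so the nodata mask is simply `is.na(values(layer))`.
#'
#' @param grid A `niche_grid`.
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = northernmost).
#' @param name Layer label.
#' @return An object of class `niche_layer`.
#' @export
raster_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "niche_grid"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("values shape does not match grid")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("layer values must be finite or NA (nodata)")
  }
  structure(list(grid = grid, values = values, name = name),
            class = "niche_layer")
}

#' @export
print.niche_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<niche_layer> '%s' %d x %d, %d data cells, range [%.4g, %.4g]\n",
              x$name, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

layer_values <- function(layer) layer$values
nodata_mask <- function(layer) is.na(layer$values)

#' Read a single-band geographic raster from an ESRI ASCII grid
#'
#' Plain-text `.asc` format (header `ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value`, then rows north to south). Coordinates must be
#' geographic (WGS84); if a `.prj` sidecar is present and describes a
#' projected CRS the read is refused.
#'
#' @param path File path.
#' @param name Layer name (default: file stem).
#' @return A `niche_layer`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  prj <- sub("\\.[^.]*$", ".prj", path)
  if (file.exists(prj)) {
    wkt <- paste(readLines(prj, warn = FALSE), collapse = " ")
    if (grepl("PROJCS", wkt, fixed = TRUE)) {
      stop("raster has a projected CRS (", sub("\\].*", "]", wkt),
           "); only geographic WGS84 rasters are supported")
    }
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("ASCII grid value count mismatch: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  grid <- grid_spec(origin_lon = hdr$xllcorner,
                    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
                    cell_size = hdr$cellsize, n_rows = nr, n_cols = nc)
  raster_layer(grid, m, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Writes full double precision so write/read round-trips preserve values;
#' a `.prj` sidecar records the WGS84 geographic CRS.
#'
#' @param layer A `niche_layer`.
#' @param path Output path (conventionally `.asc`).
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "niche_layer"))
  g <- layer$grid
  nodata <- -9999
  m <- layer$values
  if (any(m[!is.na(m)] == nodata)) nodata <- min(m, na.rm = TRUE) - 1e6
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.12f", g$origin_lon),
           sprintf("yllcorner %.12f", g$origin_lat - g$n_rows * g$cell_size),
           sprintf("cellsize %.12f", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(paste0('GEOGCS["WGS 84",DATUM["WGS_1984",',
                    'SPHEROID["WGS 84",6378137,298.257223563]],',
                    'PRIMEM["Greenwich",0],UNIT["degree",0.0174532925199433]]'),
             sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}

#' Bundle raster layers into a stack
#'
#' All layers must share one grid (or be resampled onto the grid of the
#' first layer with `resample = "bilinear"`). After alignment every layer
#' carries the union nodata footprint, so the stack has a single combined
#' mask.
#'
#' @param layers List of `niche_layer` objects with unique names.
#' @param resample `"none"` (default; grids must already match) or
#'   `"bilinear"` for continuous layers on a different grid.
#' @return An object of class `niche_stack`.
#' @export
align_stack <- function(layers, resample = c("none", "bilinear")) {
  resample <- match.arg(resample)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "niche_layer")))
  nms <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nms)) stop("layer names must be unique")
  grid <- layers[[1L]]$grid
  same <- vapply(layers, function(l) grids_identical(l$grid, grid), TRUE)
  if (!all(same)) {
    if (resample == "none") {
      stop("layers are on different grids; pass resample = \"bilinear\" ",
           "to interpolate onto the first layer's grid")
    }
    layers[!same] <- lapply(layers[!same], resample_bilinear, grid = grid)
  }
  mask <- Reduce(`|`, lapply(layers, nodata_mask))
  vals <- lapply(layers, function(l) {
    v <- l$values; v[mask] <- NA; v
  })
  structure(list(grid = grid, values = setNames(vals, nms)),
            class = "niche_stack")
}

#' @export
print.niche_stack <- function(x, ...) {
  cat(sprintf("<niche_stack> %d layers (%s), %d x %d, %d data cells\n",
              length(x$values), paste(names(x$values), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols,
              sum(!is.na(x$values[[1L]]))))
  invisible(x)
}

stack_names <- function(stack) names(stack$values)
n_cells <- function(stack) stack$grid$n_rows * stack$grid$n_cols

# Bilinear interpolation of a layer onto a target grid (continuous fields).
resample_bilinear <- function(layer, grid) {
  src <- layer$grid
  xs <- col_centers(src); ys <- rev(row_centers(src))  # ascending
  v <- layer$values[rev(seq_len(src$n_rows)), , drop = FALSE]  # south-up
  tx <- col_centers(grid); ty <- row_centers(grid)
  cx <- pmin(pmax(tx, xs[1]), xs[length(xs)])
  ix <- pmin(pmax(findInterval(cx, xs), 1L), length(xs) - 1L)
  fx <- (cx - xs[ix]) / (xs[ix + 1L] - xs[ix])
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    cy <- pmin(pmax(ty[r], ys[1]), ys[length(ys)])
    iy <- pmin(pmax(findInterval(cy, ys), 1L), length(ys) - 1L)
    fy <- (cy - ys[iy]) / (ys[iy + 1L] - ys[iy])
    out[r, ] <- (1 - fx) * ((1 - fy) * v[iy, ix] + fy * v[iy + 1L, ix]) +
      fx * ((1 - fy) * v[iy, ix + 1L] + fy * v[iy + 1L, ix + 1L])
  }
  raster_layer(grid, out, name = layer$name)
}

#' Mask a stack to a calibration region
#'
#' Cells whose centers fall outside all polygons become nodata; cells
#' inside are unchanged. Masking is idempotent.
#'
#' @param stack A `niche_stack`.
#' @param region A [region_polygons()] object (e.g. the accessible-area /
#'   M-area polygons).
#' @return The masked `niche_stack`.
#' @export
mask_to_region <- function(stack, region) {
  stopifnot(inherits(stack, "niche_stack"))
  cc <- cell_centers(stack$grid)
  inside <- region_contains(region, cc$lon, cc$lat)
  if (!any(inside)) stop("region contains no cell centers: empty calibration area")
  keep <- matrix(inside, stack$grid$n_rows, stack$grid$n_cols)
  vals <- lapply(stack$values, function(v) { v[!keep] <- NA; v })
  structure(list(grid = stack$grid, values = vals), class = "niche_stack")
}

#' Extract predictor values at cells
#'
#' @param stack A `niche_stack`.
#' @param cells Linear cell indices (default all cells).
#' @param vars Layer names to extract (default all).
#' @return Numeric matrix, one row per cell, one column per variable.
#' @export
stack_env <- function(stack, cells = NULL, vars = NULL) {
  vars <- vars %||% stack_names(stack)
  miss <- setdiff(vars, stack_names(stack))
  if (length(miss)) stop("variables not in stack: ", paste(miss, collapse = ", "))
  if (is.null(cells)) cells <- seq_len(n_cells(stack))
  out <- vapply(vars, function(v) stack$values[[v]][cells],
                numeric(length(cells)))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(cells),
                                     dimnames = list(NULL, vars))
  out
}

#' Linear indices of cells with data in every named layer
#'
#' @inheritParams stack_env
#' @return Integer vector of cell indices.
#' @export
data_cells <- function(stack, vars = NULL) {
  vars <- vars %||% stack_names(stack)
  ok <- !Reduce(`|`, lapply(stack$values[vars], is.na))
  which(ok)
}

#' Subset or reorder the layers of a stack
#'
#' @param stack A `niche_stack`.
#' @param vars Layer names to keep, in order.
#' @return A `niche_stack`.
#' @export
stack_subset <- function(stack, vars) {
  miss <- setdiff(vars, stack_names(stack))
  if (length(miss)) stop("variables not in stack: ", paste(miss, collapse = ", "))
  structure(list(grid = stack$grid, values = stack$values[vars]),
            class = "niche_stack")
}
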