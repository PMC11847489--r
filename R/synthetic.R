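#' Synthetic landscape configuration
#'
#' Defaults give a 200 x 200 grid of 0.05-degree cells (about 10 x 10
#' degrees) straddling the equator, with five spatially autocorrelated
#' standardized predictor fields of which the first two drive the truth.
#'
#' @param n_rows,n_cols Grid dimensions (default 200 x 200).
#' @param cell_size Cell edge in degrees (default 0.05).
#' @param origin_lon,origin_lat NW corner (default 130, 5).
#' @param n_vars Number of predictor fields (>= 2, default 5).
#' @param smoothness Spatial correlation length in cells (default 8).
#' @param core_gradient Weight in `[0, 1)` of a domain-centered large-scale
#'   gradient blended into the first variable (default 0.7). This emulates
#'   a bounded physical driver (shelf/bathymetry-like) that keeps the
#'   species' core habitat in the domain interior rather than scattered to
#'   the edges; 0 gives a pure random field.
#' @param seed RNG seed.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 200, n_cols = 200, cell_size = 0.05,
                             origin_lon = 130, origin_lat = 5, n_vars = 5,
                             smoothness = 8, core_gradient = 0.7,
                             seed = 1) {
  stopifnot(n_vars >= 2, smoothness > 0, core_gradient >= 0,
            core_gradient < 1)
  structure(list(grid = grid_spec(origin_lon, origin_lat, cell_size,
                                  n_rows, n_cols),
                 n_vars = as.integer(n_vars), smoothness = smoothness,
                 core_gradient = core_gradient, seed = seed),
            class = "landscape_config")
}

# Gaussian random field: white noise low-pass filtered with a Gaussian
# kernel via FFT (periodic boundary), then standardized to mean 0, sd 1.
gaussian_field <- function(n_rows, n_cols, smoothness) {
  noise <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * smoothness^2))
  kern <- kern / sum(kern)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (n_rows * n_cols)
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic landscape with known truth
#'
#' Predictor fields are seeded, spatially autocorrelated, standardized
#' Gaussian fields. The bundled truth model is a logistic suitability
#' surface in the first two variables,
#' `s(x) = plogis(b0 + b1 v1 + b2 v2 + c2 v2^2)` with `c2 < 0` (a
#' unimodal niche axis in v2).
#'
#' @param cfg A [landscape_config()].
#' @param truth Optional [truth_model()] override.
#' @return List: `stack` (a `niche_stack` of layers `v1..vk`), `truth`.
#' @export
make_landscape <- function(cfg = landscape_config(), truth = NULL) {
  g <- cfg$grid
  layers <- with_seed(cfg$seed, lapply(seq_len(cfg$n_vars), function(i) {
    f <- gaussian_field(g$n_rows, g$n_cols, cfg$smoothness)
    if (i == 1L && cfg$core_gradient > 0) {
      # domain-centered dome: a bounded physical driver keeping the core
      # habitat interior (standardized blend with the random field)
      rr <- (seq_len(g$n_rows) - (g$n_rows + 1) / 2) / (g$n_rows / 2)
      cc <- (seq_len(g$n_cols) - (g$n_cols + 1) / 2) / (g$n_cols / 2)
      dome <- 1 - outer(rr^2, cc^2, "+")
      dome <- (dome - mean(dome)) / sd(dome)
      w <- cfg$core_gradient
      f <- w * dome + sqrt(1 - w^2) * f
      f <- (f - mean(f)) / sd(f)
    }
    raster_layer(g, f, name = paste0("v", i))
  }))
  list(stack = align_stack(layers), truth = truth %||% truth_model())
}

#' Truth model for synthetic suitability
#'
#' @param active Indices of the driving variables (default 1:2).
#' @param b0,b1,b2,c2 Coefficients of
#'   `plogis(b0 + b1 v_a1 + b2 v_a2 + c2 v_a2^2)`; `c2` must be negative
#'   so the second axis is unimodal with optimum at `-b2 / (2 c2)`.
#' @return A list of class `truth_model`.
#' @export
truth_model <- function(active = c(1L, 2L), b0 = -2, b1 = 2, b2 = 1,
                        c2 = -2) {
  stopifnot(length(active) == 2L, c2 < 0)
  structure(list(active = as.integer(active), b0 = b0, b1 = b1, b2 = b2,
                 c2 = c2, optimum_v2 = -b2 / (2 * c2)),
            class = "truth_model")
}

#' Evaluate the true suitability surface
#'
#' @param truth A `truth_model`.
#' @param stack A `niche_stack` holding the active variables.
#' @return A `niche_layer` with values in (0, 1).
#' @export
true_suitability <- function(truth, stack) {
  vars <- stack_names(stack)[truth$active]
  if (anyNA(vars)) stop("active variables missing from stack")
  v1 <- stack$values[[vars[1L]]]
  v2 <- stack$values[[vars[2L]]]
  s <- plogis(truth$b0 + truth$b1 * v1 + truth$b2 * v2 + truth$c2 * v2^2)
  raster_layer(stack$grid, s, name = "true_suitability")
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability times an optional sampling-bias layer; coordinates are
#' jittered uniformly within the cell. Collection years are drawn from
#' 1990-2020 so the records pass the default date filter.
#'
#' @param truth_raster A suitability `niche_layer`.
#' @param n Number of records (>= 0).
#' @param bias_raster Optional nonnegative `niche_layer`.
#' @param seed RNG seed.
#' @return An `occurrence_table`.
#' @export
sample_occurrences <- function(truth_raster, n, bias_raster = NULL,
                               seed = 1) {
  stopifnot(n >= 0)
  w <- truth_raster$values
  if (!is.null(bias_raster)) w <- w * bias_raster$values
  cells <- which(!is.na(w))
  wts <- w[cells]
  if (n == 0L) {
    return(occurrence_table(data.frame(lon = numeric(), lat = numeric(),
                                       year = integer(),
                                       basis = character())))
  }
  if (all(wts <= 0)) stop("all sampling weights are zero")
  g <- truth_raster$grid
  with_seed(seed, {
    drawn <- sample(cells, n, replace = TRUE, prob = wts)
    cc <- cell_centers(g, drawn)
    occurrence_table(data.frame(
      lon = cc$lon + runif(n, -0.5, 0.5) * g$cell_size,
      lat = cc$lat + runif(n, -0.5, 0.5) * g$cell_size,
      year = sample(1990:2020, n, replace = TRUE),
      basis = "human_observation"))
  })
}

#' Scenario configuration for synthetic futures
#'
#' @param translation `c(dlon, dlat)` in degrees applied to the active
#'   fields (rounded to whole cells).
#' @param trend Named numeric vector of additive per-variable trends.
#' @param vars Names of the variables to translate (default: set by
#'   [make_future()] from the truth model's active variables).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(translation = c(1, 0), trend = numeric(),
                            vars = NULL) {
  if (all(translation == 0) && (!length(trend) || all(trend == 0))) {
    stop("scenario must perturb something: zero translation and trend")
  }
  structure(list(translation = translation, trend = trend, vars = vars),
            class = "scenario_config")
}

shift_matrix <- function(m, d_col, d_row) {
  nr <- nrow(m); nc <- ncol(m)
  src_col <- pmin(pmax(seq_len(nc) - d_col, 1L), nc)
  src_row <- pmin(pmax(seq_len(nr) - d_row, 1L), nr)
  m[src_row, src_col, drop = FALSE]
}

#' Build a future scenario stack
#'
#' Translates the named (default: truth-active) fields by the configured
#' whole-cell offset (edge values replicated), adds any per-variable
#' trends, and copies static fields unchanged. The translation moves the
#' true-suitability pattern by the same offset, providing a known-answer
#' range-shift target.
#'
#' @param stack The present-day `niche_stack`.
#' @param scenario A [scenario_config()].
#' @param truth Optional `truth_model` supplying the default variable set.
#' @return A `niche_stack` on the same grid.
#' @export
make_future <- function(stack, scenario, truth = NULL) {
  g <- stack$grid
  d_col <- round(scenario$translation[1L] / g$cell_size)
  d_row <- round(-scenario$translation[2L] / g$cell_size)
  if (abs(d_col) >= g$n_cols || abs(d_row) >= g$n_rows) {
    stop("translation exceeds the grid extent")
  }
  vars <- scenario$vars %||%
    (if (!is.null(truth)) stack_names(stack)[truth$active] else
       stack_names(stack))
  vals <- stack$values
  for (v in vars) vals[[v]] <- shift_matrix(vals[[v]], d_col, d_row)
  for (v in names(scenario$trend)) {
    vals[[v]] <- vals[[v]] + scenario$trend[[v]]
  }
  structure(list(grid = g, values = vals), class = "niche_stack")
}

#' Generate synthetic protected-area polygons
#'
#' Adds random rectangles (anchored at suitable cells) until they cover a
#' fraction of the currently suitable area within `coverage_frac` +/-
#' 0.05, measured by the same center-in-polygon rule used downstream.
#'
#' @param truth_binary A binary `niche_layer` of current suitable habitat.
#' @param areas A [cell_areas()] layer.
#' @param coverage_frac Target covered fraction in (0, 1).
#' @param seed RNG seed.
#' @param max_attempts Bounded attempts before giving up (default 500).
#' @return A `niche_region` with a `name` attribute column.
#' @export
make_protected_areas <- function(truth_binary, areas, coverage_frac,
                                 seed = 1, max_attempts = 500) {
  stopifnot(coverage_frac > 0, coverage_frac < 1)
  g <- truth_binary$grid
  cells <- which(!is.na(truth_binary$values) & truth_binary$values == 1)
  if (!length(cells)) stop("no suitable cells to cover")
  cc <- cell_centers(g, cells)
  w <- areas$values[cells]
  total <- sum(w)
  with_seed(seed, {
    rects <- list()
    covered <- rep(FALSE, length(cells))
    for (i in seq_len(max_attempts)) {
      frac <- sum(w[covered]) / total
      if (abs(frac - coverage_frac) <= 0.05 && frac >= coverage_frac - 0.05 &&
          length(rects)) break
      anchor <- sample(which(!covered), 1L)
      half_lon <- runif(1, 2, 15) * g$cell_size
      half_lat <- runif(1, 2, 15) * g$cell_size
      lon0 <- cc$lon[anchor] - half_lon; lon1 <- cc$lon[anchor] + half_lon
      lat0 <- cc$lat[anchor] - half_lat; lat1 <- cc$lat[anchor] + half_lat
      new_cov <- covered | (cc$lon >= lon0 & cc$lon <= lon1 &
                              cc$lat >= lat0 & cc$lat <= lat1)
      if (sum(w[new_cov]) / total > coverage_frac + 0.05) next
      covered <- new_cov
      rects[[length(rects) + 1L]] <-
        cbind(c(lon0, lon1, lon1, lon0, lon0),
              c(lat0, lat0, lat1, lat1, lat0))
    }
    frac <- sum(w[covered]) / total
    if (abs(frac - coverage_frac) > 0.05) {
      stop(sprintf("could not reach coverage %.2f +/- 0.05 (got %.2f)",
                   coverage_frac, frac))
    }
    region_polygons(rects,
                    attributes = data.frame(
                      name = sprintf("synthetic_mpa_%02d",
                                     seq_along(rects))))
  })
}
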