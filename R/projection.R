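#' Project a fitted model onto a scenario stack
#'
#' With `clamp = TRUE` (the default, matching extrapolation-with-clamping)
#' every variable is clipped to its calibration range before feature
#' evaluation, so predictions outside the calibration envelope equal the
#' prediction at the envelope edge. A scenario identical to the
#' calibration stack reproduces the calibration-period prediction exactly.
#'
#' @param model A `maxent_model`.
#' @param scenario A `niche_stack` holding all model variables (static
#'   variables carried over unchanged) on the calibration grid.
#' @param clamp Clip variables to calibration bounds (default TRUE).
#' @param name Output layer name.
#' @return A `niche_layer` of cloglog suitability.
#' @export
project <- function(model, scenario, clamp = TRUE, name = "suitability") {
  miss <- setdiff(model$feature_map$vars, stack_names(scenario))
  if (length(miss)) {
    stop("scenario lacks model variable(s): ", paste(miss, collapse = ", "))
  }
  suitability_raster(model, scenario, clamp = clamp, name = name)
}

#' Mobility-oriented parity (MOP) extrapolation map
#'
#' Variables are standardized by calibration mean/sd. A scenario cell with
#' any variable outside the calibration min-max is strict extrapolation
#' (similarity 0); otherwise similarity is
#' `1 - meanDist / max(meanDist over non-strict cells)`, where `meanDist`
#' is the mean Euclidean distance to the nearest
#' `ceiling(subset_frac * n_ref)` calibration cells.
#'
#' @param calibration_stack Masked calibration `niche_stack`.
#' @param scenario Scenario `niche_stack` sharing the variable names.
#' @param subset_frac Fraction of reference cells defining "nearest"
#'   (default 0.10).
#' @param sample_cap Reference-cell subsample cap (default 10,000).
#' @param seed RNG seed for the subsample.
#' @param vars Variables to use (default: calibration stack layers).
#' @return List of class `niche_mop`: `similarity` (`niche_layer` in
#'   `[0,1]`), `strict_mask` (`niche_layer`, 1 = strict extrapolation).
#' @export
mop <- function(calibration_stack, scenario, subset_frac = 0.10,
                sample_cap = 10000, seed = 1, vars = NULL) {
  vars <- vars %||% stack_names(calibration_stack)
  miss <- setdiff(vars, stack_names(scenario))
  if (length(miss)) stop("scenario lacks variable(s): ",
                         paste(miss, collapse = ", "))
  ref_cells <- data_cells(calibration_stack, vars)
  if (!length(ref_cells)) stop("calibration stack has no data cells")
  ref <- stack_env(calibration_stack, ref_cells, vars)
  mu <- colMeans(ref); sdev <- apply(ref, 2L, sd)
  sdev[sdev == 0] <- 1
  lo <- apply(ref, 2L, min); hi <- apply(ref, 2L, max)
  if (nrow(ref) > sample_cap) {
    ref <- ref[with_seed(seed, sort(sample.int(nrow(ref), sample_cap))), ,
               drop = FALSE]
  }
  refz <- sweep(sweep(ref, 2L, mu), 2L, sdev, "/")
  k <- max(1L, ceiling(subset_frac * nrow(refz)))
  scen_cells <- data_cells(scenario, vars)
  scen <- stack_env(scenario, scen_cells, vars)
  strict <- rowSums(sweep(scen, 2L, lo, "<") | sweep(scen, 2L, hi, ">")) > 0
  scenz <- sweep(sweep(scen, 2L, mu), 2L, sdev, "/")
  meand <- rep(NA_real_, nrow(scen))
  idx <- which(!strict)
  if (length(idx)) {
    ref_sq <- rowSums(refz^2)
    chunk <- 2000L
    for (s in seq(1L, length(idx), by = chunk)) {
      ii <- idx[s:min(s + chunk - 1L, length(idx))]
      A <- scenz[ii, , drop = FALSE]
      d2 <- outer(rowSums(A^2), ref_sq, "+") - 2 * A %*% t(refz)
      d2[d2 < 0] <- 0
      meand[ii] <- apply(d2, 1L, function(r) mean(sqrt(sort(r,
                                                            partial = k)[1:k])))
    }
    mx <- max(meand[idx])
    sim_vals <- if (mx > 0) 1 - meand / mx else rep(1, length(meand))
  } else sim_vals <- meand
  sim <- matrix(NA_real_, scenario$grid$n_rows, scenario$grid$n_cols)
  sim[scen_cells] <- ifelse(strict, 0, sim_vals)
  sm <- matrix(NA_real_, scenario$grid$n_rows, scenario$grid$n_cols)
  sm[scen_cells] <- as.numeric(strict)
  structure(list(similarity = raster_layer(scenario$grid, sim,
                                           "mop_similarity"),
                 strict_mask = raster_layer(scenario$grid, sm, "mop_strict")),
            class = "niche_mop")
}
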