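#' Sample background cells from a stack
#'
#' Uniform sample without replacement of cells with data in every layer,
#' capped at `n_max` (default 10,000). Presence cells are not excluded.
#'
#' @param stack A `niche_stack` (already masked to the calibration area).
#' @param n_max Maximum number of background cells.
#' @param seed RNG seed.
#' @param vars Layers that must have data (default all).
#' @return Integer vector of linear cell indices.
#' @export
sample_background <- function(stack, n_max = 10000, seed = 1, vars = NULL) {
  cells <- data_cells(stack, vars)
  if (!length(cells)) stop("stack has no data cells")
  if (length(cells) <= n_max) return(cells)
  sort(with_seed(seed, sample(cells, n_max)))
}

#' Fit a regularized maximum-entropy presence-background model
#'
#' Minimizes the penalized Gibbs objective
#' \deqn{-\frac{1}{m}\sum_{i \in pres} \eta(x_i) + \log Z_\lambda +
#'   \sum_j \beta_j |\lambda_j|}
#' with \eqn{\eta(x) = \sum_j \lambda_j f_j(x)} and
#' \eqn{Z_\lambda = \sum_{bg} e^{\eta(x)}}, by cyclic coordinate descent
#' with soft-thresholding (compiled). Penalties follow the per-class
#' default schedule scaled by the regularization multiplier:
#' \eqn{\beta_j = rm \cdot \beta_{class}(m) \cdot s_j / \sqrt{m}} with
#' \eqn{s_j} the feature's standard deviation over presences.
#'
#' @param pres_env Presence matrix (records x variables, named columns);
#'   at least 2 distinct rows.
#' @param bg_env Background matrix (cells x variables, same columns).
#' @param spec A [feature_spec()].
#' @param feature_map Optional prebuilt [build_feature_map()]; by default
#'   built from `bg_env`.
#' @param max_iter Maximum coordinate-descent cycles (default 500).
#' @param tol Convergence threshold on the objective (default 1e-5).
#' @param n_knots Hinge knots per variable per direction (default 50).
#' @return An object of class `maxent_model`: feature map, coefficients
#'   `lambda`, penalties `beta`, `log_normalizer` (log Z over background),
#'   `entropy` H of the fitted distribution, regularized training `gain`,
#'   and the background/presence data used.
#' @export
fit_maxent <- function(pres_env, bg_env, spec = feature_spec(),
                       feature_map = NULL, max_iter = 500, tol = 1e-5,
                       n_knots = 50) {
  pres_env <- as.matrix(pres_env); bg_env <- as.matrix(bg_env)
  if (nrow(unique(pres_env)) < 2L) {
    stop("need at least 2 distinct presence records")
  }
  fm <- feature_map %||% build_feature_map(bg_env, classes = spec$classes,
                                           n_knots = n_knots)
  Fp <- feature_matrix(fm, pres_env)
  Fb <- feature_matrix(fm, bg_env)
  beta <- feature_penalties(fm, Fp, Fb, spec$rm)
  fit <- ccd_gibbs(Fp, Fb, beta, as.integer(max_iter), tol)
  structure(list(feature_map = fm, spec = spec,
                 lambda = setNames(fit$lambda, fm$features$name),
                 beta = setNames(beta, fm$features$name),
                 log_normalizer = fit$log_normalizer,
                 entropy = fit$entropy,
                 objective = fit$objective, gain = fit$gain,
                 converged = fit$converged, iterations = fit$iterations,
                 pres_env = pres_env, bg_env = bg_env),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d vars, classes {%s}, rm = %g, ",
                     "%d/%d nonzero features, gain %.4f, H %.4f\n"),
              length(x$feature_map$vars),
              paste(x$spec$classes, collapse = ","), x$spec$rm,
              sum(x$lambda != 0), length(x$lambda), x$gain, x$entropy))
  invisible(x)
}

model_eta <- function(model, env, clamp = FALSE) {
  Fx <- feature_matrix(model$feature_map, env, clamp = clamp)
  drop(Fx %*% model$lambda)
}

#' Raw (Gibbs) output of a fitted model
#'
#' `q(x) = exp(eta(x)) / Z`; sums to 1 over the model's background sample.
#'
#' @param model A `maxent_model`.
#' @param env Matrix of predictor values (default: model background).
#' @param clamp Clip variables to calibration bounds first.
#' @return Numeric vector of nonnegative raw scores.
#' @export
raw_output <- function(model, env = model$bg_env, clamp = FALSE) {
  exp(model_eta(model, env, clamp) - model$log_normalizer)
}

#' Cloglog output of a fitted model
#'
#' `c(x) = 1 - exp(-e^H q(x))`, an occurrence-probability-like score in
#' `[0,1]`, strictly increasing in the raw output. A model with all
#' coefficients zero yields `1 - exp(-1)` everywhere.
#'
#' @inheritParams raw_output
#' @return Numeric vector in `[0,1]`.
#' @export
cloglog_output <- function(model, env = model$bg_env, clamp = FALSE) {
  1 - exp(-exp(model$entropy) * raw_output(model, env, clamp))
}

#' Predict a suitability raster over a stack
#'
#' Evaluates the cloglog output at every data cell of `stack`; nodata cells
#' stay nodata.
#'
#' @param model A `maxent_model`.
#' @param stack A `niche_stack` holding all model variables.
#' @param clamp Clip variables to calibration bounds (used when projecting
#'   onto scenario layers).
#' @param name Output layer name.
#' @return A `niche_layer` of cloglog suitability.
#' @export
suitability_raster <- function(model, stack, clamp = FALSE,
                               name = "suitability") {
  cells <- data_cells(stack, model$feature_map$vars)
  env <- stack_env(stack, cells, model$feature_map$vars)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[cells] <- cloglog_output(model, env, clamp = clamp)
  raster_layer(stack$grid, vals, name = name)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_presence > score_background) + 0.5 P(equal)`, computed from
#' midranks; equals exhaustive pair counting exactly.
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in `[0,1]`.
#' @export
auc_mw <- function(scores_presence, scores_background) {
  m <- length(scores_presence); n <- length(scores_background)
  stopifnot(m > 0, n > 0)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Training AUC of a fitted model
#'
#' AUC of the cloglog scores at the training presences against the
#' background sample.
#'
#' @param model A `maxent_model`.
#' @param pres_env,bg_env Presence/background matrices (default: the
#'   model's training data).
#' @return AUC in `[0,1]`.
#' @export
training_auc <- function(model, pres_env = model$pres_env,
                         bg_env = model$bg_env) {
  auc_mw(cloglog_output(model, pres_env), cloglog_output(model, bg_env))
}

refit_with_vars <- function(model, vars) {
  fit_maxent(model$pres_env[, vars, drop = FALSE],
             model$bg_env[, vars, drop = FALSE],
             spec = model$spec,
             n_knots = max(lengths(model$feature_map$knots), 50))
}

#' Percent contribution of each variable
#'
#' Defined by refit-drop: for each variable the model is refit without any
#' of that variable's features; the drop in regularized training gain
#' (clipped at zero) is normalized to sum to 100.
#'
#' @param model A `maxent_model`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  vars <- model$feature_map$vars
  if (length(vars) == 1L) return(setNames(100, vars))
  drops <- vapply(vars, function(v) {
    g <- refit_with_vars(model, setdiff(vars, v))$gain
    max(0, model$gain - g)
  }, numeric(1L))
  if (sum(drops) <= 0) return(setNames(rep(100 / length(vars), length(vars)),
                                       vars))
  100 * drops / sum(drops)
}

#' Permutation importance of each variable
#'
#' Shuffles one variable's values across the pooled presence+background
#' rows, recomputes the training AUC, and normalizes the (clipped) AUC
#' drops to sum to 100.
#'
#' @param model A `maxent_model`.
#' @param seed RNG seed for the permutations.
#' @return Named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, seed = 1) {
  vars <- model$feature_map$vars
  if (length(vars) == 1L) return(setNames(100, vars))
  full <- training_auc(model)
  m <- nrow(model$pres_env)
  pooled <- rbind(model$pres_env, model$bg_env)
  drops <- with_seed(seed, vapply(vars, function(v) {
    perm <- pooled
    perm[, v] <- sample(perm[, v])
    max(0, full - training_auc(model, perm[seq_len(m), , drop = FALSE],
                               perm[-seq_len(m), , drop = FALSE]))
  }, numeric(1L)))
  if (sum(drops) <= 0) return(setNames(rep(100 / length(vars), length(vars)),
                                       vars))
  100 * drops / sum(drops)
}

#' Jackknife gains and AUCs per variable
#'
#' For each variable, refits the model excluding it and using only it,
#' reporting the regularized training gain and training AUC of each refit.
#' A refit failure flags its row and leaves the others unaffected.
#'
#' @param model A `maxent_model` with at least 2 variables.
#' @return Data frame with columns `variable`, `gain_without`, `gain_only`,
#'   `auc_without`, `auc_only`, `failed`.
#' @export
jackknife_gains <- function(model) {
  vars <- model$feature_map$vars
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables")
  rows <- lapply(vars, function(v) {
    out <- data.frame(variable = v, gain_without = NA_real_,
                      gain_only = NA_real_, auc_without = NA_real_,
                      auc_only = NA_real_, failed = FALSE)
    tryCatch({
      wo <- refit_with_vars(model, setdiff(vars, v))
      on <- refit_with_vars(model, v)
      out$gain_without <- wo$gain; out$auc_without <- training_auc(wo)
      out$gain_only <- on$gain; out$auc_only <- training_auc(on)
      out
    }, error = function(e) { out$failed <- TRUE; out })
  })
  do.call(rbind, rows)
}

#' Response curve of one variable
#'
#' Evaluates the cloglog output on an even grid spanning the variable's
#' calibration range, holding all other variables at their background
#' means. For a replicate set the mean and standard deviation across
#' replicates are reported; for a single model the sd is zero.
#'
#' @param object A `maxent_model` or `maxent_replicates`.
#' @param variable Variable name.
#' @param n_points Number of evaluation points (default 100).
#' @return Data frame with columns `value`, `cloglog`, `sd`.
#' @export
response_curve <- function(object, variable, n_points = 100) {
  models <- if (inherits(object, "maxent_replicates")) object$models
            else list(object)
  fm <- models[[1L]]$feature_map
  if (!variable %in% fm$vars) stop("variable not in model: ", variable)
  xs <- seq(fm$lower[variable], fm$upper[variable], length.out = n_points)
  base <- colMeans(models[[1L]]$bg_env)
  env <- matrix(base, n_points, length(fm$vars), byrow = TRUE,
                dimnames = list(NULL, fm$vars))
  env[, variable] <- xs
  preds <- vapply(models, cloglog_output, numeric(n_points), env = env)
  if (!is.matrix(preds)) preds <- matrix(preds, ncol = length(models))
  sds <- if (ncol(preds) > 1L) apply(preds, 1L, sd) else rep(0, n_points)
  data.frame(value = xs, cloglog = rowMeans(preds), sd = sds)
}

#' Bootstrap replicate fits
#'
#' Fits `n` models, each on a with-replacement resample of the presences
#' (same size); the background is fixed across replicates. When a stack is
#' supplied, cellwise mean and standard-deviation suitability rasters are
#' attached.
#'
#' @inheritParams fit_maxent
#' @param n Number of replicates (default 10).
#' @param seed RNG seed driving the resampling.
#' @param stack Optional `niche_stack` for mean/sd rasters.
#' @return An object of class `maxent_replicates`: `models`, plus `mean`
#'   and `sd` rasters when `stack` is given.
#' @export
replicate_fit <- function(pres_env, bg_env, spec = feature_spec(), n = 10,
                          seed = 1, stack = NULL, max_iter = 500,
                          tol = 1e-5, n_knots = 50) {
  pres_env <- as.matrix(pres_env)
  m <- nrow(pres_env)
  idx <- with_seed(seed, replicate(n, sample.int(m, m, replace = TRUE),
                                   simplify = FALSE))
  models <- list(); failures <- character()
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_maxent(pres_env[idx[[i]], , drop = FALSE], bg_env, spec,
                 max_iter = max_iter, tol = tol, n_knots = n_knots),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", i,
                                      conditionMessage(fit)))
    } else models[[length(models) + 1L]] <- fit
  }
  if (!length(models)) stop("all replicates failed: ",
                            paste(failures, collapse = "; "))
  if (length(failures)) warning(paste(failures, collapse = "; "))
  out <- structure(list(models = models, failures = failures, seed = seed),
                   class = "maxent_replicates")
  if (!is.null(stack)) {
    preds <- lapply(models, suitability_raster, stack = stack)
    arr <- vapply(preds, layer_values,
                  matrix(0, stack$grid$n_rows, stack$grid$n_cols))
    out$mean <- raster_layer(stack$grid,
                             apply(arr, c(1, 2), mean),
                             name = "suitability_mean")
    out$sd <- raster_layer(stack$grid, apply(arr, c(1, 2), sd),
                           name = "suitability_sd")
  }
  out
}

#' @export
print.maxent_replicates <- function(x, ...) {
  cat(sprintf("<maxent_replicates> %d replicate model(s)\n",
              length(x$models)))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Stores the feature map, coefficients, penalties, normalizer and entropy
#' so a model can be archived alongside its predictions.
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(spec = list(classes = model$spec$classes, rm = model$spec$rm),
              vars = model$feature_map$vars,
              lower = as.list(model$feature_map$lower),
              upper = as.list(model$feature_map$upper),
              knots = model$feature_map$knots,
              features = model$feature_map$features,
              lambda = as.list(model$lambda),
              beta = as.list(model$beta),
              log_normalizer = model$log_normalizer,
              entropy = model$entropy, gain = model$gain)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
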