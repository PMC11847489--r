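#' Generate the candidate-model grid
#'
#' Cross product of regularization multipliers with every nonempty subset
#' of the base feature classes. The default grid (8 RM values 0.5-4.0 by
#' 0.5, classes l/q/p/h) yields 120 candidates.
#'
#' @param rm_values Numeric vector of regularization multipliers.
#' @param classes Base feature classes.
#' @param set_id Integer tag for the variable set (used in candidate ids).
#' @return Data frame with columns `id`, `rm`, `classes` (comma string)
#'   and a `spec` list column of [feature_spec()] objects.
#' @export
generate_candidates <- function(rm_values = seq(0.5, 4, by = 0.5),
                                classes = c("l", "q", "p", "h"),
                                set_id = 1L) {
  if (!length(rm_values)) stop("rm_values must be nonempty")
  classes <- unique(match.arg(classes, c("l", "q", "p", "h"),
                              several.ok = TRUE))
  if (!length(classes)) stop("base class set must be nonempty")
  subsets <- unlist(lapply(seq_along(classes), function(k) {
    asplit(combn(classes, k), 2L)
  }), recursive = FALSE)
  rows <- list()
  for (rm in rm_values) {
    for (cs in subsets) {
      cs <- as.character(cs)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("M_%g_F_%s_Set_%d", rm, paste(cs, collapse = ""),
                     set_id),
        rm = rm, classes = paste(cs, collapse = ","))
    }
  }
  out <- do.call(rbind, rows)
  out$spec <- lapply(seq_len(nrow(out)), function(i) {
    feature_spec(strsplit(out$classes[i], ",")[[1L]], out$rm[i])
  })
  out
}

#' Split occurrences into calibration and internal-testing subsets
#'
#' @param table An `occurrence_table` with at least 4 records.
#' @param train_frac Fraction assigned to training (default 0.7);
#'   `round(train_frac * n)` records are trained on.
#' @param seed RNG seed.
#' @return List with `train` and `test` occurrence tables (disjoint, union
#'   equals the input).
#' @export
split_occurrences <- function(table, train_frac = 0.7, seed = 1) {
  table <- occurrence_table(table)
  n <- nrow(table)
  if (n < 4L) stop("need at least 4 records to split")
  n_train <- round(train_frac * n)
  if (n_train < 1L || n_train >= n) {
    stop("train_frac = ", train_frac, " leaves an empty train or test set")
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[-sort(idx), , drop = FALSE])
}

#' Omission rate at tolerance E
#'
#' The threshold is the ceiling(E * n_train)-th smallest training score
#' (at least the smallest one); the rate is the fraction of test scores
#' strictly below it.
#'
#' @param train_scores,test_scores Suitability scores at training and
#'   testing presences.
#' @param E Omission tolerance in `[0,1)` (default 0.05).
#' @return Omission rate in `[0,1]`.
#' @export
omission_rate <- function(train_scores, test_scores, E = 0.05) {
  stopifnot(length(train_scores) > 0, length(test_scores) > 0)
  k <- max(1L, ceiling(E * length(train_scores)))
  tau <- sort(train_scores)[k]
  mean(test_scores < tau)
}

#' Partial-ROC significance test
#'
#' Bootstraps the test presences and compares the AUC ratio (area under
#' the proportional-area vs sensitivity curve restricted to sensitivity
#' >= 1 - E, over the same area under the 1:1 null line) against 1. The
#' p value is the fraction of iterations with ratio <= 1.
#'
#' @param test_scores Suitability scores at testing presences.
#' @param raster_values Suitability at every data cell of the prediction.
#' @param E Omission tolerance (default 0.05).
#' @param iterations Bootstrap iterations (default 500).
#' @param bootstrap_frac Fraction of test points resampled (with
#'   replacement) per iteration (default 0.5).
#' @param seed RNG seed.
#' @param max_thresholds Cap on threshold sweep size (default 1000 evenly
#'   spaced quantiles for large rasters).
#' @return List: `mean_auc_ratio`, `p_value`, `ratios`, `degenerate`.
#' @export
partial_roc <- function(test_scores, raster_values, E = 0.05,
                        iterations = 500, bootstrap_frac = 0.5, seed = 1,
                        max_thresholds = 1000) {
  stopifnot(length(test_scores) > 0)
  raster_values <- raster_values[!is.na(raster_values)]
  thr <- sort(unique(raster_values))
  if (length(thr) < 2L) {
    return(list(mean_auc_ratio = NA_real_, p_value = 1,
                ratios = rep(NA_real_, iterations), degenerate = TRUE))
  }
  if (length(thr) > max_thresholds) {
    thr <- unique(quantile(raster_values,
                           probs = seq(0, 1, length.out = max_thresholds),
                           names = FALSE))
  }
  # proportion of area predicted present at each threshold (descending t
  # gives ascending x); computed once per model
  n_cell <- length(raster_values)
  sorted <- sort(raster_values)
  x <- 1 - (findInterval(thr, sorted, left.open = TRUE) / n_cell)
  ord <- order(x)
  x <- x[ord]; thr_x <- thr[ord]
  n_boot <- max(1L, ceiling(bootstrap_frac * length(test_scores)))
  sens_curve <- function(scores) {
    s <- sort(scores)
    1 - findInterval(thr_x, s, left.open = TRUE) / length(s)
  }
  ratios <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    partial_auc_ratio(x, sens_curve(sample(test_scores, n_boot,
                                           replace = TRUE)), E)
  }, numeric(1L)))
  list(mean_auc_ratio = mean(ratios, na.rm = TRUE),
       p_value = mean(is.na(ratios) | ratios <= 1), ratios = ratios,
       degenerate = FALSE)
}

# AUC ratio of a (proportional area, sensitivity) curve restricted to
# sensitivity >= 1 - E against the 1:1 line over the same support; the
# null line evaluated against itself gives exactly 1.
partial_auc_ratio <- function(x, y, E) {
  keep <- y >= 1 - E
  if (sum(keep) < 2L) {
    xs <- c(max(x[keep], 1 - E), 1)
    return(trapz(xs, c(1, 1)) / trapz(xs, xs))
  }
  xs <- x[keep]; ys <- y[keep]
  if (xs[length(xs)] < 1) { xs <- c(xs, 1); ys <- c(ys, 1) }
  trapz(xs, ys) / trapz(xs, xs)
}

#' Sample-size-corrected Akaike criterion for a fitted model
#'
#' Raw scores are standardized to sum to 1 over all data cells of the
#' calibration stack; the log likelihood is the sum of log standardized
#' scores at the occurrence cells; k is the number of nonzero
#' coefficients. Undefined (NA) when n <= k + 1.
#'
#' @param model A `maxent_model`.
#' @param stack The calibration `niche_stack`.
#' @param occ_cells Linear cell indices of all occurrences.
#' @return List: `aicc`, `k`, `n`, `lnL`.
#' @export
aicc <- function(model, stack, occ_cells) {
  cells <- data_cells(stack, model$feature_map$vars)
  drop_occ <- !(occ_cells %in% cells)
  if (any(drop_occ)) {
    warning(sum(drop_occ), " occurrence cell(s) on nodata excluded from AICc")
    occ_cells <- occ_cells[!drop_occ]
  }
  raw_all <- raw_output(model, stack_env(stack, cells,
                                         model$feature_map$vars))
  p <- raw_all / sum(raw_all)
  lnL <- sum(log(p[match(occ_cells, cells)]))
  k <- sum(model$lambda != 0)
  n <- length(occ_cells)
  val <- if (n <= k + 1) NA_real_ else {
    2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  }
  list(aicc = val, k = k, n = n, lnL = lnL)
}

#' Candidate selection criteria
#'
#' @param alpha Partial-ROC significance level (default 0.05).
#' @param E Omission tolerance (default 0.05).
#' @param d_aicc_max Maximum delta AICc (default 2).
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(alpha = 0.05, E = 0.05, d_aicc_max = 2) {
  stopifnot(alpha > 0, alpha < 1, E >= 0, E < 1, d_aicc_max >= 0)
  structure(list(alpha = alpha, E = E, d_aicc_max = d_aicc_max),
            class = "selection_criteria")
}

#' Apply the three-criterion filter to a candidate results table
#'
#' Works on any data frame with `p_value`, `omission_rate` and `aicc`
#' columns: flags statistical significance (p <= alpha), omission
#' (rate <= E), computes delta AICc against the minimum over candidates
#' passing the first two criteria, and selects candidates meeting all
#' three.
#'
#' @param results Data frame of per-candidate statistics.
#' @param criteria A [selection_criteria()].
#' @return The data frame with added `significant`, `meets_omission`,
#'   `delta_aicc`, `meets_aicc`, `selected` columns.
#' @export
select_candidates <- function(results, criteria = selection_criteria()) {
  results$significant <- !is.na(results$p_value) &
    results$p_value <= criteria$alpha
  results$meets_omission <- !is.na(results$omission_rate) &
    results$omission_rate <= criteria$E
  pool <- results$significant & results$meets_omission & !is.na(results$aicc)
  if (any(pool)) {
    results$delta_aicc <- results$aicc - min(results$aicc[pool])
  } else {
    results$delta_aicc <- NA_real_
    warning("no candidate passes significance and omission; none selected")
  }
  results$meets_aicc <- !is.na(results$delta_aicc) &
    results$delta_aicc <= criteria$d_aicc_max
  results$selected <- results$significant & results$meets_omission &
    results$meets_aicc
  results
}

#' Fit and evaluate the candidate-model grid
#'
#' Each candidate is fitted on the training presences and scored by
#' partial-ROC significance, omission rate at E, and AICc (computed from
#' the train-fitted model at all occurrences), then filtered with
#' [select_candidates()]. A failed fit flags its row and is excluded from
#' the delta-AICc pool.
#'
#' @param candidates Data frame from [generate_candidates()].
#' @param train,test Occurrence tables from [split_occurrences()].
#' @param stack Masked calibration `niche_stack` (selected variables only).
#' @param criteria A [selection_criteria()].
#' @param background_max Background cap (default 10,000).
#' @param seed RNG seed (background sample, partial-ROC bootstrap).
#' @param n_knots,max_iter,tol Passed to [fit_maxent()].
#' @param proc_iterations Partial-ROC iterations (default 500).
#' @param verbose Print one line per candidate.
#' @return List: `results` (data frame, one row per candidate),
#'   `selected` (ids), `background` (cell indices used).
#' @export
evaluate_candidates <- function(candidates, train, test, stack,
                                criteria = selection_criteria(),
                                background_max = 10000, seed = 1,
                                n_knots = 50, max_iter = 500, tol = 1e-5,
                                proc_iterations = 500, verbose = FALSE) {
  stopifnot(nrow(candidates) > 0)
  train <- occurrence_table(train); test <- occurrence_table(test)
  dc <- data_cells(stack)
  occ_cells_of <- function(tab) {
    cl <- cell_index(stack$grid, tab$lon, tab$lat)
    cl[!is.na(cl) & cl %in% dc]
  }
  train_cells <- occ_cells_of(train)
  test_cells <- occ_cells_of(test)
  if (!length(train_cells) || !length(test_cells)) {
    stop("train or test occurrences have no data cells")
  }
  bg <- sample_background(stack, background_max, seed = seed)
  bg_env <- stack_env(stack, bg)
  pres_env <- stack_env(stack, train_cells)
  all_cells <- c(train_cells, test_cells)
  env_all <- stack_env(stack, dc)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    spec <- candidates$spec[[i]]
    row <- data.frame(id = candidates$id[i], rm = candidates$rm[i],
                      classes = candidates$classes[i],
                      mean_auc_ratio = NA_real_, p_value = NA_real_,
                      omission_rate = NA_real_, aicc = NA_real_,
                      k = NA_integer_, failed = FALSE)
    fit <- tryCatch(
      fit_maxent(pres_env, bg_env, spec, n_knots = n_knots,
                 max_iter = max_iter, tol = tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row$failed <- TRUE
    } else {
      pred_all <- cloglog_output(fit, env_all)
      train_scores <- cloglog_output(fit, stack_env(stack, train_cells))
      test_scores <- cloglog_output(fit, stack_env(stack, test_cells))
      proc <- partial_roc(test_scores, pred_all, E = criteria$E,
                          iterations = proc_iterations,
                          seed = seed + i)
      row$mean_auc_ratio <- proc$mean_auc_ratio
      row$p_value <- proc$p_value
      row$omission_rate <- omission_rate(train_scores, test_scores,
                                         E = criteria$E)
      row$aicc <- aicc(fit, stack, all_cells)$aicc
      row$k <- sum(fit$lambda != 0)
    }
    if (verbose) {
      message(sprintf("%s: p=%.3f OR=%.3f AICc=%.1f", row$id, row$p_value,
                      row$omission_rate, row$aicc))
    }
    rows[[i]] <- row
  }
  results <- select_candidates(do.call(rbind, rows), criteria)
  list(results = results, selected = results$id[results$selected],
       background = bg)
}
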