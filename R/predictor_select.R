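#' Pairwise Pearson correlations among stack layers
#'
#' Computed over the cells where every layer has data (the masked
#' calibration area). Constant layers get `NA` correlations and are
#' flagged.
#'
#' @param stack A `niche_stack` with at least 2 layers.
#' @return List of class `correlation_report`: `r` (symmetric matrix with
#'   unit diagonal), `n_cells`, `constant` (logical per layer).
#' @export
pairwise_correlation <- function(stack) {
  vars <- stack_names(stack)
  if (length(vars) < 2L) stop("need at least 2 layers")
  cells <- data_cells(stack)
  if (length(cells) < 3L) stop("need at least 3 shared data cells")
  env <- stack_env(stack, cells)
  constant <- apply(env, 2L, function(x) sd(x) == 0)
  r <- suppressWarnings(cor(env))
  diag(r) <- 1
  structure(list(r = r, n_cells = length(cells),
                 constant = setNames(constant, vars)),
            class = "correlation_report")
}

# VIFs of variables from their correlation matrix: VIF_i = 1/(1 - R^2_i)
# regressing i on the others; +Inf under perfect multicollinearity.
vif_from_cor <- function(r) {
  k <- ncol(r)
  if (k < 2L) return(setNames(rep(1, k), colnames(r)))
  prec <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(prec)) return(setNames(rep(Inf, k), colnames(r)))
  vifs <- diag(prec)
  vifs[!is.finite(vifs) | vifs <= 0] <- Inf
  setNames(vifs, colnames(r))
}

#' Iterative correlation / VIF pruning
#'
#' Repeatedly finds the pair of currently kept variables with the maximum
#' absolute Pearson correlation; while that correlation reaches
#' `r_threshold`, the member of the pair with the larger variance inflation
#' factor (computed against all currently kept variables) is dropped.
#' Equal VIFs drop the variable later in input order. Ends when the
#' maximum remaining |r| is below the threshold.
#'
#' @param stack A `niche_stack`.
#' @param r_threshold Correlation threshold (default 0.7).
#' @return List: `kept` (names), `report` (a `correlation_report` whose
#'   `steps` data frame logs each exclusion: pair, |r|, both VIFs, dropped
#'   variable).
#' @export
vifcor_prune <- function(stack, r_threshold = 0.7) {
  rep0 <- pairwise_correlation(stack)
  kept <- stack_names(stack)
  order_in <- setNames(seq_along(kept), kept)
  steps <- list()
  repeat {
    if (length(kept) < 2L) break
    r <- rep0$r[kept, kept]
    ra <- abs(r); diag(ra) <- 0
    ra[is.na(ra)] <- 0
    mx <- max(ra)
    if (mx < r_threshold) break
    idx <- which(ra == mx, arr.ind = TRUE)[1L, ]
    pair <- kept[idx]
    vifs <- vif_from_cor(r)
    v1 <- vifs[pair[1L]]; v2 <- vifs[pair[2L]]
    drop <- if (is.na(v1) || is.na(v2)) {
      pair[which.max(order_in[pair])]
    } else if (v1 > v2) pair[1L] else if (v2 > v1) pair[2L] else {
      pair[which.max(order_in[pair])]
    }
    steps[[length(steps) + 1L]] <-
      data.frame(var_a = pair[1L], var_b = pair[2L], abs_r = mx,
                 vif_a = unname(v1), vif_b = unname(v2), dropped = drop)
    kept <- setdiff(kept, drop)
  }
  report <- rep0
  report$steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(var_a = character(), var_b = character(), abs_r = numeric(),
               vif_a = numeric(), vif_b = numeric(), dropped = character())
  list(kept = kept, report = report)
}

#' Contribution-based predictor pruning
#'
#' Fits a preliminary model `runs` times (default feature classes lqph,
#' rm = 1) with a different background seed each run, averages the
#' per-variable percent contributions, and drops variables whose mean
#' contribution does not exceed `threshold_pct`.
#'
#' @param presences An `occurrence_table` (or lon/lat data frame).
#' @param stack A masked calibration `niche_stack`.
#' @param threshold_pct Exclusion threshold in percent (default 1).
#' @param runs Number of preliminary runs (default 10).
#' @param seed Base RNG seed; run `i` uses `seed + i`.
#' @param background_max Background cap per run (default 10,000).
#' @param min_presences Minimum presence records required (default 10).
#' @param spec Preliminary model specification.
#' @param n_knots Hinge knots per variable per direction.
#' @return List: `kept` (names), `report` (data frame of per-run and mean
#'   contributions with a `dropped` flag).
#' @export
contribution_prune <- function(presences, stack, threshold_pct = 1,
                               runs = 10, seed = 1, background_max = 10000,
                               min_presences = 10,
                               spec = feature_spec(c("l", "q", "p", "h"), 1),
                               n_knots = 50) {
  presences <- occurrence_table(presences)
  cells <- cell_index(stack$grid, presences$lon, presences$lat)
  cells <- cells[!is.na(cells)]
  cells <- cells[cells %in% data_cells(stack)]
  if (length(cells) < min_presences) {
    stop("need at least ", min_presences, " presence records with data")
  }
  pres_env <- stack_env(stack, cells)
  vars <- stack_names(stack)
  if (length(vars) == 1L) {
    rep1 <- data.frame(variable = vars, mean_contribution = 100,
                       dropped = FALSE)
    return(list(kept = vars, report = rep1))
  }
  contrib <- matrix(NA_real_, runs, length(vars),
                    dimnames = list(NULL, vars))
  for (i in seq_len(runs)) {
    bg <- sample_background(stack, background_max, seed = seed + i)
    model <- fit_maxent(pres_env, stack_env(stack, bg), spec,
                        n_knots = n_knots)
    contrib[i, ] <- percent_contribution(model)[vars]
  }
  means <- colMeans(contrib)
  dropped <- means <= threshold_pct
  if (all(dropped)) {
    stop("all variables fell at or below the contribution threshold (",
         threshold_pct, "%); review the threshold")
  }
  report <- data.frame(variable = vars, mean_contribution = means,
                       dropped = dropped, row.names = NULL)
  report <- cbind(report, setNames(as.data.frame(t(contrib)),
                                   paste0("run_", seq_len(runs))))
  list(kept = vars[!dropped], report = report)
}
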