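#' Feature-class specification for a maximum-entropy model
#'
#' @param classes Character vector, nonempty subset of
#'   `c("l","q","p","h")`: linear, quadratic, product and hinge features.
#' @param rm Regularization multiplier (> 0) scaling all per-feature L1
#'   penalties; larger values give sparser, smoother models.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("l", "q", "h"), rm = 1) {
  classes <- unique(match.arg(classes, c("l", "q", "p", "h"),
                              several.ok = TRUE))
  if (!length(classes)) stop("at least one feature class is required")
  if (!is.numeric(rm) || length(rm) != 1L || rm <= 0) stop("rm must be > 0")
  structure(list(classes = classes, rm = rm), class = "feature_spec")
}

#' Build the feature map for a predictor set
#'
#' Scaling bounds come from the calibration (background) data; hinge knots
#' sit at background quantiles, strictly inside each variable's range.
#' Feature definitions (x scaled to s = (x - min)/(max - min)):
#' linear s; quadratic s^2; product s_i * s_j (all pairs); forward hinge at
#' knot k: clamp((x - k)/(max - k), 0, 1); reverse hinge:
#' clamp((k - x)/(k - min), 0, 1). All features lie in `[0,1]` on
#' calibration data. Constant variables contribute only a flagged all-zero
#' linear feature.
#'
#' @param bg_env Background matrix (cells x variables, named columns).
#' @param classes Feature classes as in [feature_spec()].
#' @param n_knots Hinge knots per variable per direction (default 50).
#' @return A list of class `feature_map`.
#' @export
build_feature_map <- function(bg_env, classes = c("l", "q", "h"),
                              n_knots = 50) {
  bg_env <- as.matrix(bg_env)
  if (is.null(colnames(bg_env))) {
    colnames(bg_env) <- paste0("v", seq_len(ncol(bg_env)))
  }
  if (nrow(bg_env) == 0L) stop("background sample is empty")
  if (any(!is.finite(bg_env))) stop("background contains non-finite values")
  vars <- colnames(bg_env)
  lower <- apply(bg_env, 2L, min)
  upper <- apply(bg_env, 2L, max)
  constant <- upper - lower <= 0
  if (any(constant)) {
    warning("constant variable(s): ", paste(vars[constant], collapse = ", "),
            "; emitting zero linear feature only")
  }
  feats <- list(data.frame(class = "l", var1 = vars, var2 = NA, knot = NA,
                           dir = NA, stringsAsFactors = FALSE))
  live <- vars[!constant]
  if ("q" %in% classes && length(live)) {
    feats <- c(feats, list(data.frame(class = "q", var1 = live, var2 = NA,
                                      knot = NA, dir = NA)))
  }
  if ("p" %in% classes && length(live) >= 2L) {
    prs <- combn(live, 2L)
    feats <- c(feats, list(data.frame(class = "p", var1 = prs[1L, ],
                                      var2 = prs[2L, ], knot = NA, dir = NA)))
  }
  knots <- list()
  if ("h" %in% classes && length(live)) {
    for (v in live) {
      k <- unique(quantile(bg_env[, v], probs = seq_len(n_knots) / (n_knots + 1),
                           names = FALSE, type = 7))
      k <- k[k > lower[v] & k < upper[v]]
      knots[[v]] <- k
      if (length(k)) {
        feats <- c(feats,
                   list(data.frame(class = "h", var1 = v, var2 = NA, knot = k,
                                   dir = "fwd"),
                        data.frame(class = "h", var1 = v, var2 = NA, knot = k,
                                   dir = "rev")))
      }
    }
  }
  features <- do.call(rbind, feats)
  features$name <- with(features, ifelse(
    class == "l", paste0("l:", var1),
    ifelse(class == "q", paste0("q:", var1),
           ifelse(class == "p", paste0("p:", var1, "*", var2),
                  paste0("h", dir, ":", var1, "@", signif(knot, 8))))))
  rownames(features) <- NULL
  structure(list(vars = vars, lower = lower, upper = upper,
                 constant = constant, classes = classes, knots = knots,
                 features = features),
            class = "feature_map")
}

#' Evaluate the feature matrix at environmental values
#'
#' @param fm A `feature_map`.
#' @param env Matrix (points x variables) covering all `fm$vars`.
#' @param clamp Clip each variable to its calibration range before feature
#'   evaluation (the projection-time clamping rule). Default FALSE: on
#'   calibration data clamping is a no-op, and leaving it off lets linear
#'   features extrapolate.
#' @return Numeric matrix, one column per feature.
#' @export
feature_matrix <- function(fm, env, clamp = FALSE) {
  env <- as.matrix(env)
  miss <- setdiff(fm$vars, colnames(env))
  if (length(miss)) stop("env lacks model variables: ",
                         paste(miss, collapse = ", "))
  env <- env[, fm$vars, drop = FALSE]
  if (any(!is.finite(env))) {
    bad <- which(!is.finite(env), arr.ind = TRUE)
    stop(sprintf("non-finite value for variable '%s' at row %d",
                 fm$vars[bad[1L, 2L]], bad[1L, 1L]))
  }
  if (clamp) {
    for (v in fm$vars) {
      env[, v] <- pmin(pmax(env[, v], fm$lower[v]), fm$upper[v])
    }
  }
  rng <- fm$upper - fm$lower
  scaled <- sweep(sweep(env, 2L, fm$lower, "-"), 2L, ifelse(rng > 0, rng, 1),
                  "/")
  scaled[, fm$constant] <- 0
  ft <- fm$features
  out <- matrix(0, nrow(env), nrow(ft), dimnames = list(NULL, ft$name))
  for (i in seq_len(nrow(ft))) {
    v <- ft$var1[i]
    out[, i] <- switch(ft$class[i],
      l = scaled[, v],
      q = scaled[, v]^2,
      p = scaled[, v] * scaled[, ft$var2[i]],
      h = {
        k <- ft$knot[i]
        if (ft$dir[i] == "fwd") {
          pmin(pmax((env[, v] - k) / (fm$upper[v] - k), 0), 1)
        } else {
          pmin(pmax((k - env[, v]) / (k - fm$lower[v]), 0), 1)
        }
      })
  }
  out
}

# Published per-class default regularization schedules: interpolation
# tables of sample size -> base penalty (hinge uses a constant 0.5 floor).
beta_class_tables <- list(
  l = list(m = c(10, 30, 100), b = c(1, 0.2, 0.05)),
  q = list(m = c(0, 10, 17, 30, 100), b = c(1.3, 0.8, 0.5, 0.25, 0.05)),
  p = list(m = c(0, 10, 17, 30, 100), b = c(2.6, 1.6, 0.9, 0.55, 0.05)),
  h = list(m = c(0, 100), b = c(0.5, 0.5))
)

beta_class <- function(class, m) {
  tab <- beta_class_tables[[class]]
  approx(tab$m, tab$b, xout = m, rule = 2)$y
}

# Per-feature penalties: beta_j = rm * beta_class(m) * s_j / sqrt(m), where
# s_j is the feature's standard deviation over presences (background sd as
# fallback for zero-variance presence features).
feature_penalties <- function(fm, Fp, Fb, rm) {
  m <- nrow(Fp)
  s <- apply(Fp, 2L, sd)
  if (m < 2L) s[] <- 0
  zero <- !is.finite(s) | s == 0
  if (any(zero)) s[zero] <- apply(Fb[, zero, drop = FALSE], 2L, sd)
  s[!is.finite(s) | s == 0] <- 1e-6
  bcs <- vapply(fm$features$class, beta_class, numeric(1L), m = m)
  pmax(rm * bcs * s / sqrt(m), 1e-8)
}
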