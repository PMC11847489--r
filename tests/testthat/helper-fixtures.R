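# Shared fixtures and independent oracles, built in code at test time.

# small all-data stack of seeded random layers on a 1-degree toy grid
toy_stack <- function(seed = 1, n = 6, vars = 3, cell_size = 1,
                      origin_lat = 3) {
  g <- grid_spec(0, origin_lat, cell_size, n, n)
  set.seed(seed)
  layers <- lapply(seq_len(vars), function(i) {
    raster_layer(g, matrix(rnorm(n * n), n, n), name = paste0("x", i))
  })
  align_stack(layers)
}

# compact synthetic landscape for model-level tests
small_landscape <- function(seed = 1, n = 60, n_vars = 5) {
  make_landscape(landscape_config(n_rows = n, n_cols = n, smoothness = 5,
                                  n_vars = n_vars, seed = seed))
}

# O(n^2) pair-counting AUC oracle
bf_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exhaustive maximum independent set size under a min-distance constraint
bf_thin_max_size <- function(lon, lat, min_km) {
  n <- length(lon)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    nichecast:::haversine_km(lon[i], lat[i], lon[j], lat[j])
  })
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1L) {
      dd <- d[idx, idx]
      ok <- all(dd[upper.tri(dd)] >= min_km)
    }
    if (ok) best <- length(idx)
  }
  best
}

# exhaustive threshold scan oracle for maximum sens + spec
bf_mtss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  tot <- vapply(cand, function(t) mean(pres >= t) + mean(bg < t), 0)
  mx <- max(tot)
  list(threshold = cand[which(tot == mx)[1L]], total = mx)
}

# independent penalized-objective solver: split lambda = a - b, a,b >= 0,
# smooth objective + beta * (a + b), solved with L-BFGS-B
oracle_fit_lambda <- function(Fp, Fb, beta) {
  p <- ncol(Fp)
  fbar <- colMeans(Fp)
  obj <- function(par) {
    lam <- par[1:p] - par[(p + 1):(2 * p)]
    eta <- drop(Fb %*% lam)
    -sum(lam * fbar) + log(sum(exp(eta))) + sum(beta * (par[1:p] +
                                                          par[(p + 1):(2 * p)]))
  }
  fit <- optim(rep(0, 2 * p), obj, method = "L-BFGS-B",
               lower = rep(0, 2 * p),
               control = list(maxit = 2000, factr = 1e4))
  fit$par[1:p] - fit$par[(p + 1):(2 * p)]
}
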