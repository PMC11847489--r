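test_that("feature map evaluates the documented basis functions", {
  bg <- cbind(x = c(0, 2, 4, 6, 8, 10), y = c(1, 1, 2, 3, 5, 9))
  fm <- build_feature_map(bg, classes = c("l", "q", "p", "h"), n_knots = 3)
  env <- cbind(x = c(0, 10, 5), y = c(1, 9, 5))
  Fx <- feature_matrix(fm, env)
  expect_equal(Fx[, "l:x"], c(0, 1, 0.5))          # min -> 0, max -> 1
  expect_equal(Fx[, "q:x"], c(0, 1, 0.25))          # scaled 0.5 squared
  expect_equal(Fx[, "p:x*y"], Fx[, "l:x"] * Fx[, "l:y"])
  expect_true(all(Fx >= 0 & Fx <= 1))
  # forward hinge is 0 exactly at its knot, 1 at the variable max
  k <- fm$knots$x[1]
  col <- paste0("hfwd:x@", signif(k, 8))
  expect_equal(feature_matrix(fm, cbind(x = k, y = 1))[, col], 0,
               ignore_attr = TRUE)
  expect_equal(feature_matrix(fm, cbind(x = 10, y = 1))[, col], 1,
               ignore_attr = TRUE)
})

test_that("constant variables are flagged and excluded from q/p/h", {
  bg <- cbind(a = rnorm(30), k = rep(2, 30))
  expect_warning(fm <- build_feature_map(bg, c("l", "q", "h"), n_knots = 5),
                 "constant")
  expect_true(fm$constant[["k"]])
  expect_false(any(fm$features$var1 == "k" & fm$features$class != "l"))
  Fx <- feature_matrix(fm, bg)
  expect_true(all(Fx[, "l:k"] == 0))
})

test_that("a dominant penalty drives all coefficients to the uniform model", {
  set.seed(1)
  bg <- cbind(a = rnorm(200), b = rnorm(200))
  pres <- bg[1:20, ]
  m <- fit_maxent(pres, bg, feature_spec(c("l", "q"), 1e6))
  expect_true(all(m$lambda == 0))
  expect_equal(unname(raw_output(m, bg)), rep(1 / 200, 200))
  expect_equal(m$entropy, log(200), tolerance = 1e-9)
  # uniform model: cloglog = 1 - exp(-1) everywhere
  expect_equal(unique(round(cloglog_output(m, bg), 10)), 1 - exp(-1),
               tolerance = 1e-9)
})

test_that("raw output normalizes over background and cloglog is monotone", {
  set.seed(2)
  bg <- cbind(a = rnorm(300), b = runif(300))
  pres <- bg[order(bg[, "a"], decreasing = TRUE)[1:30], ]
  m <- fit_maxent(pres, bg, feature_spec(c("l", "q", "h"), 1), n_knots = 10)
  q <- raw_output(m, bg)
  expect_equal(sum(q), 1, tolerance = 1e-8)
  cl <- cloglog_output(m, bg)
  expect_true(all(cl >= 0 & cl <= 1))
  ord <- order(q)
  expect_true(all(diff(cl[ord]) >= 0))
  # informative variable gets positive weight under an l-only spec
  ml <- fit_maxent(pres, bg, feature_spec("l", 1))
  expect_gt(ml$lambda[["l:a"]], 0)
})

test_that("coordinate descent matches an independent convex solver", {
  set.seed(3)
  for (trial in 1:3) {
    bg <- cbind(a = rnorm(150), b = rnorm(150))
    pres <- bg[sample.int(150, 25, prob = exp(bg[, "a"] - 0.5 * bg[, "b"])), ]
    m <- fit_maxent(pres, bg, feature_spec("l", 1), tol = 1e-10,
                    max_iter = 5000)
    fm <- m$feature_map
    Fp <- feature_matrix(fm, pres); Fb <- feature_matrix(fm, bg)
    oracle <- oracle_fit_lambda(Fp, Fb, m$beta)
    expect_equal(unname(m$lambda), oracle, tolerance = 1e-4)
  }
})

test_that("total |lambda| shrinks as the regularization multiplier grows", {
  set.seed(4)
  bg <- cbind(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  pres <- bg[sample.int(200, 40, prob = exp(bg[, "a"])), ]
  totals <- vapply(c(0.5, 1, 2, 4), function(rm) {
    sum(abs(fit_maxent(pres, bg, feature_spec(c("l", "q"), rm))$lambda))
  }, 0)
  expect_true(all(diff(totals) <= 1e-8))
})

test_that("AUC equals brute-force pair counting, including ties", {
  set.seed(5)
  for (i in 1:5) {
    pos <- sample(seq(0, 1, 0.25), 5, replace = TRUE)
    neg <- sample(seq(0, 1, 0.25), 5, replace = TRUE)
    expect_equal(auc_mw(pos, neg), bf_auc(pos, neg))
  }
  expect_equal(auc_mw(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_mw(c(1, 2, 3), c(1, 2, 3)), 0.5)
})

test_that("importance measures are normalized and identify the driver", {
  ls <- small_landscape(seed = 31, n = 50, n_vars = 3)
  truth <- true_suitability(ls$truth, ls$stack)
  occ <- sample_occurrences(truth, 200, seed = 32)
  cells <- cell_index(ls$stack$grid, occ$lon, occ$lat)
  bg <- sample_background(ls$stack, 1500, seed = 33)
  m <- fit_maxent(stack_env(ls$stack, cells), stack_env(ls$stack, bg),
                  feature_spec(c("l", "q"), 1))
  pc <- percent_contribution(m)
  pi <- permutation_importance(m, seed = 1)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_equal(sum(pi), 100, tolerance = 1e-6)
  expect_true(all(pc >= 0) && all(pi >= 0))
  expect_gt(pc[["v1"]] + pc[["v2"]], 50)
  expect_lt(pc[["v3"]], 5)
})

test_that("jackknife gains behave like restricted optima", {
  ls <- small_landscape(seed = 41, n = 40, n_vars = 3)
  truth <- true_suitability(ls$truth, ls$stack)
  occ <- sample_occurrences(truth, 150, seed = 42)
  cells <- cell_index(ls$stack$grid, occ$lon, occ$lat)
  bg <- sample_background(ls$stack, 1000, seed = 43)
  m <- fit_maxent(stack_env(ls$stack, cells), stack_env(ls$stack, bg),
                  feature_spec(c("l", "q"), 1))
  jk <- jackknife_gains(m)
  # removing features cannot raise the penalized optimum
  expect_true(all(jk$gain_without <= m$gain + 1e-9))
  # informative variables carry more solo gain than the noise variable
  expect_gt(max(jk$gain_only[jk$variable %in% c("v1", "v2")]),
            jk$gain_only[jk$variable == "v3"])

  # twin variables: removing either alone barely moves the gain
  env_bg <- stack_env(ls$stack, bg)
  env_tw <- cbind(env_bg[, c("v1", "v2")], v1b = env_bg[, "v1"])
  env_pr <- stack_env(ls$stack, cells)
  env_ptw <- cbind(env_pr[, c("v1", "v2")], v1b = env_pr[, "v1"])
  mt <- fit_maxent(env_ptw, env_tw, feature_spec("l", 1))
  jt <- jackknife_gains(mt)
  expect_lt(mt$gain - jt$gain_without[jt$variable == "v1"],
            0.01 * max(mt$gain, 1e-9))
})

test_that("response curves span the calibration range and flatten when uniform", {
  set.seed(6)
  bg <- cbind(a = rnorm(150), b = rnorm(150))
  m0 <- fit_maxent(bg[1:20, ], bg, feature_spec("l", 1e6))
  rc <- response_curve(m0, "a", n_points = 25)
  expect_equal(nrow(rc), 25)
  expect_equal(diff(range(rc$cloglog)), 0)
  expect_equal(rc$sd, rep(0, 25))
  expect_equal(range(rc$value), unname(c(m0$feature_map$lower["a"],
                                         m0$feature_map$upper["a"])))
  expect_error(response_curve(m0, "zz"), "not in model")

  # unimodal truth in the niche axis: curve argmax near the true optimum
  ls <- small_landscape(seed = 51, n = 50, n_vars = 2)
  truth <- true_suitability(ls$truth, ls$stack)
  occ <- sample_occurrences(truth, 250, seed = 52)
  cells <- cell_index(ls$stack$grid, occ$lon, occ$lat)
  bg2 <- sample_background(ls$stack, 1500, seed = 53)
  m <- fit_maxent(stack_env(ls$stack, cells), stack_env(ls$stack, bg2),
                  feature_spec(c("l", "q", "h"), 1), n_knots = 20)
  rc2 <- response_curve(m, "v2", n_points = 200)
  argmax <- rc2$value[which.max(rc2$cloglog)]
  expect_lt(abs(argmax - ls$truth$optimum_v2), 0.1 * diff(range(rc2$value)))
})

test_that("bootstrap replicates are seeded, bounded and averaged cellwise", {
  ls <- small_landscape(seed = 61, n = 40, n_vars = 2)
  truth <- true_suitability(ls$truth, ls$stack)
  occ <- sample_occurrences(truth, 120, seed = 62)
  cells <- cell_index(ls$stack$grid, occ$lon, occ$lat)
  bg <- sample_background(ls$stack, 800, seed = 63)
  pres_env <- stack_env(ls$stack, cells)
  bg_env <- stack_env(ls$stack, bg)

  one <- replicate_fit(pres_env, bg_env, feature_spec("l", 1), n = 1,
                       seed = 9, stack = ls$stack)
  single <- suitability_raster(one$models[[1]], ls$stack)
  expect_equal(one$mean$values, single$values)
  expect_true(all(one$sd$values[!is.na(one$sd$values)] == 0))

  reps <- replicate_fit(pres_env, bg_env, feature_spec(c("l", "q"), 1),
                        n = 4, seed = 10, stack = ls$stack)
  reps2 <- replicate_fit(pres_env, bg_env, feature_spec(c("l", "q"), 1),
                         n = 4, seed = 10, stack = ls$stack)
  expect_equal(reps$mean$values, reps2$mean$values)
  expect_true(all(reps$sd$values[!is.na(reps$sd$values)] >= 0))
  arr <- vapply(reps$models, function(m) {
    suitability_raster(m, ls$stack)$values
  }, matrix(0, 40, 40))
  ok <- !is.na(reps$mean$values)
  expect_true(all(reps$mean$values[ok] >=
                    apply(arr, c(1, 2), min)[ok] - 1e-12))
  expect_true(all(reps$mean$values[ok] <=
                    apply(arr, c(1, 2), max)[ok] + 1e-12))
})

test_that("model JSON serialization captures the fitted state", {
  set.seed(7)
  bg <- cbind(a = rnorm(100), b = rnorm(100))
  m <- fit_maxent(bg[1:15, ], bg, feature_spec("l", 1))
  path <- file.path(tempdir(), "model.json")
  write_model_json(m, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$entropy, m$entropy)
  expect_equal(unlist(doc$lambda), m$lambda)
})
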