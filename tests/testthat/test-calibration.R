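test_that("candidate grid combinatorics follow the RM x FC cross product", {
  expect_equal(nrow(generate_candidates()), 120)
  expect_equal(nrow(generate_candidates(rm_values = 1)), 15)
  expect_equal(nrow(generate_candidates(rm_values = c(1, 2, 3),
                                        classes = c("l", "q"))), 9)
  cands <- generate_candidates()
  expect_false(anyDuplicated(cands$id) > 0)
  expect_true("M_4_F_h_Set_1" %in% cands$id)
  expect_error(generate_candidates(rm_values = numeric()))
})

test_that("occurrence splitting is disjoint, complete and seeded", {
  tab <- data.frame(lon = 1:10, lat = 1:10, year = 2000)
  sp <- split_occurrences(tab, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_equal(nrow(rbind(sp$train, sp$test)), 10)
  expect_length(intersect(paste(sp$train$lon), paste(sp$test$lon)), 0)
  sp2 <- split_occurrences(tab, 0.7, seed = 4)
  expect_identical(sp$train$lon, sp2$train$lon)
  expect_error(split_occurrences(tab[1:3, ], 0.7), "at least 4")
  expect_error(split_occurrences(tab, 1.0), "empty")
})

test_that("omission rate follows the inclusive E-quantile convention", {
  train <- seq(0.1, 1, by = 0.1)
  # E = 0.05, n = 10: tau is the 1st smallest training score (0.1)
  expect_equal(omission_rate(train, c(0.05, 0.5), E = 0.05), 0.5)
  # E = 0: tau = min; test scores equal to training scores are never omitted
  expect_equal(omission_rate(train, train, E = 0), 0)
  # all test below all train
  expect_equal(omission_rate(train, c(0.01, 0.02), E = 0.05), 1)
  # monotone non-decreasing in E
  set.seed(8)
  tr <- runif(50); te <- runif(30)
  rates <- vapply(c(0, 0.05, 0.1, 0.2, 0.5), function(E) {
    omission_rate(tr, te, E)
  }, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("partial ROC is exact on the null line and significant on signal", {
  # the 1:1 null evaluated against itself gives ratio exactly 1
  x <- seq(0, 1, length.out = 201)
  expect_equal(nichecast:::partial_auc_ratio(x, x, 0.05), 1,
               tolerance = 1e-12)

  # test points drawn from the raster's own value distribution: ratio ~ 1
  set.seed(9)
  raster_vals <- runif(4000)
  null_scores <- sample(raster_vals, 200, replace = TRUE)
  pr_null <- partial_roc(null_scores, raster_vals, iterations = 300,
                         seed = 2)
  expect_lt(abs(pr_null$mean_auc_ratio - 1), 0.1)

  # informative scores: p < 0.05
  good_scores <- sort(raster_vals, decreasing = TRUE)[1:150]
  pr_sig <- partial_roc(good_scores, raster_vals, iterations = 500,
                        seed = 3)
  expect_lt(pr_sig$p_value, 0.05)
  expect_gt(pr_sig$mean_auc_ratio, 1)

  # degenerate constant raster
  pr_deg <- partial_roc(c(0.5, 0.5), rep(0.5, 100), iterations = 10)
  expect_true(pr_deg$degenerate)
  expect_equal(pr_deg$p_value, 1)
})

test_that("AICc matches the direct formula and long-hand standardization", {
  # k = 2, n = 10, lnL = -5: AIC = 14, AICc = 14 + 12/7
  k <- 2; n <- 10; lnL <- -5
  expect_equal(2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
               14 + 12 / 7)

  # 3-cell toy raster with hand-set lambdas vs manual standardization
  g <- grid_spec(0, 3, 1, 1, 3)
  st <- align_stack(list(raster_layer(g, matrix(c(1, 2, 3), 1, 3), "a")))
  bg <- stack_env(st, data_cells(st))
  m <- fit_maxent(rbind(bg, bg[1:2, , drop = FALSE]), bg,
                  feature_spec("l", 1))
  m$lambda[] <- 0.7   # hand-set coefficient
  occ_cells <- data_cells(st)[c(1, 3)]
  out <- aicc(m, st, occ_cells)
  eta <- 0.7 * (bg[, "a"] - 1) / 2            # scaled linear feature
  p <- exp(eta) / sum(exp(eta))
  expect_equal(out$lnL, log(p[1]) + log(p[3]), tolerance = 1e-12)
  expect_equal(out$k, 1)
  # n = 2 = k + 1: correction denominator hits zero -> undefined
  expect_true(is.na(out$aicc))

  # defined case: n > k + 1
  out2 <- aicc(m, st, data_cells(st)[c(1, 2, 3, 3, 1)])
  expect_equal(out2$aicc,
               2 * 1 - 2 * out2$lnL + 2 * 1 * 2 / (5 - 1 - 1))
})

test_that("three-criterion selection matches a brute-force filter", {
  set.seed(10)
  n <- 40
  results <- data.frame(id = paste0("c", 1:n),
                        p_value = runif(n, 0, 0.2),
                        omission_rate = runif(n, 0, 0.15),
                        aicc = runif(n, 100, 140))
  crit <- selection_criteria(alpha = 0.05, E = 0.05, d_aicc_max = 2)
  out <- select_candidates(results, crit)

  sig <- results$p_value <= 0.05
  om <- results$omission_rate <= 0.05
  pool <- sig & om
  ref <- min(results$aicc[pool])
  manual_sel <- sig & om & (results$aicc - ref <= 2)
  expect_equal(out$selected, manual_sel)
  expect_true(all(out$delta_aicc >= 0))
  expect_equal(min(out$delta_aicc[pool]), 0)
  # selected implies all three flags
  expect_true(all(!out$selected |
                    (out$significant & out$meets_omission & out$meets_aicc)))

  # all-nonsignificant table: warning, none selected
  bad <- transform(results, p_value = 0.5)
  expect_warning(out2 <- select_candidates(bad, crit), "none selected")
  expect_false(any(out2$selected))

  # a single candidate passing the first two criteria has delta 0, selected
  one <- data.frame(id = "only", p_value = 0.01, omission_rate = 0,
                    aicc = 123)
  out3 <- select_candidates(one, crit)
  expect_equal(out3$delta_aicc, 0)
  expect_true(out3$selected)
})

test_that("candidate evaluation selects a sound model on synthetic data", {
  ls <- small_landscape(seed = 71, n = 50, n_vars = 3)
  truth <- true_suitability(ls$truth, ls$stack)
  occ <- deduplicate(sample_occurrences(truth, 260, seed = 72),
                     ls$stack$grid)
  sp <- split_occurrences(occ, 0.7, seed = 73)
  cands <- generate_candidates(rm_values = c(1, 4),
                               classes = c("l", "q"))
  ev <- suppressWarnings(
    evaluate_candidates(cands, sp$train, sp$test, ls$stack,
                        selection_criteria(), background_max = 1200,
                        seed = 74, n_knots = 10, proc_iterations = 200))
  res <- ev$results
  expect_equal(nrow(res), 6)
  # a real model fitted to real signal is always significant here
  expect_true(all(res$p_value <= 0.05))
  # omission stays within sampling tolerance of E for every candidate
  expect_true(all(res$omission_rate <= 0.05 + 0.06))
  pool <- res$significant & res$meets_omission
  if (any(pool)) {
    expect_equal(min(res$delta_aicc[pool]), 0)
    expect_true(all(res$selected == (pool & res$delta_aicc <= 2)))
  } else {
    expect_false(any(res$selected))
  }
})
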