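test_that("MTSS threshold maximizes sensitivity plus specificity", {
  out <- mtss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(out$threshold, 0.8)
  expect_equal(out$sensitivity + out$specificity, 2)

  # no-signal case: identical multisets reach total 1 at the smallest score
  out2 <- mtss_threshold(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))
  expect_equal(out2$sensitivity + out2$specificity, 1)
  expect_equal(out2$threshold, 0.2)

  # degenerate: all scores identical
  out3 <- mtss_threshold(c(0.4, 0.4), c(0.4, 0.4))
  expect_true(out3$degenerate)
  expect_equal(out3$threshold, 0.4)
})

test_that("MTSS equals an exhaustive scan on many random instances", {
  set.seed(14)
  for (i in 1:120) {
    pres <- round(runif(sample(2:15, 1)), 2)
    bg <- round(runif(sample(2:25, 1)), 2)
    got <- mtss_threshold(pres, bg)
    want <- bf_mtss(pres, bg)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sensitivity + got$specificity, want$total)
  }
})

test_that("binarization counts and preserves nodata", {
  g <- grid_spec(0, 3, 1, 3, 3)
  vals <- matrix(seq(0.1, 0.9, by = 0.1), 3, 3)
  lay <- raster_layer(g, vals, "s")
  expect_equal(sum(binarize(lay, 0.5)$values), 5)  # 0.5..0.9 inclusive
  expect_equal(sum(binarize(lay, 0)$values), 9)
  expect_equal(sum(binarize(lay, 0.95)$values), 0)
  vals[1, 1] <- NA
  lay2 <- raster_layer(g, vals, "s")
  expect_true(is.na(binarize(lay2, 0.5)$values[1, 1]))
})

test_that("change maps partition cells and summaries conserve area", {
  g <- grid_spec(0, 10, 1, 2, 5)   # 10-cell toy
  cur <- raster_layer(g, matrix(c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0), 2, 5), "c")
  fut <- raster_layer(g, matrix(c(1, 1, 1, 1, 0, 0, 1, 1, 0, 0), 2, 5), "f")
  cm <- change_map(cur, fut)
  expect_equal(sum(cm$values == 3), 4)  # maintained
  expect_equal(sum(cm$values == 1), 2)  # lost
  expect_equal(sum(cm$values == 2), 2)  # gained
  areas <- cell_areas(g)
  cs <- change_summary(cm, areas)
  expect_equal(cs$maintained_km2 + cs$lost_km2, cs$total_current_km2,
               tolerance = 1e-6)
  expect_equal(cs$maintained_km2 + cs$gained_km2, cs$total_future_km2,
               tolerance = 1e-6)
  # equal-area cells at these latitudes are nearly uniform; pct_lost ~ 2/6
  expect_equal(cs$pct_lost, 100 * cs$lost_km2 / cs$total_current_km2)
  expect_equal(cs$pct_lost, 33.3, tolerance = 0.2)

  # identical maps: nothing changes
  cs0 <- change_summary(change_map(cur, cur), areas)
  expect_equal(cs0$lost_km2, 0)
  expect_equal(cs0$gained_km2, 0)
  expect_equal(cs0$total_change_pct, 0)

  expect_error(change_map(cur, raster_layer(grid_spec(0, 10, 1, 5, 2),
                                            matrix(1, 5, 2), "x")),
               "different grids")
})

test_that("published habitat-change percentages reproduce from printed areas", {
  tab <- read.csv(system.file("extdata", "habitat_change_published.csv",
                              package = "nichecast"))
  current <- 322114
  for (i in seq_len(nrow(tab))) {
    cs <- change_summary_from_areas(current, tab$total_km2[i],
                                    tab$maintained_km2[i],
                                    tab$gained_km2[i], tab$lost_km2[i])
    expect_equal(round(cs$pct_maintained, 1), tab$pct_maintained[i],
                 info = tab$scenario[i])
    expect_equal(round(cs$pct_gained, 1), tab$pct_gained[i],
                 info = tab$scenario[i])
    expect_equal(round(cs$pct_lost, 1), tab$pct_lost[i],
                 info = tab$scenario[i])
    expect_equal(round(cs$total_change_pct, 1), tab$total_change_pct[i],
                 info = tab$scenario[i])
  }
})

test_that("published protected-area percentages reproduce from printed areas", {
  tab <- read.csv(system.file("extdata", "mpa_overlap_published.csv",
                              package = "nichecast"))
  current_total <- 322114
  current_inside <- tab$inside_km2[tab$period == "current"]
  for (i in seq_len(nrow(tab))) {
    ov <- overlap_summary_from_areas(tab$inside_km2[i], tab$outside_km2[i],
                                     current_total,
                                     current_inside_km2 = current_inside)
    expect_equal(round(ov$pct_inside, 1), tab$pct_inside[i],
                 info = tab$scenario[i])
    expect_equal(round(ov$pct_outside, 1), tab$pct_outside[i],
                 info = tab$scenario[i])
    if (tab$period[i] != "current") {
      expect_equal(ov$change_inside_km2, tab$change_inside_km2[i],
                   info = tab$scenario[i])
      expect_equal(round(ov$change_inside_pct, 1), tab$change_inside_pct[i],
                   info = tab$scenario[i])
    }
  }
})

test_that("centroids are area-weighted cell-center means", {
  g <- grid_spec(139, -34, 1, 3, 4)
  vals <- matrix(0, 3, 4)
  vals[2, 2] <- 1
  areas <- cell_areas(g)
  expect_equal(centroid(raster_layer(g, vals, "b"), areas),
               c(lon = 140.5, lat = -35.5))

  # two equal-latitude cells: midpoint by symmetry
  vals2 <- matrix(0, 3, 4); vals2[2, 1] <- 1; vals2[2, 3] <- 1
  expect_equal(centroid(raster_layer(g, vals2, "b"), areas),
               c(lon = 140.5, lat = -35.5))

  # latitude-spanning case equals the explicit weighted mean
  vals3 <- matrix(0, 3, 4); vals3[1, 1] <- 1; vals3[3, 4] <- 1
  ct <- centroid(raster_layer(g, vals3, "b"), areas)
  cells <- which(vals3 == 1)
  cc <- cell_centers(g, cells)
  w <- areas$values[cells]
  expect_equal(ct[["lon"]], sum(w * cc$lon) / sum(w))
  expect_equal(ct[["lat"]], sum(w * cc$lat) / sum(w))

  expect_error(centroid(raster_layer(g, matrix(0, 3, 4), "b"), areas),
               "no suitable cells")
})

test_that("centroid shifts use geodesic distance and initial bearing", {
  same <- shift(c(140, -35), c(140, -35))
  expect_equal(same$distance_km, 0)
  expect_equal(same$bearing_deg, 0)

  eastward <- shift(c(0, 0), c(1, 0))
  expect_equal(eastward$distance_km, 111.32, tolerance = 1e-3)
  expect_equal(eastward$bearing_deg, 90)

  south <- shift(c(140, -30), c(140, -40))
  expect_equal(south$bearing_deg, 180)
})

test_that("protected-area overlap follows the cell-center rule", {
  g <- grid_spec(0, 4, 1, 4, 4)
  vals <- matrix(1, 4, 4)
  bin <- raster_layer(g, vals, "b")
  areas <- cell_areas(g)
  total <- sum(areas$values)

  # polygons covering everything: outside = 0
  all_ov <- mpa_overlap(bin, rect_region(-1, 5, -1, 5), areas, total)
  expect_equal(all_ov$outside_km2, 0)
  expect_equal(all_ov$pct_inside, 100, tolerance = 1e-9)

  # one rectangle: inside set equals a per-cell point-in-polygon oracle
  rect <- rect_region(0.2, 2.2, 1.3, 3.8)
  ov <- mpa_overlap(bin, rect, areas, total)
  cc <- cell_centers(g)
  manual <- cc$lon > 0.2 & cc$lon < 2.2 & cc$lat > 1.3 & cc$lat < 3.8
  expect_equal(ov$inside_km2, sum(areas$values[cc$cell[manual]]),
               tolerance = 1e-9)
  expect_equal(ov$inside_km2 + ov$outside_km2, total, tolerance = 1e-6)

  # change bookkeeping against a current baseline
  ov2 <- mpa_overlap(bin, rect, areas, total, current_inside_km2 = 100)
  expect_equal(ov2$change_inside_km2, ov2$inside_km2 - 100)

  # empty polygon set flagged, all area outside
  empty <- region_polygons(list())
  ov3 <- mpa_overlap(bin, empty, areas, total)
  expect_true(ov3$empty_polygons)
  expect_equal(ov3$inside_km2, 0)
})
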