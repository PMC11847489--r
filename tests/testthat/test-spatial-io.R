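test_that("raster write/read round-trips values, mask and grid", {
  g <- grid_spec(10, -30, 0.5, 10, 10)
  m <- matrix(7, 10, 10)
  m[3, 4] <- NA; m[8, 1] <- NA
  lay <- raster_layer(g, m, name = "const")
  path <- file.path(tempdir(), "const.asc")
  write_raster(lay, path)
  back <- read_raster(path)
  expect_identical(is.na(back$values), is.na(lay$values))
  expect_equal(back$values, lay$values)
  expect_true(nichecast:::grids_identical(back$grid, g))

  # a continuous synthetic layer survives within representation precision
  ls <- small_landscape(seed = 4, n = 20)
  lay2 <- ls$stack$values[[1]]
  l2 <- raster_layer(ls$stack$grid, lay2, name = "v1")
  write_raster(l2, path)
  expect_lt(max(abs(read_raster(path)$values - lay2)), 1e-6)
})

test_that("projected-CRS rasters are refused with the CRS named", {
  g <- grid_spec(0, 1, 1, 2, 2)
  path <- file.path(tempdir(), "proj.asc")
  write_raster(raster_layer(g, matrix(1, 2, 2)), path)
  writeLines('PROJCS["WGS 84 / UTM zone 55S"]', sub("asc$", "prj", path))
  expect_error(read_raster(path), "UTM zone 55S")
  expect_error(read_raster(file.path(tempdir(), "absent.asc")), "no such file")
})

test_that("align_stack unions nodata footprints and validates grids", {
  g <- grid_spec(0, 5, 1, 5, 5)
  a <- matrix(rnorm(25), 5, 5); a[1, 1] <- NA; a[2, 2] <- NA
  b <- matrix(rnorm(25), 5, 5); b[3, 3] <- NA
  st <- align_stack(list(raster_layer(g, a, "a"), raster_layer(g, b, "b")))
  expect_equal(sum(is.na(st$values$a)), 3)  # disjoint masks: 2 + 1
  expect_identical(is.na(st$values$a), is.na(st$values$b))

  one <- align_stack(list(raster_layer(g, a, "a")))
  expect_equal(one$values$a, a)

  g2 <- grid_spec(0, 5, 0.5, 10, 10)
  expect_error(
    align_stack(list(raster_layer(g, a, "a"),
                     raster_layer(g2, matrix(1, 10, 10), "c"))),
    "different grids")
  # aligned inputs pass through unchanged
  st2 <- align_stack(list(raster_layer(g, a, "a"), raster_layer(g, b, "b")))
  keep <- !is.na(st2$values$a)
  expect_equal(st2$values$a[keep], a[keep])
})

test_that("bilinear resampling reproduces a linear field exactly", {
  src <- grid_spec(0, 4, 0.5, 8, 8)
  cc <- cell_centers(src)
  lin <- matrix(2 * cc$lon + 3 * cc$lat, 8, 8)
  tgt <- grid_spec(0.5, 3.5, 0.25, 8, 8)
  res <- nichecast:::resample_bilinear(raster_layer(src, lin, "z"), tgt)
  cc2 <- cell_centers(tgt)
  expect_equal(as.vector(res$values), 2 * cc2$lon + 3 * cc2$lat,
               tolerance = 1e-12)
})

test_that("masking keeps cells by center and is idempotent", {
  g <- grid_spec(0, 4, 1, 4, 4)
  st <- align_stack(list(raster_layer(g, matrix(1:16, 4, 4), "z")))
  left_half <- rect_region(0, 2, 0, 4)
  masked <- mask_to_region(st, left_half)
  expect_equal(sum(!is.na(masked$values$z)), 8)
  again <- mask_to_region(masked, left_half)
  expect_identical(again$values$z, masked$values$z)

  full <- mask_to_region(st, rect_region(-1, 5, -1, 5))
  expect_equal(full$values$z, st$values$z)

  expect_error(mask_to_region(st, rect_region(0.6, 0.9, 0.6, 0.9)),
               "no cell centers")
})

test_that("cell areas match the closed form and zonal integration", {
  # 0.05 deg cell with bottom edge on the equator: ~30.91 km^2
  g <- grid_spec(0, 0.05, 0.05, 1, 1)
  expect_equal(cell_areas(g)$values[1, 1], 30.91, tolerance = 1e-3)

  # cos-latitude scaling: bottom edge at 60S is ~half the equatorial value
  g60 <- grid_spec(0, -59.95, 0.05, 1, 1)
  expect_equal(cell_areas(g60)$values[1, 1] / cell_areas(g)$values[1, 1],
               0.5, tolerance = 2e-3)

  # full-longitude band area equals the analytic zonal band
  gb <- grid_spec(-180, 40, 0.5, 1, 720)
  band <- sum(cell_areas(gb)$values)
  R <- nichecast:::EARTH_RADIUS_KM
  analytic <- 2 * pi * R^2 * (sin(40 * pi / 180) - sin(39.5 * pi / 180))
  expect_equal(band, analytic, tolerance = 1e-6)

  # numerical integration of the spherical surface element on random cells
  set.seed(7)
  for (i in 1:5) {
    lat0 <- runif(1, -80, 80)
    g1 <- grid_spec(runif(1, -170, 170), lat0, 0.05, 1, 1)
    a <- cell_areas(g1)$values[1, 1]
    phi <- seq(deg <- (lat0 - 0.05), lat0, length.out = 2001) * pi / 180
    integrand <- R^2 * cos(phi) * (0.05 * pi / 180)
    num <- nichecast:::trapz(phi, integrand)
    expect_equal(a, num, tolerance = 1e-6)
  }

  # monotone decrease with |latitude| (one hemisphere, no ties)
  gg <- grid_spec(0, 50, 0.5, 100, 1)
  ar <- cell_areas(gg)$values[, 1]
  lat <- abs(nichecast:::row_centers(gg))
  expect_true(all(diff(ar[order(lat)]) < 0))

  expect_error(grid_spec(0, 0, 0.05, 0, 5))
})

test_that("grid metadata survives raster I/O bit-for-bit", {
  g <- grid_spec(112.123456789, -8.987654321, 0.05, 7, 9)
  path <- file.path(tempdir(), "meta.asc")
  write_raster(raster_layer(g, matrix(rnorm(63), 7, 9)), path)
  g2 <- read_raster(path)$grid
  expect_equal(g2$origin_lon, g$origin_lon, tolerance = 1e-12)
  expect_equal(g2$origin_lat, g$origin_lat, tolerance = 1e-12)
  expect_identical(c(g2$n_rows, g2$n_cols), c(7L, 9L))
})

test_that("GeoJSON polygons round-trip with attributes", {
  reg <- region_polygons(list(cbind(c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0)),
                              cbind(c(3, 4, 4, 3, 3), c(3, 3, 5, 5, 3))),
                         attributes = data.frame(name = c("a", "b")))
  path <- file.path(tempdir(), "region.geojson")
  write_region_geojson(reg, path)
  back <- read_region_geojson(path)
  expect_equal(length(back$parts), 2)
  expect_equal(back$attributes$name, c("a", "b"))
  expect_equal(region_contains(back, c(1, 3.5, 6), c(1, 4, 6)),
               c(TRUE, TRUE, FALSE))
})
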