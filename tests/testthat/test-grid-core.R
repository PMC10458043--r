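test_that("ascii grid round-trip preserves spec, values and nodata mask", {
  dir <- withr::local_tempdir()
  cases <- list(
    float3 = tiny_layer(matrix(c(1.25, -3.5, 0.1234567891234, 7, NA, 2,
                                 -9, 4.75, 1e6), 3, 3)),
    int3 = tiny_layer(matrix(as.numeric(1:9), 3, 3), kind = "categorical"),
    one = tiny_layer(matrix(42.5, 1, 1)))
  for (nm in names(cases)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(cases[[nm]], p)
    back <- read_ascii_grid(p, kind = cases[[nm]]$kind)
    expect_true(specs_aligned(back$spec, cases[[nm]]$spec))
    expect_identical(is.na(back$values), is.na(cases[[nm]]$values))
    expect_equal(back$values, cases[[nm]]$values, tolerance = 0)
  }
})

test_that("reading requires a CRS and a well-formed file", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.asc")
  write_ascii_grid(tiny_layer(matrix(1:4, 2, 2)), p)
  file.remove(file.path(dir, "x.prj"))
  expect_error(read_ascii_grid(p), "missing CRS")
  expect_silent(read_ascii_grid(p, crs = "EPSG:3763"))
  expect_error(read_ascii_grid(file.path(dir, "nope.asc")), "not found")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "dx 1", "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p, crs = "x"), "non-square")
})

test_that("nodata sentinel cells come back as the mask", {
  dir <- withr::local_tempdir()
  l <- tiny_layer(matrix(c(1, NA, 3, NA), 2, 2))
  p <- file.path(dir, "nd.asc")
  write_ascii_grid(l, p)
  txt <- readLines(p)
  expect_true(any(grepl("-9999", txt)))
  back <- read_ascii_grid(p)
  expect_identical(which(is.na(back$values)), which(is.na(l$values)))
})

test_that("resample: identity, block_mean and block_mode hand oracles", {
  l <- tiny_layer(matrix(c(1, 5, 3, 7), 2, 2))      # [[1,3],[5,7]]
  expect_equal(resample(l, l$spec, "nearest")$values, l$values)
  coarse <- grid_spec(0, 200, 200, 1, 1, "EPSG:3763")
  expect_equal(resample(l, coarse, "block_mean")$values[1, 1], 4.0)
  lc <- tiny_layer(matrix(c(1, 1, 1, 2), 2, 2), kind = "categorical")
  expect_equal(resample(lc, coarse, "block_mode")$values[1, 1], 1)
  expect_error(resample(lc, coarse, "bilinear"), "categorical")
  expect_error(resample(lc, coarse, "block_mean"), "categorical")
})

test_that("resample never interpolates nodata into valid cells", {
  withr::with_seed(13, v <- matrix(rnorm(16), 4, 4)); v[2, 2] <- NA
  l <- tiny_layer(v)
  coarse <- grid_spec(0, 400, 200, 2, 2, "EPSG:3763")
  out <- resample(l, coarse, "block_mean")
  expect_true(is.na(out$values[1, 1]))     # window holds the NA
  expect_false(anyNA(out$values[2, ]))     # clean windows survive
  fine <- grid_spec(0, 400, 50, 8, 8, "EPSG:3763")
  bi <- resample(l, fine, "bilinear")
  # every bilinear window touching the NA source cell is NA
  expect_true(all(is.na(bi$values[3:4, 3:4])))
})

test_that("categorical nearest resampling invents no new codes", {
  withr::with_seed(1, {
    v <- matrix(sample(c(2, 5, 9), 36, TRUE), 6, 6)
  })
  l <- tiny_layer(v, kind = "categorical")
  coarse <- grid_spec(0, 600, 300, 2, 2, "EPSG:3763")
  fine <- grid_spec(0, 600, 100, 6, 6, "EPSG:3763")
  back <- resample(resample(l, coarse, "nearest"), fine, "nearest")
  expect_true(all(back$values %in% c(2, 5, 9)))
})

test_that("slope/aspect: flat, south-rising and east-rising planes", {
  cell <- 100
  # flat plane: slope 0, aspect nodata in the interior
  flat <- tiny_layer(matrix(5, 5, 5), cell = cell)
  sa <- derive_slope_aspect(flat)
  expect_equal(sa$slope$values[2:4, 2:4], matrix(0, 3, 3))
  expect_true(all(is.na(sa$aspect$values)))
  expect_true(all(is.na(sa$slope$values[1, ])))    # border nodata
  # z grows with row index (southward): downslope faces north -> 0 deg
  zs <- matrix(rep(seq_len(5), 5) * 10, 5, 5)
  sa <- derive_slope_aspect(tiny_layer(zs, cell = cell))
  expect_equal(unique(as.vector(sa$aspect$values[2:4, 2:4])), 0)
  # z = 0.1 * x: gradient 0.1 east -> slope 10%, aspect 270 (faces west)
  xs <- matrix(rep((seq_len(5) - 0.5) * cell, each = 5) * 0.1, 5, 5)
  sa <- derive_slope_aspect(tiny_layer(xs, cell = cell))
  expect_equal(unique(round(as.vector(sa$slope$values[2:4, 2:4]), 10)), 10)
  expect_equal(unique(as.vector(sa$aspect$values[2:4, 2:4])), 270)
  expect_error(derive_slope_aspect(tiny_layer(matrix(1:4, 2, 2))), "3 x 3")
})

test_that("aspect in [0,360) and slope >= 0 on random terrain", {
  withr::with_seed(11, {
    dem <- tiny_layer(matrix(cumsum(rnorm(100)), 10, 10))
  })
  sa <- derive_slope_aspect(dem)
  a <- sa$aspect$values[!is.na(sa$aspect$values)]
  expect_true(all(a >= 0 & a < 360))
  expect_true(all(sa$slope$values >= 0, na.rm = TRUE))
})

test_that("summarize matches textbook formulas and handles constants", {
  cl <- tiny_layer(matrix(7, 3, 3))
  s <- summarize_stack(raster_stack(list(cl)))
  expect_equal(c(s$min, s$max, s$mean, s$sd), c(7, 7, 7, 0))
  l123 <- tiny_layer(matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3))
  s <- summarize_stack(raster_stack(list(l123)))
  expect_equal(c(s$mean, s$min, s$max), c(2, 1, 3))
  withr::with_seed(5, v <- rnorm(5))
  lv <- tiny_layer(matrix(c(v, rep(NA, 4)), 3, 3))
  s <- summarize_stack(raster_stack(list(lv)))
  mu <- sum(v) / 5
  expect_equal(s$mean, mu)
  expect_equal(s$sd, sqrt(sum((v - mu)^2) / 4))
  s2 <- summarize_stack(raster_stack(list(lv)), sd_type = "population")
  expect_equal(s2$sd, sqrt(sum((v - mu)^2) / 5))
})

test_that("summarize splits area and point scopes and validates points", {
  st <- tiny_stack(6, 6, 2)
  pts <- cell_center(st$spec, c(1, 2), c(1, 5))
  s <- summarize_stack(st, points = pts)
  expect_setequal(unique(s$scope), c("area", "points"))
  expect_equal(s$n[s$scope == "points"], c(2, 2))
  expect_error(summarize_stack(st, points = data.frame(x = 1e9, y = 0)),
               "outside")
  expect_error(summarize_stack(raster_stack(list(tiny_layer(
    matrix(NA_real_, 2, 2))))), "no valid cells")
})

test_that("mean over a partition recombines by weighted formula", {
  st <- tiny_stack(6, 6, 1, seed = 9)
  m1 <- matrix(FALSE, 6, 6); m1[, 1:3] <- TRUE
  m2 <- !m1
  a <- summarize_stack(st, mask = m1); b <- summarize_stack(st, mask = m2)
  full <- summarize_stack(st)
  expect_equal((a$mean * a$n + b$mean * b$n) / (a$n + b$n), full$mean)
})

test_that("point-to-cell mapping follows the half-open convention", {
  sp <- tiny_spec(4, 4, 100)
  # interior point
  expect_equal(unlist(cell_of_point(sp, 150, 250)), c(row = 2, col = 2))
  # shared vertical edge belongs to the right cell, horizontal to below
  expect_equal(cell_of_point(sp, 100, 350)$col, 2L)
  expect_equal(cell_of_point(sp, 50, 300)$row, 2L)
  # outside
  expect_true(is.na(cell_of_point(sp, -1, 50)$row))
  expect_true(is.na(cell_of_point(sp, 50, 401)$row))
})
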