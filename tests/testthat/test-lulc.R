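toy_legend <- function() {
  lulc_legend(data.frame(
    code = c(11, 21, 22, 31, 32, 41),
    level1 = c("Artificialized", "Agriculture", "Agriculture", "Forests",
               "Forests", "Shrublands"),
    level4 = c("Artificialized", "Orchards", "Olive groves", "Chestnut",
               "Pine woods", "Shrublands")))
}

test_that("legend validation catches duplicates and broken hierarchy", {
  expect_s3_class(toy_legend(), "lulc_legend")
  expect_error(lulc_legend(data.frame(code = c(1, 1), level1 = "a",
                                      level4 = c("x", "y"))), "duplicate")
  expect_error(lulc_legend(data.frame(code = 1:2, level1 = c("a", "b"),
                                      level4 = "x")),
               "more than one")
  expect_error(lulc_legend(data.frame(code = 1)), "missing column")
})

test_that("reclass merges level-4 codes into level-1 classes", {
  leg <- toy_legend()
  m <- tiny_layer(matrix(c(21, 22, 31, 32), 2, 2), kind = "categorical")
  l1 <- reclass_to_level(m, leg, 1)
  labs <- attr(l1, "class_labels")
  expect_equal(labs[l1$values[1, 1]], "Agriculture")
  expect_equal(labs[l1$values[2, 1]], "Agriculture")   # merged orchards+olive
  l4 <- reclass_to_level(m, leg, 4)
  labs4 <- attr(l4, "class_labels")
  expect_equal(sort(labs4[as.vector(l4$values)]),
               sort(c("Orchards", "Olive groves", "Chestnut", "Pine woods")))
  # already at target level: relabelling is a bijection, counts conserved
  expect_equal(sum(!is.na(l4$values)), sum(!is.na(m$values)))
  # mixed scheme: agriculture merged, forests kept at level 4
  mx <- reclass_to_level(m, leg, "mixed",
    mapping = data.frame(code = c(21, 22, 31, 32),
                         class = c("Agriculture", "Agriculture",
                                   "Chestnut", "Pine woods")))
  expect_equal(sort(unique(attr(mx, "class_labels"))),
               c("Agriculture", "Chestnut", "Pine woods"))
  expect_error(reclass_to_level(tiny_layer(matrix(99, 1, 1),
                                           kind = "categorical"), leg, 1),
               "99")
})

test_that("class-area tables: single class, 50/50, percentages sum to 100", {
  leg <- toy_legend()
  mono <- reclass_to_level(tiny_layer(matrix(31, 2, 2),
                                      kind = "categorical"), leg, 1)
  t1 <- class_area_table(mono, epoch = "t1")
  expect_equal(t1$percent[t1$class == "Forests"], 100)
  two <- reclass_to_level(tiny_layer(matrix(c(21, 21, 31, 31), 2, 2),
                                     kind = "categorical"), leg, 1)
  t2 <- class_area_table(two)
  expect_equal(sort(t2$percent[t2$cells > 0]), c(50, 50))
  expect_equal(sum(t2$percent), 100)
})

test_that("polygon masking agrees with brute-force point-in-polygon", {
  # striped 2-class map; mask covers the left half of the grid
  v <- matrix(rep(c(1, 2), each = 4, times = 4), 8, 8)
  m <- tiny_layer(v, kind = "categorical")
  half <- area_polygon(data.frame(x = c(0, 400, 400, 0),
                                  y = c(0, 0, 800, 800)))
  tab <- class_area_table(m, mask = half)
  ctr <- expand.grid(row = 1:8, col = 1:8)
  cc <- cell_center(m$spec, ctr$row, ctr$col)
  inside <- point_in_polygon(half, cc$x, cc$y)
  want <- table(v[cbind(ctr$row, ctr$col)][inside])
  expect_equal(tab$cells[tab$class == "1"], unname(want["1"]) * 1L)
  expect_equal(sum(tab$cells), sum(inside))
  expect_error(class_area_table(m, mask = area_polygon(
    data.frame(x = c(-30, -10, -10, -30), y = c(-30, -30, -10, -10)))),
    "does not intersect")
})

test_that("table_change reproduces hand deltas and sums to zero", {
  a <- structure(data.frame(class = c("A", "B"), cells = NA,
                            percent = c(60, 40)),
                 class = c("lulc_table", "data.frame"))
  b <- structure(data.frame(class = c("B", "A"), cells = NA,
                            percent = c(55, 45)),
                 class = c("lulc_table", "data.frame"))
  d <- table_change(a, b)
  expect_equal(d$delta_pp[d$class == "A"], -15)
  expect_equal(d$delta_pp[d$class == "B"], 15)
  expect_equal(sum(d$delta_pp), 0)
  expect_equal(table_change(a, a)$delta_pp, c(0, 0))
  bad <- a; bad$class <- c("A", "C")
  expect_error(table_change(a, bad), "class sets differ")
})

test_that("transition matrix: identity, full change, hand cross-tab", {
  leg <- toy_legend()
  mk <- function(codes) reclass_to_level(
    tiny_layer(matrix(codes, 3, 3), kind = "categorical"), leg, 1)
  a <- mk(c(21, 21, 21, 31, 31, 31, 41, 41, 11))
  same <- transition_matrix(a, a)
  expect_equal(same$persistence_pct, 100)
  expect_true(all(same$counts[upper.tri(same$counts)] == 0))
  b <- mk(c(31, 31, 31, 41, 41, 41, 21, 21, 21))
  flip <- transition_matrix(a, b)
  expect_equal(flip$persistence_pct, 0)
  expect_equal(sum(diag(flip$counts)), 0)
  # hand cross-tab for a mixed pair
  c2 <- mk(c(21, 31, 21, 31, 31, 41, 41, 41, 11))
  tm <- transition_matrix(a, c2)
  expect_equal(tm$counts["Agriculture", "Agriculture"], 2L)
  expect_equal(tm$counts["Agriculture", "Forests"], 1L)
  expect_equal(tm$counts["Forests", "Forests"], 2L)
  expect_equal(tm$counts["Forests", "Shrublands"], 1L)
  expect_equal(sum(tm$counts), 9L)
})

test_that("transition marginals reproduce per-epoch class tables exactly", {
  leg <- toy_legend()
  withr::with_seed(77, {
    a <- reclass_to_level(tiny_layer(matrix(sample(leg$code, 100, TRUE),
                                            10, 10), kind = "categorical"),
                          leg, 1)
    b <- reclass_to_level(tiny_layer(matrix(sample(leg$code, 100, TRUE),
                                            10, 10), kind = "categorical"),
                          leg, 1)
  })
  tm <- transition_matrix(a, b)
  ta <- class_area_table(a); tb <- class_area_table(b)
  expect_equal(unname(rowSums(tm$counts)[ta$class]), ta$cells * 1)
  expect_equal(unname(colSums(tm$counts)[tb$class]), tb$cells * 1)
  # persistence + off-diagonal share = 100
  expect_equal(tm$persistence_pct +
                 100 * sum(tm$counts[row(tm$counts) != col(tm$counts)]) /
                 sum(tm$counts), 100)
  # gain/loss decompositions are the off-diagonal column/row entries
  g <- tm$gains[["Forests"]]
  expect_equal(sum(g), sum(tm$counts[, "Forests"]) -
                 tm$counts["Forests", "Forests"])
})

test_that("published-table mode reads epochs and feeds table_change", {
  path <- system.file("extdata", "lulc_study_area_pct.csv",
                      package = "ecosuit")
  tabs <- read_lulc_tables(path)
  expect_length(tabs, 4)
  expect_equal(attr(tabs[[1]], "epoch"), "MAF1951-1980")
  expect_equal(sum(tabs[["COS2018"]]$percent), 100, tolerance = 0.1)
  d <- table_change(tabs[["MAF1951-1980"]], tabs[["COS1995"]])
  expect_equal(d$delta_pp[d$class == "Forests"], 4.0)
})
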