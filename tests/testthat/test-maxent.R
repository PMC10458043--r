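test_that("auto feature rule follows the presence-count table", {
  expect_setequal(auto_feature_classes(5), c("linear", "categorical"))
  expect_setequal(auto_feature_classes(10),
                  c("linear", "quadratic", "categorical"))
  expect_setequal(auto_feature_classes(15),
                  c("linear", "quadratic", "hinge", "categorical"))
  expect_setequal(auto_feature_classes(201),
                  c("linear", "quadratic", "hinge", "product", "threshold",
                    "categorical"))
})

test_that("build_features: auto classes, categorical indicators, bounds", {
  pb <- tiny_pb(m = 5)
  fs <- build_features(pb$presence, pb$background, maxent_settings())
  expect_setequal(unique(fs$defs$class), "linear")   # m = 5 -> linear only
  # m = 201, two continuous variables -> every class present
  withr::with_seed(2, {
    p <- data.frame(a = runif(201), b = runif(201))
    b <- data.frame(a = runif(300), b = runif(300))
  })
  fs2 <- build_features(p, b, maxent_settings())
  expect_setequal(unique(fs2$defs$class),
                  c("linear", "quadratic", "product", "hinge_fwd",
                    "hinge_rev", "threshold"))
  # categorical with 3 levels -> exactly 3 indicator features
  p$soil <- factor(c("CM1", "RG2", "X")[c(rep(1, 100), rep(2, 100), 3)])
  b$soil <- factor(rep(c("CM1", "RG2", "X"), 100))
  fs3 <- build_features(p, b, maxent_settings())
  expect_equal(sum(fs3$defs$class == "categorical"), 3)
  # every feature value lies in [0, 1] on the training data
  F <- eval_features(fs3, rbind(p, b))
  expect_true(all(F >= 0 & F <= 1))
  # constant variable contributes nothing, with a warning
  p$const <- 1; b$const <- 1
  expect_warning(fs4 <- build_features(p, b, maxent_settings()),
                 "constant")
  expect_false("const" %in% fs4$defs$var)
})

test_that("total shrinkage gives the uniform model and zero gain", {
  pb <- tiny_pb(m = 5, nbg = 10)
  mod <- maxent(pb$presence, pb$background,
                maxent_settings(regularization_multiplier = 1e6))
  expect_true(all(mod$lambda == 0))
  expect_equal(mod$gain, 0)
  expect_equal(mod$raw_bg, rep(0.1, 10))
  expect_equal(mod$entropy, log(10))
  # uniform limit: every cloglog prediction is 1 - exp(-1)
  pred <- predict(mod, pb$background, type = "cloglog")
  expect_equal(pred, rep(1 - exp(-1), 10), tolerance = 1e-12)
})

test_that("no signal (presences = background distribution) gives ~zero gain", {
  bg <- data.frame(a = rep(seq(0, 1, length.out = 10), 2))
  p <- data.frame(a = seq(0, 1, length.out = 10))
  mod <- maxent(p, bg, maxent_settings(feature_classes = "linear"))
  expect_lt(abs(mod$gain), 1e-6)
  expect_lt(max(abs(mod$lambda)), 0.1)
})

test_that("1-feature fit matches a golden-section / optimize() oracle", {
  pb <- tiny_pb(m = 5, nbg = 10)
  set <- maxent_settings(feature_classes = "linear",
                         convergence_threshold = 1e-10)
  mod <- maxent(pb$presence[, "a", drop = FALSE],
                pb$background[, "a", drop = FALSE], set, beta = 0.05)
  Fp <- eval_features(mod$feature_set, pb$presence[, "a", drop = FALSE])
  Fbg <- eval_features(mod$feature_set, pb$background[, "a", drop = FALSE])
  oracle <- stats::optimize(function(l) gain_direct(l, Fp, Fbg, 0.05),
                            c(-50, 50), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(mod$lambda - oracle$maximum), 1e-4)
  expect_equal(mod$gain, oracle$objective, tolerance = 1e-8)
})

test_that("coordinate descent matches dense grid search on small instances", {
  withr::with_seed(21, {
    bg <- data.frame(a = runif(20), b = runif(20))
    p <- data.frame(a = runif(8, 0.5, 1), b = runif(8, 0, 0.6))
  })
  set <- maxent_settings(feature_classes = "linear",
                         convergence_threshold = 1e-10)
  mod <- maxent(p, bg, set)
  Fp <- eval_features(mod$feature_set, p)
  Fbg <- eval_features(mod$feature_set, bg)
  grid <- seq(-6, 6, by = 0.05)
  best <- -Inf
  for (l1 in grid) {
    g <- vapply(grid, function(l2)
      gain_direct(c(l1, l2), Fp, Fbg, mod$beta), 0)
    best <- max(best, max(g))
  }
  expect_gte(mod$gain, best - 1e-3)
})

test_that("fit invariants: raw sums to 1, gain path monotone, G(0)=0", {
  withr::with_seed(33, {
    bg <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
    p <- data.frame(a = rnorm(30, 1), b = rnorm(30, 0.5), c = rnorm(30))
  })
  mod <- maxent(p, bg, maxent_settings())
  expect_equal(sum(mod$raw_bg), 1, tolerance = 1e-8)
  expect_true(all(diff(c(0, mod$gain_path)) >= -1e-9))
  expect_gte(mod$gain, 0)
  expect_gte(mod$entropy, 0)
  expect_lte(mod$entropy, log(100) + 1e-12)
})

test_that("lambda shrinks in max-norm as the multiplier grows", {
  pb <- tiny_pb(m = 20, nbg = 50)
  norms <- vapply(c(0.5, 1, 2, 5), function(mult) {
    m <- maxent(pb$presence, pb$background,
                maxent_settings(regularization_multiplier = mult))
    max(abs(m$lambda))
  }, 0)
  expect_true(all(diff(norms) <= 1e-9))
})

test_that("predict: hand-computed 2-cell oracle and monotonicity", {
  # manufactured model with raw = (0.9, 0.1) over a 2-cell background
  set <- maxent_settings(feature_classes = "linear")
  p <- data.frame(a = c(1, 1)); bg <- data.frame(a = c(1, 0))
  fs <- build_features(p, bg, set)
  lam <- log(9)
  # eta = (log 9, 0); Z = 10 -> raw = (0.9, 0.1)
  H <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  mod <- structure(list(feature_set = fs, lambda = lam, beta = 0,
                        log_z = log(10), entropy = H, settings = set),
                   class = "maxent_model")
  raw <- predict(mod, bg, type = "raw")
  expect_equal(raw, c(0.9, 0.1))
  expect_equal(predict(mod, bg, type = "cloglog"),
               1 - exp(-exp(H) * c(0.9, 0.1)))
  expect_equal(predict(mod, bg, type = "logistic"),
               0.5 * exp(H) * raw / (1 - 0.5 + 0.5 * exp(H) * raw))
  # cloglog strictly increasing in the linear predictor
  sweep <- data.frame(a = seq(0, 1, length.out = 50))
  cl <- predict(mod, sweep, type = "cloglog")
  expect_true(all(diff(cl) > 0))
  expect_true(all(cl > 0 & cl < 1))
})

test_that("AUC: perfect separation, ties, and exhaustive pair oracle", {
  expect_equal(maxent_auc(presence_scores = c(4, 5),
                          background_scores = c(1, 2, 3)), 1.0)
  expect_equal(maxent_auc(presence_scores = rep(2, 5),
                          background_scores = rep(2, 7)), 0.5)
  withr::with_seed(6, {
    sp <- sample(1:5, 4, TRUE); sb <- sample(1:5, 6, TRUE)
  })
  pairs <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(maxent_auc(presence_scores = sp, background_scores = sb),
               mean(pairs))
})

test_that("importance: single variable, normalization, noise variable", {
  pb <- tiny_pb(m = 20, nbg = 50)
  mod1 <- maxent(pb$presence[, "a", drop = FALSE],
                 pb$background[, "a", drop = FALSE], maxent_settings(),
                 beta = 0.05)
  imp1 <- maxent_importance(mod1, jackknife = FALSE)
  expect_equal(imp1$percent_contribution, 100)
  expect_equal(imp1$permutation_importance, 100)
  # presence depends only on a; b is pure noise
  withr::with_seed(9, {
    bg <- data.frame(a = runif(1000), b = runif(1000))
    p <- data.frame(a = runif(200, 0.75, 1), b = runif(200))
  })
  mod <- maxent(p, bg, maxent_settings())
  imp <- maxent_importance(mod, jackknife = TRUE)
  expect_equal(sum(imp$percent_contribution), 100, tolerance = 0.1)
  expect_equal(sum(imp$permutation_importance), 100, tolerance = 0.1)
  expect_gt(imp$permutation_importance[imp$variable == "a"], 90)
  # jackknife gains nest below the full-model gain
  expect_true(all(imp$gain_with_only <= mod$gain + 1e-4))
  expect_true(all(imp$gain_without <= mod$gain + 1e-4))
  expect_true(all(imp$gain_with_only >= -1e-9))
})

test_that("response curves: monotone, categorical levels, null weight", {
  pb <- tiny_pb(m = 20, nbg = 50)
  set <- maxent_settings(feature_classes = "linear")
  mod <- maxent(pb$presence, pb$background, set, beta = 0.05)
  rc <- response_curve(mod, "a")
  expect_true(all(diff(rc$prediction) > 0))   # positive linear effect
  expect_error(response_curve(mod, "zzz"), "unknown variable")
  # categorical sweep: one prediction per level
  withr::with_seed(14, {
    p <- data.frame(a = runif(30, 0.5, 1),
                    s = factor(sample(c("u", "v", "w"), 30, TRUE)))
    bg <- data.frame(a = runif(60), s = factor(sample(c("u", "v", "w"),
                                                      60, TRUE)))
  })
  mcat <- maxent(p, bg, maxent_settings())
  rcc <- response_curve(mcat, "s")
  expect_equal(nrow(rcc), 3)
  # a variable whose features all have zero weight -> flat curve
  zero_vars <- setdiff(unique(mod$feature_set$defs$var), "a")
  for (v in zero_vars) {
    idx <- mod$feature_set$defs$var == v
    if (all(mod$lambda[idx] == 0)) {
      expect_equal(diff(range(response_curve(mod, v)$prediction)), 0)
    }
  }
})

test_that("sample_background: determinism, exhaustion, uniformity", {
  st <- tiny_stack(10, 10, 2, seed = 50)
  b1 <- sample_background(st, 30, seed = 99)
  b2 <- sample_background(st, 30, seed = 99)
  expect_equal(b1$cells, b2$cells)
  expect_equal(nrow(b1$env), 30)
  expect_warning(ball <- sample_background(st, 200, seed = 1), "using all")
  expect_equal(nrow(ball$env), 100)
  # 2-cell grid, n = 1: each cell drawn ~50% across seeds (3 sigma)
  st2 <- tiny_stack(1, 2, 1)
  picks <- vapply(1:400, function(s)
    sample_background(st2, 1, seed = s)$cells$col, 0L)
  ph <- mean(picks == 1)
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("projection is consistent with predict and propagates nodata", {
  withr::with_seed(61, {
    v1 <- matrix(runif(64), 8, 8); v2 <- matrix(runif(64), 8, 8)
  })
  v1[3, 4] <- NA
  st <- raster_stack(list(tiny_layer(v1, name = "a"),
                          tiny_layer(v2, name = "b")))
  bg <- sample_background(st, 40, seed = 3)
  p_env <- bg$env[bg$env$a > 0.6, , drop = FALSE][1:5, ]
  mod <- maxent(p_env, bg, maxent_settings(feature_classes = "linear"))
  suit <- project_suitability(mod, st)
  expect_true(is.na(suit$values[3, 4]))
  at_bg <- suit$values[cbind(bg$cells$row, bg$cells$col)]
  expect_equal(at_bg, predict(mod, bg$env, type = "cloglog"))
  # uniform model projects the constant 1 - exp(-1)
  uni <- maxent(p_env, bg, maxent_settings(
    regularization_multiplier = 1e6))
  psuit <- project_suitability(uni, st)
  expect_equal(unique(as.vector(psuit$values[!is.na(psuit$values)])),
               1 - exp(-1))
  st_miss <- raster_stack(list(tiny_layer(v2, name = "b")))
  expect_error(project_suitability(mod, st_miss), "a")
})

test_that("model JSON serialization round-trips predictions", {
  dir <- withr::local_tempdir()
  pb <- tiny_pb(m = 20, nbg = 50)
  mod <- maxent(pb$presence, pb$background, maxent_settings())
  path <- file.path(dir, "model.json")
  write_maxent_model(mod, path)
  back <- read_maxent_model(path)
  newdata <- data.frame(a = c(0.2, 0.9), b = c(0.5, 0.1))
  expect_equal(predict(back, newdata), predict(mod, newdata))
})
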