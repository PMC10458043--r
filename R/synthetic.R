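#' Describe a synthetic study system
#'
#' A scenario fixes everything the generators need: the grid, the
#' environmental variables and their target pairwise correlations, the true
#' suitability weights, the presence count, the LULC class set with its
#' per-pixel Markov transition kernel, and the seed.  Generators are pure
#' functions of (scenario, seed), so a scenario is a complete, reproducible
#' stand-in for field rasters and occurrence records.
#'
#' @param n_rows,n_cols Grid size (default 200 x 200, mirroring a 100 m
#'   analysis resolution at desk scale).
#' @param cell_size Cell size in metres (default 100).
#' @param variables Names of the continuous environmental fields.
#' @param correlation Target correlation matrix for the fields (symmetric
#'   PSD).  The default is the identity except for a 0.9 correlation
#'   between the first two variables, so the default world contains one
#'   collinear pair that a 0.8-cutoff pruning step must resolve.
#' @param smooth_sigma Gaussian smoothing radius in cells controlling
#'   spatial autocorrelation (default 5; larger = smoother fields, which
#'   makes occurrence thinning non-trivial).
#' @param lambda_lin,lambda_quad Named true weights on z-scored variables
#'   (linear and quadratic terms) defining the true suitability surface.
#'   The defaults emulate a narrow-endemic system: one strong monotone
#'   driver (`V1`), one secondary unimodal driver (`V4`, niche peak one SD
#'   above its mean), one weak driver (`V6`), and map-wide mean
#'   suitability below 1%.
#' @param m Presence count to draw (default 200).
#' @param n_soil_classes Number of categorical soil classes (default 4).
#' @param lulc_classes LULC class labels (default 3 classes).
#' @param lulc_kernel K x K per-pixel Markov transition matrix (rows sum to
#'   1); default has 0.9 persistence with symmetric leakage.
#' @param lulc_prior Initial class proportions (default equal).
#' @param n_epochs Number of LULC epochs to simulate (default 4, matching a
#'   four-date map series).
#' @param future_shift Named per-variable mean shift (in SD units) applied
#'   to build a "future" climate stack (default +1 SD on the first
#'   variable).
#' @param seed Integer seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows = 200L, n_cols = 200L,
                               cell_size = 100,
                               variables = paste0("V", 1:7),
                               correlation = NULL, smooth_sigma = 5,
                               lambda_lin = c(V1 = 4, V4 = 1.5, V6 = 0.75),
                               lambda_quad = c(V4 = -0.75),
                               m = 200L, n_soil_classes = 4L,
                               lulc_classes = c("Agriculture", "Forests",
                                                "Shrublands"),
                               lulc_kernel = NULL, lulc_prior = NULL,
                               n_epochs = 4L,
                               future_shift = NULL,
                               seed = 1L) {
  k <- length(variables)
  if (is.null(correlation)) {
    correlation <- diag(k)
    if (k >= 2) correlation[1, 2] <- correlation[2, 1] <- 0.9
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))))
    stop("correlation matrix must be symmetric", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  K <- length(lulc_classes)
  if (is.null(lulc_kernel)) {
    lulc_kernel <- matrix(0.1 / (K - 1), K, K); diag(lulc_kernel) <- 0.9
  }
  lulc_kernel <- as.matrix(lulc_kernel)
  if (any(abs(rowSums(lulc_kernel) - 1) > 1e-8))
    stop("transition kernel rows must sum to 1", call. = FALSE)
  if (is.null(lulc_prior)) lulc_prior <- rep(1 / K, K)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (is.null(future_shift))
    future_shift <- stats::setNames(1, variables[1])
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, variables = variables,
                 correlation = correlation, smooth_sigma = smooth_sigma,
                 lambda_lin = lambda_lin, lambda_quad = lambda_quad,
                 m = as.integer(m), n_soil_classes = as.integer(n_soil_classes),
                 lulc_classes = lulc_classes, lulc_kernel = lulc_kernel,
                 lulc_prior = lulc_prior, n_epochs = as.integer(n_epochs),
                 future_shift = future_shift, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# smooth standardized Gaussian random field: white noise convolved with a
# separable Gaussian kernel; generated on a padded grid so edges carry no
# artefacts, then cropped and z-scored.
smooth_field <- function(nr, nc, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  z <- matrix(stats::rnorm((nr + 2 * r) * (nc + 2 * r)), nr + 2 * r)
  z <- apply(z, 2, function(col) stats::convolve(col, kern, type = "filter"))
  z <- t(apply(z, 1, function(row) stats::convolve(row, kern,
                                                   type = "filter")))
  z <- z[seq_len(nr), seq_len(nc)]
  (z - mean(z)) / stats::sd(z)
}

#' Generate a correlated synthetic environment stack
#'
#' Independent smooth Gaussian random fields are mixed through the Cholesky
#' factor of the scenario's target correlation matrix, yielding continuous
#' layers with both spatial autocorrelation and the requested cross-layer
#' correlation.  A categorical `soil` layer is built by quantile-binning an
#' extra smooth field, and a `dem` elevation field (600 +/- 150 m) supports
#' slope/aspect derivation.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Seed override (defaults to the scenario seed).
#' @param shift Optional named per-variable mean shift in SD units (used
#'   for future-climate stacks).
#' @return A [raster_stack()] with the scenario variables plus `soil`
#'   (categorical) and `dem`.
#' @export
gen_env_stack <- function(scenario, seed = NULL, shift = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  nr <- scenario$n_rows; nc <- scenario$n_cols
  k <- length(scenario$variables)
  spec <- grid_spec(0, nr * scenario$cell_size, scenario$cell_size, nr, nc,
                    "EPSG:3763")
  withr::with_seed(seed, {
    Z <- vapply(seq_len(k), function(i)
      as.vector(smooth_field(nr, nc, scenario$smooth_sigma)),
      numeric(nr * nc))
    X <- Z %*% chol(scenario$correlation)
    soil_f <- smooth_field(nr, nc, scenario$smooth_sigma)
    dem_f <- smooth_field(nr, nc, 2 * scenario$smooth_sigma)
  })
  if (!is.null(shift))
    for (v in names(shift)) {
      i <- match(v, scenario$variables)
      if (!is.na(i)) X[, i] <- X[, i] + shift[[v]]
    }
  layers <- lapply(seq_len(k), function(i)
    grid_layer(spec, matrix(X[, i], nr, nc), name = scenario$variables[i],
               kind = "continuous"))
  qs <- stats::quantile(soil_f, seq(0, 1,
                                    length.out = scenario$n_soil_classes + 1))
  soil <- matrix(as.numeric(cut(soil_f, qs, include.lowest = TRUE,
                                labels = FALSE)), nr, nc)
  layers <- c(layers,
              list(grid_layer(spec, soil, name = "soil",
                              kind = "categorical"),
                   grid_layer(spec, 600 + 150 * dem_f, name = "dem",
                              kind = "continuous")))
  raster_stack(layers)
}

#' True suitability surface of a scenario
#'
#' The linear + quadratic score on z-scored variables defined by the
#' scenario's true weights, pushed through the same raw -> cloglog chain
#' the model uses (partition and entropy taken over all valid cells).
#'
#' @param scenario A [synthetic_scenario()].
#' @param stack A stack from [gen_env_stack()].
#' @return A continuous [grid_layer()] `"true_suitability"` in (0, 1).
#' @export
true_suitability <- function(scenario, stack) {
  spec <- stack$spec
  eta <- 0
  zs <- list()
  for (v in unique(c(names(scenario$lambda_lin),
                     names(scenario$lambda_quad)))) {
    x <- as.vector(stack$layers[[v]]$values)
    zs[[v]] <- (x - mean(x)) / stats::sd(x)
  }
  for (v in names(scenario$lambda_lin))
    eta <- eta + scenario$lambda_lin[[v]] * zs[[v]]
  for (v in names(scenario$lambda_quad))
    eta <- eta + scenario$lambda_quad[[v]] * zs[[v]]^2
  lz <- max(eta) + log(sum(exp(eta - max(eta))))
  raw <- exp(eta - lz)
  H <- -sum(raw * log(raw))
  suit <- 1 - exp(-exp(H) * raw)
  grid_layer(spec, matrix(suit, spec$n_rows, spec$n_cols),
             name = "true_suitability", kind = "continuous")
}

#' Sample occurrences from a known suitability surface
#'
#' Presence cells are drawn with probability proportional to the true
#' suitability; one point is placed at each sampled cell center.  By
#' default cells are drawn without replacement; duplicates (pre-thinning)
#' can be allowed.
#'
#' @param stack Environment stack (defines the grid).
#' @param suitability A suitability [grid_layer()], e.g. from
#'   [true_suitability()].
#' @param m Number of presences.
#' @param seed Integer seed.
#' @param allow_duplicates Draw cells with replacement (default FALSE).
#' @return An [occurrence_set()].
#' @export
gen_occurrences <- function(stack, suitability, m, seed = 1L,
                            allow_duplicates = FALSE) {
  spec <- stack$spec
  w <- as.vector(suitability$values)
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("suitability is zero everywhere", call. = FALSE)
  idx <- withr::with_seed(seed,
    sample.int(length(w), m, replace = allow_duplicates, prob = w))
  row <- ((idx - 1) %% spec$n_rows) + 1
  col <- ((idx - 1) %/% spec$n_rows) + 1
  ctr <- cell_center(spec, row, col)
  occurrence_set(ctr$x, ctr$y, "synthetic")
}

#' Simulate a multitemporal LULC series
#'
#' Epoch 1 assigns classes with the scenario's prior proportions in
#' spatially coherent patches (quantile bins of a smooth field); every
#' later epoch evolves each cell independently through the per-pixel
#' Markov kernel.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Seed override.
#' @return List of categorical [grid_layer()]s (one per epoch) with
#'   `class_labels` attributes.
#' @export
gen_lulc_series <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(seed)) seed <- scenario$seed + 7L
  nr <- scenario$n_rows; nc <- scenario$n_cols
  K <- length(scenario$lulc_classes)
  spec <- grid_spec(0, nr * scenario$cell_size, scenario$cell_size, nr, nc,
                    "EPSG:3763")
  withr::with_seed(seed, {
    f <- smooth_field(nr, nc, scenario$smooth_sigma)
    qs <- stats::quantile(f, cumsum(c(0, scenario$lulc_prior)))
    cur <- as.numeric(cut(f, qs, include.lowest = TRUE, labels = FALSE))
    out <- vector("list", scenario$n_epochs)
    out[[1]] <- cur
    if (scenario$n_epochs > 1)
      for (e in 2:scenario$n_epochs) {
        nxt <- cur
        for (cl in seq_len(K)) {
          sel <- which(cur == cl)
          if (length(sel))
            nxt[sel] <- sample.int(K, length(sel), replace = TRUE,
                                   prob = scenario$lulc_kernel[cl, ])
        }
        out[[e]] <- nxt
        cur <- nxt
      }
  })
  lapply(seq_along(out), function(e) {
    l <- grid_layer(spec, matrix(out[[e]], nr, nc),
                    name = sprintf("lulc_epoch%d", e), kind = "categorical")
    attr(l, "class_labels") <- scenario$lulc_classes
    l
  })
}
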