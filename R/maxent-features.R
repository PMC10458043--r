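#' MaxEnt model settings
#'
#' Collects every tunable of the presence-background maximum-entropy model.
#' Defaults mirror the emulated software's documented defaults: 2000
#' background points, at most 2000 optimization cycles, convergence
#' threshold 1e-5, regularization multiplier 1, prevalence 0.5, automatic
#' feature-class selection by presence count.
#'
#' @param n_background Background sample size (default 2000).
#' @param max_iterations Maximum coordinate-descent cycles (default 2000).
#' @param convergence_threshold Stop when the gain improves by less than
#'   this over a full cycle (default 1e-5).
#' @param regularization_multiplier Scales every per-feature L1 penalty
#'   (default 1).
#' @param prevalence_tau Assumed species prevalence for the logistic output
#'   (default 0.5).
#' @param feature_classes `"auto"` or a character subset of
#'   `c("linear","quadratic","product","hinge","threshold","categorical")`.
#' @param hinge_knots,threshold_knots Number of evenly spaced knots per
#'   variable (default 50 each).
#' @param seed Integer seed used for background sampling and permutations.
#' @return An object of class `maxent_settings`.
#' @export
maxent_settings <- function(n_background = 2000L, max_iterations = 2000L,
                            convergence_threshold = 1e-5,
                            regularization_multiplier = 1,
                            prevalence_tau = 0.5,
                            feature_classes = "auto",
                            hinge_knots = 50L, threshold_knots = 50L,
                            seed = 1L) {
  stopifnot(n_background >= 1, max_iterations >= 1,
            convergence_threshold > 0, regularization_multiplier > 0,
            hinge_knots >= 1, threshold_knots >= 1)
  if (prevalence_tau <= 0 || prevalence_tau >= 1)
    stop("prevalence_tau must lie in (0, 1)", call. = FALSE)
  known <- c("linear", "quadratic", "product", "hinge", "threshold",
             "categorical")
  if (!identical(feature_classes, "auto")) {
    bad <- setdiff(feature_classes, known)
    if (length(bad))
      stop("unknown feature class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(n_background = as.integer(n_background),
                 max_iterations = as.integer(max_iterations),
                 convergence_threshold = convergence_threshold,
                 regularization_multiplier = regularization_multiplier,
                 prevalence_tau = prevalence_tau,
                 feature_classes = feature_classes,
                 hinge_knots = as.integer(hinge_knots),
                 threshold_knots = as.integer(threshold_knots),
                 seed = as.integer(seed)),
            class = "maxent_settings")
}

#' Automatic feature classes by presence count
#'
#' The default rule of the emulated software: linear always; quadratic from
#' 10 presences; hinge from 15; product and threshold from 80.  Categorical
#' expansion is always used for factor variables.
#'
#' @param m Number of presence records.
#' @return Character vector of feature classes.
#' @export
auto_feature_classes <- function(m) {
  fc <- "linear"
  if (m >= 10) fc <- c(fc, "quadratic")
  if (m >= 15) fc <- c(fc, "hinge")
  if (m >= 80) fc <- c(fc, "product", "threshold")
  c(fc, "categorical")
}

#' Build the feature expansion for a presence/background dataset
#'
#' Continuous variables are min/max-normalized over presence + background
#' and clamped to `[0, 1]`; every derived feature also lies in `[0, 1]`:
#' linear (scaled value), quadratic (its square), product (pairwise
#' products), forward/reverse hinge and step ("threshold") features on an
#' evenly spaced interior knot grid, and one indicator per level of each
#' categorical (factor) variable.  Constant variables contribute no
#' features (warning).
#'
#' @param presence_env,background_env data.frames with identical columns;
#'   factors mark categorical variables.
#' @param settings A [maxent_settings()].
#' @return A `feature_set`: list with the per-feature definition table and
#'   per-variable normalization constants.
#' @export
build_features <- function(presence_env, background_env, settings) {
  stopifnot(identical(names(presence_env), names(background_env)))
  if (!ncol(presence_env)) stop("no variables", call. = FALSE)
  m <- nrow(presence_env)
  fc <- settings$feature_classes
  if (identical(fc, "auto")) fc <- auto_feature_classes(m)
  all_env <- rbind(presence_env, background_env)
  vars <- names(all_env)
  is_cat <- vapply(all_env, is.factor, TRUE)
  norms <- list(); defs <- list()
  add <- function(var, class, knot = NA_real_, level = NA_character_) {
    defs[[length(defs) + 1L]] <<- data.frame(
      var = var, class = class, knot = knot, level = level,
      stringsAsFactors = FALSE)
  }
  for (v in vars[!is_cat]) {
    x <- all_env[[v]]
    if (anyNA(x)) stop("NA in variable ", v, call. = FALSE)
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning("variable '", v, "' is constant; no features built",
              call. = FALSE)
      next
    }
    norms[[v]] <- c(min = lo, max = hi)
    if ("linear" %in% fc) add(v, "linear")
    if ("quadratic" %in% fc) add(v, "quadratic")
    if ("hinge" %in% fc) {
      ks <- seq(0, 1, length.out = settings$hinge_knots + 2L)
      ks <- ks[-c(1, length(ks))]
      for (k in ks) { add(v, "hinge_fwd", k); add(v, "hinge_rev", k) }
    }
    if ("threshold" %in% fc) {
      ks <- seq(0, 1, length.out = settings$threshold_knots + 2L)
      ks <- ks[-c(1, length(ks))]
      for (k in ks) add(v, "threshold", k)
    }
  }
  if ("product" %in% fc) {
    cv <- intersect(vars[!is_cat], names(norms))
    if (length(cv) >= 2)
      for (i in seq_len(length(cv) - 1))
        for (j in (i + 1):length(cv))
          add(cv[i], "product", level = cv[j])
  }
  if ("categorical" %in% fc) {
    for (v in vars[is_cat]) {
      for (lev in levels(all_env[[v]])) add(v, "categorical", level = lev)
    }
  }
  if (!length(defs)) stop("no features could be built", call. = FALSE)
  defs <- do.call(rbind, defs)
  defs$name <- ifelse(defs$class == "product",
                      paste0(defs$var, ":", defs$level),
    ifelse(defs$class == "categorical",
           paste0(defs$var, "==", defs$level),
    ifelse(is.na(defs$knot), paste0(defs$class, "(", defs$var, ")"),
           sprintf("%s(%s,%.4f)", defs$class, defs$var, defs$knot))))
  structure(list(defs = defs, norms = norms,
                 variables = vars, categorical = vars[is_cat],
                 classes = fc),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features over %d variable(s) [%s]\n",
              nrow(x$defs), length(x$variables),
              paste(setdiff(x$classes, "categorical"), collapse = ", ")))
  invisible(x)
}

scale01 <- function(x, nm) pmin(pmax((x - nm["min"]) /
                                       (nm["max"] - nm["min"]), 0), 1)

#' Evaluate a feature set on environment data
#'
#' @param fs A `feature_set` from [build_features()].
#' @param env data.frame with the variables used to build `fs`.
#' @return Numeric matrix, one column per feature, values in `[0, 1]`.
#' @export
eval_features <- function(fs, env) {
  stopifnot(inherits(fs, "feature_set"))
  miss <- setdiff(unique(fs$defs$var), names(env))
  if (length(miss))
    stop("missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(env)
  defs <- fs$defs
  out <- matrix(0, n, nrow(defs))
  colnames(out) <- defs$name
  scaled <- lapply(fs$norms, function(nm) NULL)
  get_scaled <- function(v) {
    if (is.null(scaled[[v]]))
      scaled[[v]] <<- scale01(as.numeric(env[[v]]), fs$norms[[v]])
    scaled[[v]]
  }
  for (j in seq_len(nrow(defs))) {
    cl <- defs$class[j]; v <- defs$var[j]
    out[, j] <- switch(cl,
      linear = get_scaled(v),
      quadratic = get_scaled(v)^2,
      product = get_scaled(v) * get_scaled(defs$level[j]),
      hinge_fwd = {
        k <- defs$knot[j]
        pmax(0, get_scaled(v) - k) / (1 - k)
      },
      hinge_rev = {
        k <- defs$knot[j]
        pmax(0, k - get_scaled(v)) / k
      },
      threshold = as.numeric(get_scaled(v) >= defs$knot[j]),
      categorical = as.numeric(as.character(env[[v]]) == defs$level[j]),
      stop("unknown feature class ", cl))
  }
  out
}

#' Default per-feature L1 regularization
#'
#' Interpolates the published per-feature-class default tables by presence
#' count `m` and scales by the regularization multiplier:
#' linear/quadratic/product interpolate 1.0 -> 0.05 over m = 0/10/30/100;
#' categorical 0.65/0.5/0.25 at 0/10/17; threshold 2.0 -> 1.0 at 0/100;
#' hinge is 0.5 regardless of m.
#'
#' @param fs A `feature_set`.
#' @param m Presence count.
#' @param multiplier Regularization multiplier.
#' @return Numeric vector, one beta per feature.
#' @export
default_regularization <- function(fs, m, multiplier = 1) {
  interp <- function(xs, ys) stats::approx(xs, ys, m, rule = 2)$y
  lqp <- interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05))
  cat_b <- interp(c(0, 10, 17), c(0.65, 0.5, 0.25))
  thr <- interp(c(0, 100), c(2, 1))
  hin <- 0.5
  cls <- fs$defs$class
  beta <- ifelse(cls %in% c("linear", "quadratic", "product"), lqp,
          ifelse(cls %in% c("hinge_fwd", "hinge_rev"), hin,
          ifelse(cls == "threshold", thr, cat_b)))
  beta * multiplier
}
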