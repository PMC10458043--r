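#' Predict suitability from a fitted model
#'
#' Output transforms of the raw maximum-entropy density `r(x) =
#' exp(lambda . f(x)) / Z` (with `Z` the partition sum over the background
#' sample, so raw values sum to 1 over the background):
#' * `raw` — the density itself;
#' * `logistic` — `tau e^H r / (1 - tau + tau e^H r)` with `tau` the
#'   assumed prevalence;
#' * `cloglog` (default) — `1 - exp(-e^H r)`, a 0–1 habitat-suitability
#'   score, 0 unsuitable and 1 suitable,
#' where `H` is the entropy of the fitted raw distribution over the
#' background.
#'
#' @param object A `maxent_model`.
#' @param newdata data.frame of environment values.
#' @param type `"cloglog"`, `"logistic"` or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("cloglog", "logistic", "raw"),
                                 ...) {
  type <- match.arg(type)
  F <- eval_features(object$feature_set, as.data.frame(newdata))
  eta <- as.numeric(F %*% object$lambda)
  raw <- exp(eta - object$log_z)
  if (type == "raw") return(raw)
  eH <- exp(object$entropy)
  if (type == "cloglog") return(1 - exp(-eH * raw))
  tau <- object$settings$prevalence_tau
  tau * eH * raw / (1 - tau + tau * eH * raw)
}

#' Training AUC (rank-based)
#'
#' The probability that a randomly chosen presence scores above a randomly
#' chosen background point, ties counted half — the Mann-Whitney statistic,
#' equal to the trapezoidal area under the ROC curve.
#'
#' @param model A `maxent_model`, or `NULL` when raw scores are supplied.
#' @param presence_env,background_env Optional data.frames; default to the
#'   model's training data.
#' @param presence_scores,background_scores Optionally, precomputed scores
#'   (bypass the model entirely).
#' @return AUC in `[0, 1]`.
#' @export
maxent_auc <- function(model = NULL, presence_env = NULL,
                       background_env = NULL, presence_scores = NULL,
                       background_scores = NULL) {
  if (is.null(presence_scores)) {
    if (is.null(presence_env)) presence_env <- model$presence_env
    if (is.null(background_env)) background_env <- model$background_env
    presence_scores <- predict(model, presence_env, type = "raw")
    background_scores <- predict(model, background_env, type = "raw")
  }
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 1 || nb < 1) stop("need scores on both sides", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Project a model over a raster stack
#'
#' Per-cell prediction; a cell is nodata whenever any model variable is
#' nodata there.  Evaluation is chunked so large grids never materialize a
#' full feature matrix.
#'
#' @param model A `maxent_model`.
#' @param stack A [raster_stack()] containing every model variable.
#' @param type Output transform, as in [predict.maxent_model()].
#' @param chunk Cells per evaluation block.
#' @return A continuous [grid_layer()] named `"suitability"`.
#' @export
project_suitability <- function(model, stack, type = "cloglog",
                                chunk = 20000L) {
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "raster_stack"))
  vars <- model$feature_set$variables
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop("stack is missing model variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  spec <- stack$spec
  ncell <- spec$n_rows * spec$n_cols
  vals <- lapply(stack$layers[vars], function(l) as.vector(l$values))
  valid <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  out <- rep(NA_real_, ncell)
  idx <- which(valid)
  cats <- model$feature_set$categorical
  for (start in seq(1, length(idx), by = chunk)) {
    ii <- idx[start:min(start + chunk - 1, length(idx))]
    env <- as.data.frame(lapply(vals, function(v) v[ii]), optional = TRUE)
    for (v in cats) env[[v]] <- factor(as.character(env[[v]]))
    out[ii] <- predict(model, env, type = type)
  }
  grid_layer(spec, matrix(out, spec$n_rows, spec$n_cols),
             name = "suitability", kind = "continuous")
}

#' Marginal response curve for one variable
#'
#' Sweeps the target variable across its observed (training) range — or its
#' levels, if categorical — while every other continuous variable is held
#' at its background mean and every other categorical at its background
#' modal level.
#'
#' @param model A `maxent_model` (with training data attached).
#' @param variable Variable name.
#' @param n_points Sweep resolution for continuous variables (default 100).
#' @param type Output transform (default `"cloglog"`).
#' @return data.frame with columns `value` and `prediction`.
#' @export
response_curve <- function(model, variable, n_points = 100L,
                           type = "cloglog") {
  fs <- model$feature_set
  if (!variable %in% fs$variables)
    stop("unknown variable: ", variable, call. = FALSE)
  bg <- model$background_env
  if (is.null(bg)) stop("model carries no training data", call. = FALSE)
  base <- lapply(names(bg), function(v) {
    if (is.factor(bg[[v]])) {
      tab <- table(bg[[v]])
      factor(names(tab)[which.max(tab)], levels = levels(bg[[v]]))
    } else mean(bg[[v]])
  })
  names(base) <- names(bg)
  if (is.factor(bg[[variable]])) {
    sweep_vals <- levels(bg[[variable]])
    env <- as.data.frame(base, optional = TRUE)[rep(1, length(sweep_vals)), ,
                                                drop = FALSE]
    env[[variable]] <- factor(sweep_vals, levels = levels(bg[[variable]]))
    data.frame(value = sweep_vals,
               prediction = predict(model, env, type = type))
  } else {
    nm <- fs$norms[[variable]]
    sweep_vals <- seq(nm["min"], nm["max"], length.out = n_points)
    env <- as.data.frame(base, optional = TRUE)[rep(1, n_points), ,
                                                drop = FALSE]
    env[[variable]] <- sweep_vals
    data.frame(value = sweep_vals,
               prediction = predict(model, env, type = type))
  }
}
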