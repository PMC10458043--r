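#' Sample background cells from a stack
#'
#' Draws a uniform sample *without replacement* of cells that are valid in
#' every layer.  Presence cells are eligible (no exclusion).  If fewer
#' valid cells exist than requested, all are used with a warning.
#'
#' @param stack A [raster_stack()].
#' @param n Sample size (default 2000).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `background_sample`: list with `env` (data.frame of layer
#'   values, factors for categorical layers) and `cells` (data.frame with
#'   `row`, `col`, `x`, `y`).
#' @export
sample_background <- function(stack, n = 2000L, seed = 1L) {
  stopifnot(inherits(stack, "raster_stack"))
  valid <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$values)))
  idx <- which(valid)
  if (!length(idx)) stop("no valid cells in stack", call. = FALSE)
  if (length(idx) < n) {
    warning(sprintf("only %d valid cells (< n = %d): using all of them",
                    length(idx), n), call. = FALSE)
    take <- idx
  } else {
    take <- withr::with_seed(seed, sort(sample(idx, n)))
  }
  nr <- stack$spec$n_rows
  row <- as.integer((take - 1) %% nr + 1)
  col <- as.integer((take - 1) %/% nr + 1)
  ctr <- cell_center(stack$spec, row, col)
  env <- lapply(stack$layers, function(l) {
    v <- l$values[cbind(row, col)]
    if (l$kind == "categorical")
      factor(v, levels = sort(unique(as.vector(l$values))))
    else v
  })
  structure(list(env = as.data.frame(env, optional = TRUE),
                 cells = data.frame(row = row, col = col, x = ctr$x,
                                    y = ctr$y)),
            class = "background_sample")
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("<background_sample> %d cells, %d variable(s)\n",
              nrow(x$env), ncol(x$env)))
  invisible(x)
}

#' Fit a presence-background maximum-entropy model
#'
#' Finds the distribution over the background sample with maximum entropy
#' subject to feature-expectation constraints at the presences —
#' equivalently, maximizes the L1-regularized training gain
#' \deqn{G(\lambda) = \overline{\lambda f(x_p)} -
#'   \log \sum_{bg} e^{\lambda f(x)} + \log n_{bg} -
#'   \sum_j \beta_j |\lambda_j|}
#' by cyclic coordinate descent with backtracking (the gain never
#' decreases; `G(0) = 0` by construction).  Fitting stops when a full
#' cycle improves the gain by less than the convergence threshold.
#'
#' @param presence_env data.frame of environment values at the presences.
#' @param background A `background_sample` from [sample_background()], or a
#'   plain data.frame of background environment values.
#' @param settings A [maxent_settings()].
#' @param beta Optional explicit L1 penalty (scalar or one value per
#'   feature), overriding [default_regularization()].
#' @return A `maxent_model`: feature set, weights `lambda`, `log_z`
#'   (log-partition over the background), `entropy` H of the fitted raw
#'   distribution, training `gain`, per-variable gain `credits`, the
#'   training data, and fit diagnostics.
#' @export
maxent <- function(presence_env, background,
                   settings = maxent_settings(), beta = NULL) {
  if (inherits(background, "background_sample")) {
    bg_env <- background$env
    bg_cells <- background$cells
  } else {
    bg_env <- as.data.frame(background)
    bg_cells <- NULL
  }
  presence_env <- as.data.frame(presence_env)
  m <- nrow(presence_env)
  if (m < 2) stop("need at least 2 presence records", call. = FALSE)
  if (!nrow(bg_env)) stop("background is empty", call. = FALSE)
  # harmonize factor levels across presence and background
  for (v in names(presence_env)) {
    if (is.factor(presence_env[[v]]) || is.factor(bg_env[[v]])) {
      levs <- sort(unique(c(as.character(presence_env[[v]]),
                            as.character(bg_env[[v]]))))
      presence_env[[v]] <- factor(as.character(presence_env[[v]]), levs)
      bg_env[[v]] <- factor(as.character(bg_env[[v]]), levs)
    }
  }
  fs <- build_features(presence_env, bg_env, settings)
  Fp <- eval_features(fs, presence_env)
  Fbg <- eval_features(fs, bg_env)
  if (is.null(beta))
    beta <- default_regularization(fs, m, settings$regularization_multiplier)
  else beta <- rep_len(beta, nrow(fs$defs))
  var_id <- match(fs$defs$var, fs$variables) - 1L
  fit <- cd_fit(Fp, Fbg, beta, var_id, length(fs$variables),
                settings$max_iterations, settings$convergence_threshold)
  credits <- as.numeric(fit$credits)
  names(credits) <- fs$variables
  structure(list(feature_set = fs, lambda = as.numeric(fit$lambda),
                 beta = beta, log_z = fit$log_z, entropy = fit$entropy,
                 gain = fit$gain, gain_path = as.numeric(fit$gain_path),
                 credits = credits, raw_bg = as.numeric(fit$raw_bg),
                 cycles = fit$cycles, converged = fit$converged,
                 settings = settings, presence_env = presence_env,
                 background_env = bg_env, background_cells = bg_cells),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d presences vs %d background, ",
                     "%d features (%d active)\n"),
              nrow(x$presence_env), nrow(x$background_env),
              length(x$lambda), sum(x$lambda != 0)))
  cat(sprintf("  regularized training gain %.4f, entropy %.4f, %d cycle(s)%s\n",
              x$gain, x$entropy, x$cycles,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Stores feature definitions, normalization constants, weights, entropy,
#' log-partition and settings so a model can be re-loaded and projected
#' without the training data.
#'
#' @param model A `maxent_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  doc <- list(defs = model$feature_set$defs,
              norms = model$feature_set$norms,
              variables = model$feature_set$variables,
              categorical = model$feature_set$categorical,
              classes = model$feature_set$classes,
              lambda = model$lambda, beta = model$beta,
              log_z = model$log_z, entropy = model$entropy,
              gain = model$gain,
              settings = unclass(model$settings))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path JSON path written by [write_maxent_model()].
#' @return A `maxent_model` (without training data; prediction and
#'   projection work, importance does not).
#' @export
read_maxent_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- structure(list(defs = doc$defs,
                       norms = lapply(doc$norms, function(v)
                         stats::setNames(as.numeric(v), c("min", "max"))),
                       variables = doc$variables,
                       categorical = doc$categorical,
                       classes = doc$classes),
                  class = "feature_set")
  structure(list(feature_set = fs, lambda = doc$lambda, beta = doc$beta,
                 log_z = doc$log_z, entropy = doc$entropy, gain = doc$gain,
                 settings = do.call(maxent_settings, doc$settings),
                 presence_env = NULL, background_env = NULL,
                 background_cells = NULL),
            class = "maxent_model")
}
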