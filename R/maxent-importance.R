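#' Variable importance: contribution, permutation, jackknife
#'
#' Three complementary views of a fitted model:
#' * **percent contribution** — during fitting, each coordinate update's
#'   gain increment is credited to the updated feature's source variable;
#'   per-variable totals are floored at zero and normalized to 100;
#' * **permutation importance** — one variable's values are permuted
#'   jointly across presence + background rows (seeded; optionally averaged
#'   over replicates), training AUC is recomputed with fixed weights, and
#'   the AUC drops (floored at 0) are normalized to 100;
#' * **jackknife** — the model is refit with only variable *v*
#'   (`gain_with_only`) and with all variables but *v* (`gain_without`),
#'   reporting regularized training gains against the full-model gain.
#'
#' @param model A `maxent_model` with training data attached.
#' @param seed Seed for the permutations (defaults to the model seed).
#' @param replicates Permutation replicates to average (default 1).
#' @param jackknife Set `FALSE` to skip the (costly) refits.
#' @return An `importance_report`: data.frame with one row per variable and
#'   columns `variable`, `percent_contribution`, `permutation_importance`,
#'   `gain_without`, `gain_with_only`; the full-model training gain is in
#'   `attr(, "full_gain")`.
#' @export
maxent_importance <- function(model, seed = NULL, replicates = 1L,
                              jackknife = TRUE) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$presence_env))
    stop("model carries no training data", call. = FALSE)
  if (is.null(seed)) seed <- model$settings$seed
  vars <- model$feature_set$variables
  used <- vars[vars %in% unique(model$feature_set$defs$var)]

  pc <- pmax(model$credits[used], 0)
  pc <- if (sum(pc) > 0) 100 * pc / sum(pc) else
    rep(100 / length(used), length(used))

  np <- nrow(model$presence_env)
  full_auc <- maxent_auc(model)
  drops <- vapply(seq_along(used), function(i) {
    v <- used[i]
    mean(vapply(seq_len(replicates), function(r) {
      all_env <- rbind(model$presence_env, model$background_env)
      perm <- withr::with_seed(seed + 1000L * (r - 1L) + i, {
        sample.int(nrow(all_env))
      })
      all_env[[v]] <- all_env[[v]][perm]
      sp <- predict(model, all_env[seq_len(np), , drop = FALSE], "raw")
      sb <- predict(model, all_env[-seq_len(np), , drop = FALSE], "raw")
      max(0, full_auc - maxent_auc(presence_scores = sp,
                                   background_scores = sb))
    }, 0))
  }, 0)
  pi <- if (sum(drops) > 0) 100 * drops / sum(drops) else
    rep(0, length(used))

  gw <- gwo <- rep(NA_real_, length(used))
  if (jackknife && length(used) >= 2) {
    for (i in seq_along(used)) {
      v <- used[i]
      only <- maxent(model$presence_env[, v, drop = FALSE],
                     model$background_env[, v, drop = FALSE],
                     model$settings)
      gwo[i] <- only$gain
      rest <- setdiff(used, v)
      wo <- maxent(model$presence_env[, rest, drop = FALSE],
                   model$background_env[, rest, drop = FALSE],
                   model$settings)
      gw[i] <- wo$gain
    }
  }
  out <- data.frame(variable = used, percent_contribution = as.numeric(pc),
                    permutation_importance = as.numeric(pi),
                    gain_without = gw, gain_with_only = gwo)
  attr(out, "full_gain") <- model$gain
  class(out) <- c("importance_report", "data.frame")
  out
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> full-model training gain %.4f\n",
              attr(x, "full_gain")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write an importance report to CSV
#'
#' Mirrors the layout of a percent-contribution / permutation-importance /
#' jackknife-gain table.
#'
#' @param report An `importance_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
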