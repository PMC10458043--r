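#' Default pipeline configuration
#'
#' All analysis parameters in one validated structure.  Two input modes:
#' `inputs$mode = "synthetic"` (a [synthetic_scenario()] generates every
#' input) or `"files"` (paths to rasters, occurrences and legends).  The
#' single global `seed` fans out deterministically to per-stage seeds
#' (polynomial hash of stage name mixed with the seed).
#'
#' @param seed Global seed.
#' @return Named list of configuration defaults.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    output_dir = "ecosuit_out",
    inputs = list(mode = "synthetic", scenario = list(),
                  rasters = NULL, occurrences = NULL, legend = NULL),
    collinearity = list(cutoff = 0.8, representative = "lexicographic"),
    maxent = list(n_background = 2000L, max_iterations = 2000L,
                  convergence_threshold = 1e-5,
                  regularization_multiplier = 1, prevalence_tau = 0.5,
                  feature_classes = "auto", hinge_knots = 50L,
                  threshold_knots = 50L),
    threshold = list(percentile = 10),
    lulc = list(level = 1),
    stages = c("simulate", "thin", "select-vars", "fit", "importance",
               "project", "threshold", "classify", "presence-change",
               "lulc-areas", "lulc-transitions")
  )
}

#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON.  Unknown top-level or section keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Config file path.
#' @return Validated config list (defaults merged in).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("config must be .yaml/.yml or .json", call. = FALSE)
  merge_config(cfg)
}

merge_config <- function(cfg) {
  base <- default_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in c("inputs", "collinearity", "maxent", "threshold", "lulc")) {
    if (!is.null(cfg[[sec]])) {
      extra <- setdiff(names(cfg[[sec]]), names(base[[sec]]))
      if (length(extra))
        stop("unknown key(s) in config section '", sec, "': ",
             paste(extra, collapse = ", "), call. = FALSE)
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    }
  }
  for (k in setdiff(names(cfg),
                    c("inputs", "collinearity", "maxent", "threshold",
                      "lulc")))
    base[[k]] <- cfg[[k]]
  base$seed <- as.integer(base$seed)
  base
}

#' Deterministic per-stage seed
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer below 2^31, a stable hash of (stage, seed).
#' @export
stage_seed <- function(seed, stage) {
  h <- as.integer(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

log_stage <- function(stage, msg) {
  message(sprintf("[ecosuit] %s: %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) ->
#' thin -> select-vars -> fit -> importance -> project current/future ->
#' threshold -> classify -> presence-change; lulc-areas ->
#' lulc-transitions.  Every artifact is written under `output_dir` and
#' recorded in a manifest (file, stage, md5); rerunning with the same
#' config and seed reproduces identical outputs.
#'
#' @param config A config list (see [default_config()], [read_config()]),
#'   or a path to a config file.
#' @param stages Optional subset of stage names to run.
#' @return The manifest data.frame (also written as `manifest.csv`),
#'   invisibly; stage results are attached as `attr(, "results")`.
#' @export
run_pipeline <- function(config = default_config(), stages = NULL) {
  if (is.character(config)) config <- read_config(config)
  else config <- merge_config(config)
  if (is.null(stages)) stages <- config$stages
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), stage = character(0),
                         md5 = character(0))
  res <- list()
  emit <- function(path, stage) {
    manifest[nrow(manifest) + 1L, ] <<- list(basename(path), stage,
                                             unname(tools::md5sum(path)))
  }
  out <- function(f) file.path(config$output_dir, f)
  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  scn <- do.call(synthetic_scenario,
                 c(config$inputs$scenario,
                   list(seed = stage_seed(config$seed, "simulate"))))
  # ---- inputs ----
  if (config$inputs$mode == "synthetic") {
    tryCatch({
      res$stack <- gen_env_stack(scn)
      res$truth <- true_suitability(scn, res$stack)
      res$occ <- gen_occurrences(res$stack, res$truth, scn$m,
                                 stage_seed(config$seed, "occurrences"))
      res$future_stack <- gen_env_stack(scn, shift = scn$future_shift)
      res$lulc <- gen_lulc_series(scn)
      if ("simulate" %in% stages) {
        for (l in res$stack$layers) {
          p <- out(paste0(l$name, ".asc")); write_ascii_grid(l, p)
          emit(p, "simulate")
        }
        p <- out("occurrences.csv"); write_occurrences(res$occ, p)
        emit(p, "simulate")
        log_stage("simulate", sprintf("%d layers, %d occurrences, %d epochs",
                  length(res$stack$layers), nrow(res$occ),
                  length(res$lulc)))
      }
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      paths <- config$inputs$rasters
      res$stack <- raster_stack(lapply(names(paths), function(nm)
        read_ascii_grid(paths[[nm]],
                        kind = if (nm %in% c("soil", "lulc"))
                          "categorical" else "continuous", name = nm)))
      res$occ <- load_occurrences(config$inputs$occurrences)
    }, error = function(e) fail("load", e))
  }

  if ("thin" %in% stages) tryCatch({
    res$occ_thin <- thin_to_grid(res$occ, res$stack$spec)
    p <- out("occurrences_thinned.csv")
    write_occurrences(res$occ_thin, p); emit(p, "thin")
    res$hull <- convex_hull(res$occ_thin)
    p <- out("occurrence_area.wkt")
    writeLines(polygon_to_wkt(res$hull), p); emit(p, "thin")
    log_stage("thin", sprintf("%d -> %d records, hull area %.3g km^2",
              nrow(res$occ), nrow(res$occ_thin), res$hull$area / 1e6))
  }, error = function(e) fail("thin", e))
  occ_use <- if (!is.null(res$occ_thin)) res$occ_thin else res$occ

  if ("select-vars" %in% stages) tryCatch({
    rep0 <- correlation_matrix(res$stack)
    res$corr <- remove_collinear(rep0, config$collinearity$cutoff,
                                 config$collinearity$representative,
                                 seed = stage_seed(config$seed, "select-vars"))
    p <- out("correlation_matrix.csv")
    write_correlation_report(res$corr, p, out("retained_variables.txt"))
    emit(p, "select-vars"); emit(out("retained_variables.txt"), "select-vars")
    log_stage("select-vars", paste("retained:",
              paste(res$corr$retained, collapse = ", ")))
  }, error = function(e) fail("select-vars", e))

  vars <- if (!is.null(res$corr)) setdiff(res$corr$retained, "dem")
          else setdiff(names(res$stack$layers), "dem")

  if ("fit" %in% stages) tryCatch({
    model_stack <- raster_stack(res$stack$layers[vars])
    settings <- do.call(maxent_settings,
                        c(config$maxent,
                          list(seed = stage_seed(config$seed, "fit"))))
    res$background <- sample_background(model_stack, settings$n_background,
                                        settings$seed)
    pres_env <- env_at_points(model_stack, occ_use$x, occ_use$y)
    res$model <- maxent(pres_env, res$background, settings)
    res$auc <- maxent_auc(res$model)
    p <- out("model.json"); write_maxent_model(res$model, p); emit(p, "fit")
    log_stage("fit", sprintf("gain %.4f, training AUC %.3f (no held-out %s",
              res$model$gain, res$auc, "evaluation: training AUC only)"))
  }, error = function(e) fail("fit", e))

  if ("importance" %in% stages && !is.null(res$model)) tryCatch({
    res$importance <- maxent_importance(res$model,
      seed = stage_seed(config$seed, "importance"))
    p <- out("importance.csv")
    write_importance_report(res$importance, p); emit(p, "importance")
    log_stage("importance", paste("top:",
      res$importance$variable[which.max(
        res$importance$permutation_importance)]))
  }, error = function(e) fail("importance", e))

  if ("project" %in% stages && !is.null(res$model)) tryCatch({
    res$suit_current <- project_suitability(res$model, res$stack)
    p <- out("suitability_current.asc")
    write_ascii_grid(res$suit_current, p); emit(p, "project")
    if (!is.null(res$future_stack)) {
      res$suit_future <- project_suitability(res$model, res$future_stack)
      p <- out("suitability_future.asc")
      write_ascii_grid(res$suit_future, p); emit(p, "project")
    }
  }, error = function(e) fail("project", e))

  if ("threshold" %in% stages && !is.null(res$model)) tryCatch({
    res$threshold <- percentile_threshold(res$model,
                                          q = config$threshold$percentile)
    res$binary_current <- binarize(res$suit_current, res$threshold)
    p <- out("presence_current.asc")
    write_ascii_grid(res$binary_current, p); emit(p, "threshold")
    if (!is.null(res$suit_future)) {
      res$binary_future <- binarize(res$suit_future, res$threshold)
      p <- out("presence_future.asc")
      write_ascii_grid(res$binary_future, p); emit(p, "threshold")
    }
    log_stage("threshold", sprintf("%dth percentile cloglog threshold %.3f",
              config$threshold$percentile, res$threshold))
  }, error = function(e) fail("threshold", e))

  if ("classify" %in% stages && !is.null(res$suit_current)) tryCatch({
    cls_c <- classify_equal_interval(res$suit_current, "current")
    res$class_table <- cls_c$table
    p <- out("suitability_classes_current.csv")
    utils::write.csv(cls_c$table, p, row.names = FALSE); emit(p, "classify")
    if (!is.null(res$suit_future)) {
      cls_f <- classify_equal_interval(res$suit_future, "future")
      res$class_table <- rbind(res$class_table, cls_f$table)
      p <- out("suitability_classes_future.csv")
      utils::write.csv(cls_f$table, p, row.names = FALSE)
      emit(p, "classify")
    }
  }, error = function(e) fail("classify", e))

  if ("presence-change" %in% stages && !is.null(res$binary_future))
    tryCatch({
      res$change <- presence_change(res$binary_current, res$binary_future)
      p <- out("presence_change.csv")
      utils::write.csv(data.frame(metric = c(names(res$change)[1:4],
                                             names(res$change$crosstab)),
                                  value = c(unlist(res$change[1:4]),
                                            res$change$crosstab)),
                       p, row.names = FALSE)
      emit(p, "presence-change")
      log_stage("presence-change", sprintf("relative change %+.1f%%",
                res$change$relative_change_pct))
    }, error = function(e) fail("presence-change", e))

  if ("lulc-areas" %in% stages && !is.null(res$lulc)) tryCatch({
    masks <- list(study_area = NULL)
    if (!is.null(res$hull)) masks$occurrence_area <- res$hull
    res$lulc_tables <- list()
    for (mn in names(masks)) {
      tabs <- lapply(seq_along(res$lulc), function(e)
        class_area_table(res$lulc[[e]], masks[[mn]],
                         epoch = sprintf("epoch%d", e)))
      names(tabs) <- sprintf("epoch%d", seq_along(res$lulc))
      res$lulc_tables[[mn]] <- tabs
      wide <- data.frame(class = tabs[[1]]$class)
      for (e in names(tabs)) wide[[e]] <- tabs[[e]]$percent
      p <- out(sprintf("lulc_areas_%s.csv", mn))
      utils::write.csv(wide, p, row.names = FALSE); emit(p, "lulc-areas")
      deltas <- table_change(tabs[[1]], tabs[[length(tabs)]])
      p <- out(sprintf("lulc_change_%s.csv", mn))
      utils::write.csv(deltas, p, row.names = FALSE); emit(p, "lulc-areas")
    }
  }, error = function(e) fail("lulc-areas", e))

  if ("lulc-transitions" %in% stages && !is.null(res$lulc)) tryCatch({
    mask <- res$hull
    tm <- transition_matrix(res$lulc[[1]], res$lulc[[length(res$lulc)]],
                            mask)
    res$transitions <- tm
    p <- out("lulc_transitions.csv")
    utils::write.csv(tm$percent, p); emit(p, "lulc-transitions")
    log_stage("lulc-transitions", sprintf("persistence %.1f%%",
              tm$persistence_pct))
  }, error = function(e) fail("lulc-transitions", e))

  mpath <- out("manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  attr(manifest, "results") <- res
  invisible(manifest)
}
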