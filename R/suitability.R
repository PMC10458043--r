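#' Percentile training-presence threshold
#'
#' The q-th percentile of the cloglog predictions at the training
#' presences, by the nearest-rank rule: the value at index
#' `ceiling(q/100 * m)` of the sorted predictions (so the threshold is an
#' attained prediction value, and at most q% of training presences fall
#' strictly below it).  An interpolated percentile is available by flag.
#'
#' @param model A `maxent_model`.
#' @param presence_env Presence environment (defaults to training data).
#' @param q Percentile (default 10, the "10th percentile training presence"
#'   rule).
#' @param interpolate Use `stats::quantile` type-7 interpolation instead of
#'   nearest rank.
#' @param predictions Optionally, precomputed presence predictions (the
#'   model is then not consulted).
#' @return The threshold, a single number in `[0, 1]`.
#' @export
percentile_threshold <- function(model, presence_env = NULL, q = 10,
                                 interpolate = FALSE, predictions = NULL) {
  pred <- if (!is.null(predictions)) predictions else {
    if (is.null(presence_env)) presence_env <- model$presence_env
    predict(model, presence_env, type = "cloglog")
  }
  if (!length(pred)) stop("no presences", call. = FALSE)
  if (interpolate) return(as.numeric(stats::quantile(pred, q / 100)))
  s <- sort(pred)
  s[max(1L, ceiling(q / 100 * length(s)))]
}

#' Binarize a suitability map at a threshold
#'
#' Cells with value `>= threshold` become 1 (presence; values under the
#' threshold are unsuitable, and a cell exactly at the threshold counts as
#' presence), others 0; nodata is preserved.
#'
#' @param map A continuous [grid_layer()] with values in `[0, 1]`.
#' @param threshold Number in `[0, 1]`.
#' @return A `grid_layer` (categorical 0/1) with attributes `threshold`
#'   and `source_map`.
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "grid_layer"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  v <- map$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  bl <- grid_layer(map$spec, out, name = paste0(map$name, "_binary"),
                   kind = "categorical")
  attr(bl, "threshold") <- threshold
  attr(bl, "source_map") <- map$name
  bl
}

#' Five-class equal-interval suitability classification
#'
#' Fixed-width bins of a 0–1 suitability map: class 1 `[0, 0.2)` non-
#' suitable, 2 `[0.2, 0.4)` low, 3 `[0.4, 0.6)` regular, 4 `[0.6, 0.8)`
#' medium, 5 `[0.8, 1.0]` high (half-open bins, top bin closed):
#' `k = min(floor(v / 0.2) + 1, 5)`.
#'
#' @param map A continuous [grid_layer()]; values outside `[0, 1]` are an
#'   error.
#' @param scenario Tag recorded in the class table (e.g. `"current"`).
#' @return list with `layer` (categorical `grid_layer` of classes 1–5) and
#'   `table` (data.frame: class, label, cells, percent; percentages sum to
#'   100).
#' @export
classify_equal_interval <- function(map, scenario = "current") {
  stopifnot(inherits(map, "grid_layer"))
  v <- map$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values outside [0, 1]", call. = FALSE)
  # findInterval, not floor(v/0.2): 0.6/0.2 is 2.9999... in binary floating
  # point and would misclassify exact bin edges
  k <- matrix(findInterval(v, c(0.2, 0.4, 0.6, 0.8)) + 1,
              nrow(v), ncol(v))
  k[is.na(v)] <- NA_real_
  layer <- grid_layer(map$spec, k, name = paste0(map$name, "_class"),
                      kind = "categorical")
  labels <- c("non-suitable", "low", "regular", "medium", "high")
  counts <- vapply(1:5, function(cl) sum(k == cl, na.rm = TRUE), 0L)
  nvalid <- sum(counts)
  if (!nvalid) stop("no valid cells", call. = FALSE)
  tab <- data.frame(class = 1:5, label = labels, cells = counts,
                    percent = 100 * counts / nvalid,
                    scenario = scenario)
  list(layer = layer, table = tab)
}

#' Present-vs-future presence change report
#'
#' Compares two aligned binary presence/absence maps: presence share of
#' each, the absolute difference in percentage points, the relative change
#' `100 (A_future - A_current) / A_current`, and the 2x2 cross-tabulation
#' (stable presence, gain, loss, stable absence) over cells valid in both
#' maps.
#'
#' @param current,future Binary [grid_layer()]s from [binarize()] on the
#'   same grid.
#' @return list with `current_pct`, `future_pct`, `difference_pp`,
#'   `relative_change_pct`, and `crosstab` (named counts).
#' @export
presence_change <- function(current, future) {
  stopifnot(inherits(current, "grid_layer"), inherits(future, "grid_layer"))
  if (!specs_aligned(current$spec, future$spec))
    stop("maps are not aligned", call. = FALSE)
  a <- as.vector(current$values); b <- as.vector(future$values)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no jointly valid cells", call. = FALSE)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  cur <- sum(a == 1); fut <- sum(b == 1)
  rel <- if (cur > 0) 100 * (fut - cur) / cur else NA_real_
  list(current_pct = 100 * cur / n,
       future_pct = 100 * fut / n,
       difference_pp = 100 * (fut - cur) / n,
       relative_change_pct = rel,
       crosstab = c(stable_presence = sum(a == 1 & b == 1),
                    gain = sum(a == 0 & b == 1),
                    loss = sum(a == 1 & b == 0),
                    stable_absence = sum(a == 0 & b == 0)))
}
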