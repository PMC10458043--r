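#' Resample a layer onto a target grid
#'
#' Supported methods:
#' * `nearest` — value of the source cell containing each target cell
#'   center (only method besides `block_mode` allowed for categorical
#'   layers);
#' * `bilinear` — interpolation between the four surrounding source cell
#'   centers (continuous only);
#' * `block_mean` / `block_mode` — aggregate all source cells whose centers
#'   fall inside the target cell.
#'
#' Nodata is never interpolated into valid cells: for `bilinear` and the
#' block methods, any window containing nodata (or falling outside the
#' source grid) yields nodata.
#'
#' @param layer A [grid_layer()].
#' @param target Target [grid_spec()]; must share the source CRS tag.
#' @param method One of `"nearest"`, `"bilinear"`, `"block_mean"`,
#'   `"block_mode"`.
#' @return A [grid_layer()] on `target`.
#' @export
resample <- function(layer, target,
                     method = c("nearest", "bilinear", "block_mean",
                                "block_mode")) {
  method <- match.arg(method)
  stopifnot(inherits(layer, "grid_layer"), inherits(target, "grid_spec"))
  if (!identical(layer$spec$crs_tag, target$crs_tag))
    stop("CRS mismatch between source and target grid", call. = FALSE)
  if (layer$kind == "categorical" && !method %in% c("nearest", "block_mode"))
    stop("categorical layers can only be resampled with nearest or ",
         "block_mode", call. = FALSE)
  src <- layer$spec
  if (specs_aligned(src, target) && method == "nearest")
    return(layer)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  # target cell centers
  tx <- target$origin_x + (seq_len(target$n_cols) - 0.5) * target$cell_size
  ty <- target$origin_y - (seq_len(target$n_rows) - 0.5) * target$cell_size
  if (method == "nearest") {
    sc <- floor((tx - src$origin_x) / src$cell_size) + 1
    sr <- floor((src$origin_y - ty) / src$cell_size) + 1
    okc <- sc >= 1 & sc <= src$n_cols
    okr <- sr >= 1 & sr <= src$n_rows
    for (i in which(okr)) {
      out[i, okc] <- layer$values[sr[i], sc[okc]]
    }
  } else if (method == "bilinear") {
    # fractional position in source cell-center coordinates
    gx <- (tx - src$origin_x) / src$cell_size - 0.5   # 0 at col-1 center
    gy <- (src$origin_y - ty) / src$cell_size - 0.5
    c0 <- floor(gx) + 1; r0 <- floor(gy) + 1
    fx <- gx - (c0 - 1); fy <- gy - (r0 - 1)
    for (i in seq_len(target$n_rows)) {
      r <- r0[i]; wy <- fy[i]
      if (r < 1 || r + 1 > src$n_rows) next
      for (j in seq_len(target$n_cols)) {
        cc <- c0[j]
        if (cc < 1 || cc + 1 > src$n_cols) next
        q <- layer$values[r:(r + 1), cc:(cc + 1)]
        if (anyNA(q)) next
        wx <- fx[j]
        out[i, j] <- (1 - wy) * ((1 - wx) * q[1, 1] + wx * q[1, 2]) +
          wy * ((1 - wx) * q[2, 1] + wx * q[2, 2])
      }
    }
  } else {
    # block aggregation: source cell centers inside each target cell
    sx <- src$origin_x + (seq_len(src$n_cols) - 0.5) * src$cell_size
    sy <- src$origin_y - (seq_len(src$n_rows) - 0.5) * src$cell_size
    tc <- floor((sx - target$origin_x) / target$cell_size) + 1
    tr <- floor((target$origin_y - sy) / target$cell_size) + 1
    for (i in seq_len(target$n_rows)) {
      ri <- which(tr == i)
      if (!length(ri)) next
      for (j in seq_len(target$n_cols)) {
        cj <- which(tc == j)
        if (!length(cj)) next
        w <- layer$values[ri, cj, drop = FALSE]
        if (anyNA(w)) next
        out[i, j] <- if (method == "block_mean") mean(w) else {
          tab <- table(as.vector(w))
          as.numeric(names(tab)[which.max(tab)])  # ties: smallest code
        }
      }
    }
  }
  grid_layer(target, out, name = layer$name, kind = layer$kind,
             nodata = layer$nodata)
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Gradients use Horn's 3x3 weighted finite differences.  Slope is returned
#' in percent (100 * rise/run); aspect is the downslope azimuth in degrees
#' clockwise from north, in `[0, 360)`.  Border cells and cells with any
#' missing neighbour are nodata; flat cells (zero gradient) get slope 0 and
#' aspect nodata, so they cannot pollute circular statistics.
#'
#' @param dem A continuous [grid_layer()] of elevations, at least 3x3.
#' @return list with elements `slope` and `aspect` (both `grid_layer`).
#' @export
derive_slope_aspect <- function(dem) {
  stopifnot(inherits(dem, "grid_layer"))
  if (dem$kind != "continuous") stop("DEM must be continuous", call. = FALSE)
  s <- dem$spec
  if (s$n_rows < 3 || s$n_cols < 3)
    stop("DEM must be at least 3 x 3", call. = FALSE)
  z <- dem$values
  nr <- s$n_rows; nc <- s$n_cols
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  # 3x3 neighbourhood: a b c / d e f / g h i (a = NW)
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc <- z[ri - 1, ci + 1]
  d <- z[ri, ci - 1];                          f <- z[ri, ci + 1]
  g <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i2 <- z[ri + 1, ci + 1]
  dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + g)) / (8 * s$cell_size)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i2)) / (8 * s$cell_size)  # northward
  grad <- sqrt(dzdx^2 + dzdy^2)
  slope_in <- 100 * grad
  # downslope azimuth clockwise from north
  asp_in <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  asp_in[grad == 0] <- NA_real_
  slope <- matrix(NA_real_, nr, nc); aspect <- matrix(NA_real_, nr, nc)
  slope[ri, ci] <- slope_in
  aspect[ri, ci] <- asp_in
  list(slope = grid_layer(s, slope, name = "slope", kind = "continuous"),
       aspect = grid_layer(s, aspect, name = "aspect", kind = "continuous"))
}

#' Per-layer summary statistics
#'
#' Min/max/mean/standard deviation per layer over valid cells (optionally
#' restricted to a mask), and separately over the cells containing a set of
#' points — the layout of a study-area vs species-occurrence summary table.
#'
#' @param stack A [raster_stack()].
#' @param mask Optional logical matrix (`TRUE` = inside) on the stack grid.
#' @param points Optional data.frame with `x`, `y` columns; all points must
#'   fall inside the grid.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return data.frame with columns `layer`, `scope` (`"area"`/`"points"`),
#'   `n`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_stack <- function(stack, mask = NULL, points = NULL,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(stack, "raster_stack"))
  sdfun <- function(v) {
    if (sd_type == "sample") stats::sd(v)
    else sqrt(mean((v - mean(v))^2))
  }
  one <- function(v, layer, scope) {
    v <- v[!is.na(v)]
    if (!length(v))
      stop("no valid cells for layer '", layer, "' (", scope, ")",
           call. = FALSE)
    data.frame(layer = layer, scope = scope, n = length(v), min = min(v),
               max = max(v), mean = mean(v),
               sd = if (length(v) > 1 || sd_type == "population") sdfun(v)
                    else 0)
  }
  res <- list()
  for (l in stack$layers) {
    v <- l$values
    if (!is.null(mask)) v <- v[mask]
    res[[length(res) + 1L]] <- one(as.vector(v), l$name, "area")
  }
  if (!is.null(points)) {
    cells <- cell_of_point(stack$spec, points$x, points$y)
    if (anyNA(cells$row))
      stop("points outside grid extent", call. = FALSE)
    idx <- cbind(cells$row, cells$col)
    for (l in stack$layers)
      res[[length(res) + 1L]] <- one(l$values[idx], l$name, "points")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
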