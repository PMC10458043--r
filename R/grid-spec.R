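#' Define a raster grid geometry
#'
#' A `grid_spec` fixes the geometry every layer in an analysis must share:
#' the projected coordinate of the upper-left corner, a square cell size in
#' metres, the grid dimensions and an opaque CRS tag.  Two specs are
#' *aligned* when all five fields are equal; the package validates alignment
#' everywhere but never reprojects.
#'
#' Cell `(1, 1)` is the top-left cell.  A point `(x, y)` maps to the cell
#' `(floor((origin_y - y) / cell_size) + 1, floor((x - origin_x) / cell_size) + 1)`,
#' so cells are half-open: a point on a shared vertical edge belongs to the
#' cell on its right, a point on a shared horizontal edge to the cell below.
#'
#' @param origin_x,origin_y Projected coordinates (metres) of the grid's
#'   upper-left corner.
#' @param cell_size Cell edge length in metres (> 0, square cells).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param crs_tag Opaque CRS identifier string (e.g. `"EPSG:3763"`).
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(0, 2000, 100, 20, 20, "EPSG:3763")
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                      crs_tag = "LOCAL") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), is.numeric(cell_size))
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive finite number", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be integers >= 1", call. = FALSE)
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = n_rows, n_cols = n_cols,
                 crs_tag = as.character(crs_tag)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m, origin (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_tag))
  invisible(x)
}

#' Test whether two grid specs are aligned
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` iff all fields (origin, cell size, dimensions, CRS) match.
#' @export
specs_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    identical(a$crs_tag, b$crs_tag)
}

#' Map projected points to grid cells
#'
#' Applies the half-open cell convention of [grid_spec()].  Cells are
#' returned 1-based; points outside the grid get `NA` row/col.
#'
#' @param spec A `grid_spec`.
#' @param x,y Numeric coordinate vectors (metres).
#' @return A data.frame with integer columns `row`, `col` (NA if outside).
#' @export
cell_of_point <- function(spec, x, y) {
  stopifnot(inherits(spec, "grid_spec"), length(x) == length(y))
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > spec$n_rows | col < 1 | col > spec$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centers
#'
#' @param spec A `grid_spec`.
#' @param row,col 1-based cell indices (vectors of equal length).
#' @return data.frame with numeric `x`, `y` at the cell centers.
#' @export
cell_center <- function(spec, row, col) {
  stopifnot(inherits(spec, "grid_spec"))
  data.frame(x = spec$origin_x + (col - 0.5) * spec$cell_size,
             y = spec$origin_y - (row - 0.5) * spec$cell_size)
}

#' Construct a raster layer
#'
#' A `grid_layer` couples a value matrix to a [grid_spec()].  Missing cells
#' are stored as `NA`; the `nodata` sentinel is only used when writing to
#' disk.  Categorical layers hold integer class codes.
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix of dimension `n_rows x n_cols` (row 1 = top).
#' @param name Layer name, e.g. `"BIO4"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param nodata Sentinel written for `NA` cells on export (default -9999).
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(spec, values, name = "layer",
                       kind = c("continuous", "categorical"),
                       nodata = -9999) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop(sprintf("values must be %d x %d, got %d x %d", spec$n_rows,
                 spec$n_cols, nrow(values), ncol(values)), call. = FALSE)
  v <- values
  storage.mode(v) <- "double"
  if (any(is.infinite(v)))
    stop("layer values must be finite or NA", call. = FALSE)
  if (kind == "categorical") {
    ok <- is.na(v) | v == round(v)
    if (!all(ok))
      stop("categorical layer contains non-integer codes", call. = FALSE)
  }
  structure(list(spec = spec, name = as.character(name), kind = kind,
                 values = v, nodata = nodata),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<grid_layer> '%s' (%s), %d x %d, %d valid cells\n",
              x$name, x$kind, x$spec$n_rows, x$spec$n_cols, nv))
  invisible(x)
}

#' Bundle aligned layers into a stack
#'
#' @param ... `grid_layer` objects, or a single list of them.
#' @return An object of class `raster_stack` (named list of layers).
#' @export
raster_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "grid_layer"))
    layers <- layers[[1]]
  if (!length(layers)) stop("empty stack", call. = FALSE)
  if (!all(vapply(layers, inherits, TRUE, "grid_layer")))
    stop("all elements must be grid_layer objects", call. = FALSE)
  nms <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nms))
    stop("layer names must be unique: ", paste(nms[duplicated(nms)],
         collapse = ", "), call. = FALSE)
  spec <- layers[[1]]$spec
  for (l in layers[-1])
    if (!specs_aligned(spec, l$spec))
      stop("layer '", l$name, "' is not aligned with the stack grid",
           call. = FALSE)
  names(layers) <- nms
  structure(list(spec = spec, layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' Extract layer values at point locations
#'
#' Looks up the cell containing each point and returns one row per point.
#' Categorical layers come back as factors (levels = codes present in the
#' layer).
#'
#' @param stack A `raster_stack`.
#' @param x,y Projected point coordinates.
#' @return data.frame, one column per layer, one row per point.
#' @export
env_at_points <- function(stack, x, y) {
  stopifnot(inherits(stack, "raster_stack"))
  cells <- cell_of_point(stack$spec, x, y)
  if (anyNA(cells$row))
    stop("points outside grid extent at rows: ",
         paste(which(is.na(cells$row)), collapse = ", "), call. = FALSE)
  idx <- cbind(cells$row, cells$col)
  out <- lapply(stack$layers, function(l) {
    v <- l$values[idx]
    if (l$kind == "categorical")
      factor(v, levels = sort(unique(as.vector(l$values))))
    else v
  })
  as.data.frame(out, optional = TRUE)
}
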