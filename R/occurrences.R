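#' Load species occurrences from CSV
#'
#' Reads projected x/y presence points, preserving file order.  Malformed
#' rows (missing or non-numeric coordinates) are an error that names the
#' offending data rows.
#'
#' @param path CSV path.
#' @param x_col,y_col Column names holding the projected coordinates.
#' @param source_tag Provenance label attached to every record; defaults to
#'   the file name.
#' @return An `occurrence_set`: data.frame with columns `x`, `y`, `source`.
#' @export
load_occurrences <- function(path, x_col = "x", y_col = "y",
                             source_tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(source_tag)) source_tag <- basename(path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no occurrence records in ", path, call. = FALSE)
    return(occurrence_set(numeric(0), numeric(0), source_tag))
  }
  miss <- setdiff(c(x_col, y_col), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- suppressWarnings(as.numeric(df[[x_col]]))
  y <- suppressWarnings(as.numeric(df[[y_col]]))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("non-numeric or missing coordinates at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  occurrence_set(x, y, source_tag)
}

#' Construct an occurrence set
#'
#' @param x,y Finite projected coordinates (metres), order preserved.
#' @param source Provenance tag, recycled to one per record.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(x, y, source = "manual") {
  stopifnot(length(x) == length(y))
  if (length(x) && any(!is.finite(x) | !is.finite(y)))
    stop("coordinates must be finite", call. = FALSE)
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       source = rep_len(as.character(source),
                                        length(x))),
            class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records from %d source(s)\n", nrow(x),
              length(unique(x$source))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Combine occurrence sets
#'
#' @param ... `occurrence_set` objects; record order is first set first.
#' @return The pooled `occurrence_set`.
#' @export
combine_occurrences <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "occurrence_set")))
  out <- do.call(rbind, lapply(sets, as.data.frame))
  occurrence_set(out$x, out$y, out$source)
}

#' Thin occurrences to one record per grid cell
#'
#' Reduces clustered presence records so that at most one remains in each
#' cell of the analysis grid, attenuating spatial autocorrelation.  Within a
#' cell the *first* record in input order is kept (deterministic
#' tie-break); the operation is idempotent.
#'
#' @param occ An `occurrence_set`.
#' @param spec The analysis [grid_spec()] (typically the environmental
#'   grid itself).
#' @return Thinned `occurrence_set`.
#' @export
thin_to_grid <- function(occ, spec) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(spec, "grid_spec"))
  if (!nrow(occ)) return(occ)
  cells <- cell_of_point(spec, occ$x, occ$y)
  out_rows <- which(is.na(cells$row))
  if (length(out_rows))
    stop("occurrence(s) outside grid extent at record(s): ",
         paste(out_rows, collapse = ", "), call. = FALSE)
  key <- (cells$row - 1) * spec$n_cols + cells$col
  keep <- !duplicated(key)
  occurrence_set(occ$x[keep], occ$y[keep], occ$source[keep])
}

#' Convex hull of an occurrence set
#'
#' Minimum bounding convex polygon of the points; its area (shoelace
#' formula) defines the species occurrence area used as an analysis mask.
#'
#' @param occ An `occurrence_set` with at least 3 non-collinear points.
#' @return An `area_polygon`: list with `vertices` (counter-clockwise open
#'   ring data.frame, a subset of the input points) and `area` in m^2.
#' @export
convex_hull <- function(occ) {
  stopifnot(inherits(occ, "occurrence_set"))
  pts <- unique(data.frame(x = occ$x, y = occ$y))
  if (nrow(pts) < 3)
    stop("convex hull needs at least 3 distinct points", call. = FALSE)
  idx <- grDevices::chull(pts$x, pts$y)   # clockwise order
  vert <- pts[rev(idx), , drop = FALSE]   # counter-clockwise
  rownames(vert) <- NULL
  a <- shoelace_area(vert$x, vert$y)
  if (a <= 0)
    stop("points are collinear: hull has zero area", call. = FALSE)
  area_polygon(vert)
}

#' Construct a polygon with its shoelace area
#'
#' @param vertices data.frame with `x`, `y`; open ring (first vertex not
#'   repeated), counter-clockwise.
#' @return `area_polygon` object.
#' @export
area_polygon <- function(vertices) {
  stopifnot(is.data.frame(vertices), nrow(vertices) >= 3)
  structure(list(vertices = vertices,
                 area = shoelace_area(vertices$x, vertices$y)),
            class = "area_polygon")
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @export
print.area_polygon <- function(x, ...) {
  cat(sprintf("<area_polygon> %d vertices, area %.6g m^2\n",
              nrow(x$vertices), x$area))
  invisible(x)
}

#' Point-in-polygon test (ray casting)
#'
#' Cell-center mask membership test; points exactly on an edge count as
#' inside.
#'
#' @param poly An `area_polygon`.
#' @param x,y Point coordinate vectors.
#' @return Logical vector.
#' @export
point_in_polygon <- function(poly, x, y) {
  v <- poly$vertices
  n <- nrow(v)
  px <- v$x; py <- v$y
  vapply(seq_along(x), function(k) {
    xp <- x[k]; yp <- y[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
      # on-edge check
      cross <- (xj - xi) * (yp - yi) - (yj - yi) * (xp - xi)
      if (abs(cross) < 1e-9 * max(1, abs(xj - xi), abs(yj - yi)) &&
          xp >= min(xi, xj) - 1e-12 && xp <= max(xi, xj) + 1e-12 &&
          yp >= min(yi, yj) - 1e-12 && yp <= max(yi, yj) + 1e-12)
        return(TRUE)
      if ((yi > yp) != (yj > yp) &&
          xp < (xj - xi) * (yp - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
    inside
  }, logical(1))
}

#' Export a polygon as WKT text
#'
#' @param poly An `area_polygon`.
#' @return A `POLYGON ((...))` WKT string (closed ring).
#' @export
polygon_to_wkt <- function(poly) {
  v <- poly$vertices
  ring <- rbind(v, v[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", ring$x, ring$y), collapse = ", "))
}

#' Write occurrences to CSV
#'
#' @param occ An `occurrence_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
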