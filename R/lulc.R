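#' Load a hierarchical LULC legend
#'
#' A legend maps raster class codes to names at two levels of a
#' hierarchical nomenclature: a coarse level-1 class (e.g. "Forests") and a
#' detailed level-4 class (e.g. "Forests-Chestnut").  Codes must be unique
#' and every level-4 class must belong to exactly one level-1 class.
#'
#' @param path CSV with columns `code`, `level1`, `level4`; or a data.frame.
#' @return A `lulc_legend` (validated data.frame).
#' @export
lulc_legend <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "level1", "level4")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("legend missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$code))
    stop("duplicate legend codes: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "),
         call. = FALSE)
  chk <- unique(df[, c("level1", "level4")])
  if (anyDuplicated(chk$level4))
    stop("level-4 class mapped to more than one level-1 class",
         call. = FALSE)
  structure(df[need], class = c("lulc_legend", "data.frame"))
}

#' Reclassify a categorical map to a legend level
#'
#' Replaces raster codes by class labels of the requested hierarchy level.
#' `level = "mixed"` supports schemes that mix coarse and detailed classes
#' (some level-1 merges, some level-4 classes kept apart): supply a
#' `mapping` data.frame with columns `code`, `class`.
#'
#' @param map A categorical [grid_layer()] whose codes are all in the
#'   legend.
#' @param legend A [lulc_legend()] (ignored for `level = "mixed"` when
#'   `mapping` is given).
#' @param level 1, 4, or `"mixed"`.
#' @param mapping Required for `"mixed"`: data.frame `code`, `class`.
#' @return A categorical `grid_layer` of integer class ids with a
#'   `class_labels` attribute (id -> label).
#' @export
reclass_to_level <- function(map, legend, level = 1, mapping = NULL) {
  stopifnot(inherits(map, "grid_layer"))
  if (map$kind != "categorical") stop("map must be categorical", call. = FALSE)
  if (identical(level, "mixed")) {
    if (is.null(mapping) || !all(c("code", "class") %in% names(mapping)))
      stop("mixed level needs a mapping data.frame with code, class",
           call. = FALSE)
    codes <- mapping$code; classes <- as.character(mapping$class)
  } else {
    stopifnot(inherits(legend, "lulc_legend"))
    col <- if (level == 1) "level1" else if (level == 4) "level4" else
      stop("level must be 1, 4 or 'mixed'", call. = FALSE)
    codes <- legend$code; classes <- as.character(legend[[col]])
  }
  v <- as.vector(map$values)
  unknown <- setdiff(unique(v[!is.na(v)]), codes)
  if (length(unknown))
    stop("map code(s) not in legend: ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  labels <- sort(unique(classes))
  id_of_code <- match(classes, labels)          # code -> class id
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  out[ok] <- id_of_code[match(v[ok], codes)]
  layer <- grid_layer(map$spec, matrix(out, map$spec$n_rows),
                      name = map$name, kind = "categorical")
  attr(layer, "class_labels") <- labels
  layer
}

lulc_labels <- function(map) {
  lab <- attr(map, "class_labels")
  if (is.null(lab)) lab <- as.character(sort(unique(as.vector(
    map$values[!is.na(map$values)]))))
  lab
}

mask_matrix <- function(spec, mask) {
  if (is.null(mask)) return(matrix(TRUE, spec$n_rows, spec$n_cols))
  if (is.matrix(mask)) return(mask)
  stopifnot(inherits(mask, "area_polygon"))
  ctr_x <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  ctr_y <- spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  # quick bounding-box reject, exact ray-cast inside
  m <- matrix(FALSE, spec$n_rows, spec$n_cols)
  bx <- range(mask$vertices$x); by <- range(mask$vertices$y)
  cols <- which(ctr_x >= bx[1] & ctr_x <= bx[2])
  rows <- which(ctr_y >= by[1] & ctr_y <= by[2])
  for (r in rows)
    m[r, cols] <- point_in_polygon(mask, ctr_x[cols], rep(ctr_y[r],
                                                          length(cols)))
  m
}

#' Class-area table for one LULC epoch
#'
#' Share of each class inside a mask: a cell belongs to the mask iff its
#' center lies inside the polygon; percentages are class cells over valid
#' masked cells times 100 (they sum to 100).
#'
#' @param map A categorical [grid_layer()] (ideally from
#'   [reclass_to_level()], which attaches labels).
#' @param mask `NULL` (whole grid), a logical matrix, or an
#'   [area_polygon()].
#' @param epoch Epoch tag recorded in the table (e.g. `"COS2018"`).
#' @param labels Optional class labels (id -> label); defaults to the
#'   map's `class_labels` attribute or the sorted codes.
#' @return A `lulc_table`: data.frame `class`, `cells`, `percent` with
#'   attribute `epoch`.
#' @export
class_area_table <- function(map, mask = NULL, epoch = "epoch",
                             labels = NULL) {
  stopifnot(inherits(map, "grid_layer"))
  if (is.null(labels)) labels <- lulc_labels(map)
  inmask <- mask_matrix(map$spec, mask)
  v <- map$values[inmask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("mask does not intersect any valid cell",
                       call. = FALSE)
  counts <- vapply(seq_along(labels), function(i) sum(v == i), 0L)
  # maps without a labels attribute index classes by their raw codes
  if (is.null(attr(map, "class_labels"))) {
    codes <- as.numeric(labels)
    counts <- vapply(codes, function(cd) sum(v == cd), 0L)
  }
  out <- data.frame(class = labels, cells = counts,
                    percent = 100 * counts / length(v))
  attr(out, "epoch") <- epoch
  class(out) <- c("lulc_table", "data.frame")
  out
}

#' Read a published per-epoch class-percentage table
#'
#' Published-table mode: accepts a typed-in table of class shares (one
#' class column plus one percentage column per epoch) so printed deltas
#' are reproducible without any raster.
#'
#' @param path CSV whose first column is the class name and remaining
#'   columns are epoch percentages.
#' @return Named list of `lulc_table` objects, one per epoch column.
#' @export
read_lulc_tables <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cls <- df[[1]]
  epochs <- names(df)[-1]
  out <- lapply(epochs, function(e) {
    t <- data.frame(class = cls, cells = NA_integer_, percent = df[[e]])
    attr(t, "epoch") <- e
    class(t) <- c("lulc_table", "data.frame")
    t
  })
  names(out) <- epochs
  out
}

#' Per-class change between two epochs
#'
#' Signed differences of class shares, `b - a`, in percentage points.
#'
#' @param a,b `lulc_table` objects over the same class set.
#' @return data.frame `class`, `from`, `to`, `delta_pp`.
#' @export
table_change <- function(a, b) {
  stopifnot(inherits(a, "lulc_table"), inherits(b, "lulc_table"))
  if (!setequal(a$class, b$class))
    stop("class sets differ between epochs", call. = FALSE)
  bb <- b[match(a$class, b$class), ]
  data.frame(class = a$class, from = a$percent, to = bb$percent,
             delta_pp = bb$percent - a$percent)
}

#' Cross-tabulated transition matrix between two epochs
#'
#' Co-located class pairs inside a mask: entry (i, j) is the number of
#' cells in class i at epoch A and class j at epoch B.  Row sums reproduce
#' epoch-A class counts and column sums epoch-B counts; the diagonal share
#' of the total is the persistence.
#'
#' @param map_a,map_b Aligned categorical [grid_layer()]s sharing a class
#'   scheme (same `class_labels`).
#' @param mask As in [class_area_table()].
#' @param labels Optional shared class labels.
#' @return A `transition_matrix`: list with `counts` (K x K matrix),
#'   `percent` (of masked valid cells), `persistence_pct`, and per-class
#'   `gains`/`losses` decompositions (largest donors and recipients first).
#' @export
transition_matrix <- function(map_a, map_b, mask = NULL, labels = NULL) {
  stopifnot(inherits(map_a, "grid_layer"), inherits(map_b, "grid_layer"))
  if (!specs_aligned(map_a$spec, map_b$spec))
    stop("epoch maps are not aligned", call. = FALSE)
  la <- lulc_labels(map_a); lb <- lulc_labels(map_b)
  if (is.null(labels)) labels <- sort(unique(c(la, lb)))
  inmask <- mask_matrix(map_a$spec, mask)
  va <- map_a$values[inmask]; vb <- map_b$values[inmask]
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop("mask does not intersect any jointly valid cell",
                     call. = FALSE)
  ida <- if (is.null(attr(map_a, "class_labels")))
    match(va[ok], as.numeric(la)) else va[ok]
  idb <- if (is.null(attr(map_b, "class_labels")))
    match(vb[ok], as.numeric(lb)) else vb[ok]
  fa <- factor(la[ida], levels = labels)
  fb <- factor(lb[idb], levels = labels)
  counts <- table(from = fa, to = fb)
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(from = labels, to = labels))
  total <- sum(counts)
  off <- counts; diag(off) <- 0L
  gains <- lapply(seq_along(labels), function(j) sort(off[, j][off[, j] > 0],
                                                      decreasing = TRUE))
  losses <- lapply(seq_along(labels), function(i) sort(off[i, ][off[i, ] > 0],
                                                       decreasing = TRUE))
  names(gains) <- names(losses) <- labels
  structure(list(counts = counts, percent = 100 * counts / total,
                 persistence_pct = 100 * sum(diag(counts)) / total,
                 gains = gains, losses = losses, labels = labels),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, persistence %.1f%%\n",
              length(x$labels), x$persistence_pct))
  print(round(x$percent, 2))
  invisible(x)
}
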