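#' Read a raster from an ESRI ASCII grid file
#'
#' Plain-text raster interchange: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' value matrix, top row first.  The CRS tag is read from a sidecar `.prj`
#' file next to the raster; a missing sidecar is an error unless `crs` is
#' supplied, because all grids in an analysis must carry a validated
#' projected CRS.
#'
#' @param path Path to the `.asc` file.
#' @param kind `"continuous"` or `"categorical"`.
#' @param name Layer name; defaults to the file name without extension.
#' @param crs Optional CRS tag overriding / replacing the `.prj` sidecar.
#' @return A [grid_layer()].
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical"),
                            name = NULL, crs = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("unreadable ASCII grid header in ", path, call. = FALSE)
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square pixels (dx/dy header) are not supported", call. = FALSE)
  if (!all(c("xllcorner", "yllcorner") %in% names(hdr)))
    stop("header must use xllcorner/yllcorner", call. = FALSE)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(crs)) {
    prj <- paste0(tools::file_path_sans_ext(path), ".prj")
    if (!file.exists(prj))
      stop("missing CRS: no sidecar ", prj, " and no crs= argument",
           call. = FALSE)
    crs <- trimws(readLines(prj, warn = FALSE)[1])
  }
  spec <- grid_spec(origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize,
                    cell_size = hdr$cellsize, n_rows = nr, n_cols = nc,
                    crs_tag = crs)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  grid_layer(spec, m, name = name, kind = kind, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits so that doubles round-trip
#' bit-exactly; `NA` cells are written as the layer's nodata sentinel.  The
#' CRS tag goes to a `.prj` sidecar.
#'
#' @param layer A [grid_layer()].
#' @param path Output `.asc` path.
#' @return The path, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  s <- layer$spec
  v <- layer$values
  if (any(v == layer$nodata, na.rm = TRUE))
    stop("layer contains valid cells equal to the nodata sentinel ",
         layer$nodata, call. = FALSE)
  v[is.na(v)] <- layer$nodata
  hdr <- c(sprintf("ncols %d", s$n_cols),
           sprintf("nrows %d", s$n_rows),
           sprintf("xllcorner %.10f", s$origin_x),
           sprintf("yllcorner %.10f", s$origin_y - s$n_rows * s$cell_size),
           sprintf("cellsize %.10f", s$cell_size),
           sprintf("NODATA_value %s", format(layer$nodata, scientific = FALSE)))
  body <- apply(v, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(s$crs_tag, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}
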