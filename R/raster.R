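#' Grid geometry for an equal-area analysis grid
#'
#' Defines the geometry shared by every layer of an analysis stack: number of
#' rows and columns, the cell size in kilometres, and the projected coordinate
#' of the top-left cell's outer corner. Indexing is 0-based and row-major;
#' the centre of cell (row, col) sits at
#' `origin + ((col + 0.5) * cell, -(row + 0.5) * cell)`.
#'
#' The grid is an abstract equal-area plane: no geodesy or reprojection is
#' performed anywhere in the package. Real-world rasters must be co-registered
#' to a common equal-area projection before ingestion.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_size cell edge length in km (default 1, the analysis scale).
#' @param origin numeric length-2, (x, y) of the top-left outer corner in km.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 1, origin = c(0, 0)) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1L, n_cols >= 1L,
            is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            is.numeric(origin), length(origin) == 2L)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells, %.3g km, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Test whether two grid geometries are identical
#'
#' Layers are alignable only if their geometries are exactly equal.
#'
#' @param a,b `grid_geometry` objects.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12))
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_geometry(geometry(a), geometry(b)))
    stop("alignment error: ", what, " do not share one grid geometry",
         call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid geometry
#'
#' @param geom a `grid_geometry`.
#' @return List with matrices `x` and `y` (n_rows x n_cols) of centre
#'   coordinates in km.
#' @export
cell_centers <- function(geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  cs <- geom$cell_size
  xs <- geom$origin[1] + (seq_len(geom$n_cols) - 0.5) * cs
  ys <- geom$origin[2] - (seq_len(geom$n_rows) - 0.5) * cs
  list(x = matrix(xs, geom$n_rows, geom$n_cols, byrow = TRUE),
       y = matrix(ys, geom$n_rows, geom$n_cols))
}

#' Construct a raster layer
#'
#' A raster couples a numeric matrix of cell values to a [grid_geometry()]
#' and a declared kind. Missing data is held as `NA` internally; the `nodata`
#' sentinel only matters on disk (see [write_raster_ascii()]).
#'
#' @param values numeric matrix (n_rows x n_cols); `NA` marks nodata.
#' @param geometry a `grid_geometry`; defaults to a unit-origin 1-km grid of
#'   matching shape.
#' @param kind one of `"continuous"`, `"categorical"`, `"binary"`.
#' @return An object of class `fire_raster`.
#' @export
raster_layer <- function(values,
                         geometry = grid_geometry(nrow(values), ncol(values)),
                         kind = c("continuous", "categorical", "binary")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), inherits(geometry, "grid_geometry"))
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols)
    stop("alignment error: values shape does not match geometry", call. = FALSE)
  storage.mode(values) <- "double"
  if (kind == "binary") {
    bad <- !is.na(values) & !(values %in% c(0, 1))
    if (any(bad)) stop("binary raster may contain only 0, 1 or NA",
                       call. = FALSE)
  }
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical raster must hold integer codes", call. = FALSE)
  }
  structure(list(values = values, geometry = geometry, kind = kind),
            class = "fire_raster")
}

#' @export
print.fire_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<fire_raster:%s> %d x %d, %d nodata cells",
              x$kind, nrow(v), ncol(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf(", range [%.4g, %.4g]", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @rdname raster_layer
#' @param x a `fire_raster`.
#' @export
values_of <- function(x) {
  stopifnot(inherits(x, "fire_raster"))
  x$values
}

#' @rdname raster_layer
#' @export
geometry <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  stopifnot(inherits(x, "fire_raster"))
  x$geometry
}

## replace the value matrix, keeping geometry/kind
with_values <- function(r, v, kind = r$kind) {
  raster_layer(v, r$geometry, kind)
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange. The header carries `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize` and `NODATA_value`; values
#' follow row-major from the top row. Coordinates are in km to match
#' [grid_geometry()]. This is the package's raster interchange format; binary
#' formats are out of scope.
#'
#' @param path file path.
#' @param kind declared raster kind for the loaded layer.
#' @return `read_raster_ascii()` returns a `fire_raster`;
#'   `write_raster_ascii()` returns `path` invisibly.
#' @export
read_raster_ascii <- function(path,
                              kind = c("continuous", "categorical", "binary")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  geom <- grid_geometry(nr, nc, hdr$cellsize,
                        origin = c(xll, yll + nr * hdr$cellsize))
  raster_layer(m, geom, kind)
}

#' @rdname read_raster_ascii
#' @param r a `fire_raster` to write.
#' @param nodata sentinel written in place of `NA` (default -9999).
#' @param digits significant digits for continuous values.
#' @export
write_raster_ascii <- function(r, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(r, "fire_raster"))
  g <- r$geometry
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  fmt <- if (r$kind == "continuous") function(x) formatC(x, digits = digits,
                                                         format = "g")
         else function(x) formatC(x, format = "d")
  for (i in seq_len(g$n_rows))
    writeLines(paste(fmt(v[i, ]), collapse = " "), con)
  invisible(path)
}
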