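#' Read an active-fire detection CSV
#'
#' Reads a detection table in the MODIS active-fire (MCD14ML) column dialect:
#' one row per detection with `latitude`, `longitude`, `brightness`, `scan`,
#' `track`, `acq_date`, `acq_time`, `satellite`, `confidence`, `version`.
#' The synthetic dialect adds `x_km` / `y_km` columns holding projected grid
#' coordinates. Only the coordinates and `confidence` are interpreted; other
#' columns pass through.
#'
#' Malformed rows (missing coordinates, confidence outside 0-100, latitude or
#' longitude out of range) are rejected row-by-row, not fatally; the count of
#' rejected rows is attached as attribute `n_rejected` and reported in a
#' message.
#'
#' @param path CSV file path.
#' @return `data.frame` of valid detections with attribute `n_rejected`.
#' @export
read_fire_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"confidence" %in% names(df))
    stop("fire CSV lacks a confidence column", call. = FALSE)
  ok <- is.finite(df$confidence) & df$confidence >= 0 & df$confidence <= 100
  if (all(c("x_km", "y_km") %in% names(df))) {
    ok <- ok & is.finite(df$x_km) & is.finite(df$y_km)
  } else if (all(c("latitude", "longitude") %in% names(df))) {
    ok <- ok & is.finite(df$latitude) & is.finite(df$longitude) &
      abs(df$latitude) <= 90 & abs(df$longitude) <= 180
  } else {
    stop("fire CSV needs x_km/y_km or latitude/longitude columns",
         call. = FALSE)
  }
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message("read_fire_csv: rejected ", n_rej, " malformed row(s)")
  out <- df[ok, , drop = FALSE]
  attr(out, "n_rejected") <- n_rej
  out
}

#' Rasterize fire detections to presence/absence
#'
#' Drops detections below the confidence threshold (the analysis uses a
#' high-confidence filter at 95, inclusive), assigns the survivors to grid
#' cells, and marks a cell 1 if at least one detection falls inside it.
#' Fire enters the analysis as presence/absence per cell, not a count.
#' Detections falling outside the grid are dropped; their number is attached
#' as attribute `n_outside`.
#'
#' @param points detection `data.frame` (see [read_fire_csv()]); coordinate
#'   columns `x_km`/`y_km` (projected km) are preferred, else
#'   `longitude`/`latitude` are taken as already-projected grid coordinates.
#' @param geom target `grid_geometry`.
#' @param min_confidence inclusive confidence threshold (default 95).
#' @return Binary `fire_raster` with attributes `n_outside` and `n_dropped_confidence`.
#' @export
rasterize_fires <- function(points, geom, min_confidence = 95) {
  stopifnot(inherits(geom, "grid_geometry"), is.data.frame(points))
  if (all(c("x_km", "y_km") %in% names(points))) {
    x <- points$x_km; y <- points$y_km
  } else if (all(c("longitude", "latitude") %in% names(points))) {
    x <- points$longitude; y <- points$latitude
  } else stop("detections need x_km/y_km or longitude/latitude columns",
              call. = FALSE)
  keep <- points$confidence >= min_confidence
  n_conf <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  col <- floor((x - geom$origin[1]) / geom$cell_size) + 1
  row <- floor((geom$origin[2] - y) / geom$cell_size) + 1
  inside <- row >= 1 & row <= geom$n_rows & col >= 1 & col <= geom$n_cols
  out <- matrix(0, geom$n_rows, geom$n_cols)
  out[cbind(row[inside], col[inside])] <- 1
  r <- raster_layer(out, geom, "binary")
  attr(r, "n_outside") <- sum(!inside)
  attr(r, "n_dropped_confidence") <- n_conf
  r
}

#' Mean fire-season temperature
#'
#' Cellwise arithmetic mean of aligned monthly temperature rasters (the fire
#' season of the study system is February-April, i.e. three rasters), with
#' nodata propagating: a cell missing in any month is missing in the mean.
#'
#' @param monthly list of aligned continuous `fire_raster`s (>= 1).
#' @return Continuous `fire_raster` of the cellwise mean.
#' @export
fire_season_temperature <- function(monthly) {
  stopifnot(is.list(monthly), length(monthly) >= 1)
  ref <- monthly[[1]]
  acc <- matrix(0, ref$geometry$n_rows, ref$geometry$n_cols)
  for (m in monthly) {
    stop_if_misaligned(ref, m, "monthly temperature rasters")
    acc <- acc + m$values
  }
  with_values(ref, acc / length(monthly), "continuous")
}
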