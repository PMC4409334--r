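#' Majority-filter resampling of a categorical raster
#'
#' Aggregates a fine categorical raster to a coarser aligned grid by taking,
#' in each target cell, the modal category among the source cells whose
#' centres fall inside it. Nodata source cells are excluded from the vote and
#' an all-nodata block yields nodata. Ties are broken deterministically by
#' the lowest category code. When the source is coarser than the target
#' (integer ratio), each target cell takes the code of the source cell that
#' contains its centre.
#'
#' @param src categorical `fire_raster`.
#' @param target `grid_geometry` whose cell size relates to the source cell
#'   size by an integer factor and whose extent is covered by the source.
#' @return Categorical `fire_raster` on `target`.
#' @export
resample_categorical <- function(src, target) {
  stopifnot(inherits(src, "fire_raster"), inherits(target, "grid_geometry"))
  if (src$kind != "categorical")
    stop("kind error: resample_categorical requires a categorical raster",
         call. = FALSE)
  sg <- src$geometry
  if (same_geometry(sg, target)) return(src)
  ratio <- target$cell_size / sg$cell_size
  if (ratio >= 1) {
    k <- check_integer_ratio(ratio)
    idx <- block_index(sg, target)
    out <- matrix(NA_real_, target$n_rows, target$n_cols)
    ok <- !is.na(idx$row) & !is.na(idx$col)
    if (!any(ok)) stop("coverage error: source does not overlap target",
                       call. = FALSE)
    cell <- (idx$col[ok] - 1L) * target$n_rows + idx$row[ok]
    val <- src$values[ok]
    keep <- !is.na(val)
    out[] <- NA_real_
    if (any(keep)) {
      modal <- vapply(split(val[keep], cell[keep]), lowest_mode, numeric(1))
      out[as.integer(names(modal))] <- modal
    }
    raster_layer(out, target, "categorical")
  } else {
    k <- check_integer_ratio(1 / ratio)
    ctr <- cell_centers(target)
    sr <- floor((sg$origin[2] - ctr$y) / sg$cell_size) + 1
    sc <- floor((ctr$x - sg$origin[1]) / sg$cell_size) + 1
    if (any(sr < 1 | sr > sg$n_rows | sc < 1 | sc > sg$n_cols))
      stop("coverage error: source does not cover target extent",
           call. = FALSE)
    out <- matrix(src$values[cbind(as.vector(sr), as.vector(sc))],
                  target$n_rows, target$n_cols)
    raster_layer(out, target, "categorical")
  }
}

check_integer_ratio <- function(ratio) {
  k <- round(ratio)
  if (abs(ratio - k) > 1e-9)
    stop("alignment error: cell sizes are not related by an integer factor",
         call. = FALSE)
  as.integer(k)
}

lowest_mode <- function(x) {
  tab <- table(x)
  codes <- as.numeric(names(tab))
  codes[order(-as.integer(tab), codes)][1]
}

## target (row, col) index of every source cell centre; NA when outside
block_index <- function(src_geom, target) {
  ctr <- cell_centers(src_geom)
  row <- floor((target$origin[2] - ctr$y) / target$cell_size) + 1
  col <- floor((ctr$x - target$origin[1]) / target$cell_size) + 1
  row[row < 1 | row > target$n_rows] <- NA
  col[col < 1 | col > target$n_cols] <- NA
  list(row = row, col = col)
}

#' Cubic-convolution resampling of a continuous raster
#'
#' Interpolates source samples at the target cell centres with the separable
#' Keys cubic convolution kernel (a = -0.5) over a 4 x 4 source neighbourhood.
#' The kernel is interpolating (reproduces source samples exactly) and exact
#' on constant and linear fields. Indices outside the source are clamped to
#' the nearest valid sample (edge replication). Nodata within the 4 x 4
#' support propagates to the output cell.
#'
#' @param src continuous `fire_raster`.
#' @param target `grid_geometry` covered by the source extent.
#' @return Continuous `fire_raster` on `target`.
#' @export
resample_continuous <- function(src, target) {
  stopifnot(inherits(src, "fire_raster"), inherits(target, "grid_geometry"))
  if (src$kind != "continuous")
    stop("kind error: resample_continuous requires a continuous raster",
         call. = FALSE)
  sg <- src$geometry
  ctr <- cell_centers(target)
  ## fractional source index of each target centre (1-based sample grid)
  fx <- (ctr$x - sg$origin[1]) / sg$cell_size + 0.5
  fy <- (sg$origin[2] - ctr$y) / sg$cell_size + 0.5
  if (max(fx) < 1 || min(fx) > sg$n_cols || max(fy) < 1 || min(fy) > sg$n_rows)
    stop("coverage error: source does not overlap target extent",
         call. = FALSE)
  jx <- floor(fx); jy <- floor(fy)
  tx <- fx - jx;  ty <- fy - jy
  out <- matrix(0, target$n_rows, target$n_cols)
  wy <- lapply(-1:2, function(m) keys_kernel(ty - m))
  wx <- lapply(-1:2, function(m) keys_kernel(tx - m))
  for (mi in 1:4) {
    ri <- pmin(pmax(jy + (mi - 2L), 1), sg$n_rows)
    for (mj in 1:4) {
      ci <- pmin(pmax(jx + (mj - 2L), 1), sg$n_cols)
      out <- out + wy[[mi]] * wx[[mj]] *
        src$values[cbind(as.vector(ri), as.vector(ci))]
    }
  }
  raster_layer(out, target, "continuous")
}

## Keys (1981) cubic convolution kernel, a = -0.5
keys_kernel <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  i2 <- s > 1 & s < 2
  w[i2] <- a * (s[i2]^3 - 5 * s[i2]^2 + 8 * s[i2] - 4)
  dim(w) <- dim(s)
  w
}

#' Proportional allocation of a coarse count layer to a fine grid
#'
#' Splits each coarse cell's count equally among the k x k fine cells it
#' covers (uniform-area proportions), conserving the global total exactly.
#' Intended for count-like layers such as gridded population.
#'
#' @param src continuous `fire_raster` of nonnegative counts.
#' @param target `grid_geometry` whose cell size divides the source cell
#'   size by an integer factor k.
#' @return Continuous `fire_raster` on `target`; each fine cell holds
#'   `coarse count / k^2`.
#' @export
allocate_proportional <- function(src, target) {
  stopifnot(inherits(src, "fire_raster"), inherits(target, "grid_geometry"))
  sg <- src$geometry
  if (any(src$values < 0, na.rm = TRUE))
    stop("domain error: allocate_proportional requires nonnegative counts",
         call. = FALSE)
  k <- check_integer_ratio(sg$cell_size / target$cell_size)
  ctr <- cell_centers(target)
  sr <- floor((sg$origin[2] - ctr$y) / sg$cell_size) + 1
  sc <- floor((ctr$x - sg$origin[1]) / sg$cell_size) + 1
  if (any(sr < 1 | sr > sg$n_rows | sc < 1 | sc > sg$n_cols))
    stop("coverage error: source does not cover target extent", call. = FALSE)
  out <- matrix(src$values[cbind(as.vector(sr), as.vector(sc))] / k^2,
                target$n_rows, target$n_cols)
  raster_layer(out, target, "continuous")
}
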