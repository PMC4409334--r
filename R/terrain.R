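#' Slope and aspect from an elevation raster
#'
#' Computes the terrain gradient with Horn's eight-neighbour finite
#' difference, using edge replication at the grid border. Slope is
#' `atan(|grad z|)` in degrees in `[0, 90)`. Aspect is the compass direction
#' of steepest descent in degrees `[0, 360)`, measured clockwise from north;
#' flat cells (zero gradient) receive the flat sentinel -1 and are excluded
#' from factor classing downstream.
#'
#' @param elevation continuous `fire_raster` of elevation in metres, on the
#'   analysis grid (cell size in km, converted internally to metres).
#' @return List with `slope` and `aspect`, both continuous `fire_raster`s.
#' @export
slope_aspect <- function(elevation) {
  stopifnot(inherits(elevation, "fire_raster"))
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3)
    stop("size error: slope_aspect needs a grid of at least 3 x 3 cells",
         call. = FALSE)
  w <- elevation$geometry$cell_size * 1000  # metres
  up <- c(1, seq_len(nr - 1)); dn <- c(seq_len(nr)[-1], nr)
  lf <- c(1, seq_len(nc - 1)); rt <- c(seq_len(nc)[-1], nc)
  a <- z[up, lf]; b <- z[up, ]; cc <- z[up, rt]
  d <- z[, lf];                 f <- z[, rt]
  g <- z[dn, lf]; h <- z[dn, ]; i <- z[dn, rt]
  dzde <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * w)  # eastward
  dzdn <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * w)  # northward
  mag <- sqrt(dzde^2 + dzdn^2)
  slope <- atan(mag) * 180 / pi
  aspect <- (atan2(-dzde, -dzdn) * 180 / pi) %% 360
  aspect[mag == 0] <- -1
  aspect[is.na(mag)] <- NA
  list(slope = with_values(elevation, slope, "continuous"),
       aspect = with_values(elevation, aspect, "continuous"))
}

#' Euclidean distance to the nearest mask cell
#'
#' Exact centre-to-centre Euclidean distance (in km) from every cell to the
#' nearest 1-cell of a binary mask, by the exact two-pass squared distance
#' transform (column sweep followed by a row-wise lower-envelope pass).
#' Mask cells hold 0. `NA` mask cells are treated as non-source.
#'
#' @param mask binary `fire_raster` with at least one 1-cell.
#' @return Continuous `fire_raster` of distances in km.
#' @export
euclidean_distance <- function(mask) {
  stopifnot(inherits(mask, "fire_raster"))
  if (mask$kind != "binary")
    stop("kind error: euclidean_distance requires a binary mask",
         call. = FALSE)
  m <- mask$values
  src <- !is.na(m) & m == 1
  if (!any(src))
    stop("no-source error: mask contains no 1-cells", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  ## pass 1: squared distance to nearest source within each column
  f <- matrix(Inf, nr, nc)
  for (j in seq_len(nc)) {
    col <- src[, j]
    if (!any(col)) next
    d <- rep(Inf, nr)
    d[col] <- 0
    for (i in seq_len(nr)[-1])  d[i] <- min(d[i], d[i - 1] + 1)
    for (i in rev(seq_len(nr - 1))) d[i] <- min(d[i], d[i + 1] + 1)
    f[, j] <- d^2
  }
  ## pass 2: 1-d squared distance transform along each row
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) out[i, ] <- dt1d_squared(f[i, ])
  with_values(mask, sqrt(out) * mask$geometry$cell_size, "continuous")
}

## Lower-envelope 1-d squared distance transform (Felzenszwalb-Huttenlocher):
## g[q] = min_p (f[p] + (q - p)^2). Infinite f entries are skipped.
dt1d_squared <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(f)
  v <- integer(n); zl <- numeric(n + 1)
  k <- 1L
  v[1] <- fin[1]
  zl[1] <- -Inf; zl[2] <- Inf
  for (q in fin[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      if (s <= zl[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    zl[k] <- s
    zl[k + 1] <- Inf
  }
  g <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (zl[k + 1] < q) k <- k + 1L
    g[q] <- (q - v[k])^2 + f[v[k]]
  }
  g
}
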