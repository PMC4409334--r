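#' Matching covariate names
#'
#' The nine covariates entering the matching analysis: tree cover percent,
#' travel time to the nearest city, elevation, slope, aspect, distance to
#' forest edge, distance to road, mean fire-season temperature, and
#' population density. Land cover is categorical and is excluded from the
#' matching covariate vector.
#'
#' @return Character vector of covariate layer names.
#' @export
matching_covariates <- function() {
  c("tree_cover", "travel_time", "elevation", "slope", "aspect",
    "dist_edge", "dist_road", "temperature", "population")
}

#' Build the per-cell unit table for matching
#'
#' Turns an aligned raster stack into one matching unit per valid grid cell:
#' treatment `T` (1 = protected), outcome `Y` (fire presence), and the
#' covariate vector. Cells with nodata in any used layer are dropped
#' (complete-case rule). Optionally restricts to forested cells, defined by
#' a tree-cover floor.
#'
#' @param stack named list of aligned `fire_raster`s containing the layers
#'   named by `covariates` plus `fire` and `protection`.
#' @param forest_only if `TRUE`, keep only cells with
#'   `tree_cover >= forest_threshold`.
#' @param forest_threshold tree-cover percent floor defining forest
#'   (default 25, the lower bound of forest tree cover in the study system).
#' @param covariates covariate layer names (default [matching_covariates()]).
#' @return `data.frame` of class `unit_table` with columns `unit_id`, `row`,
#'   `col`, `T`, `Y`, then one column per covariate; attribute `covariates`
#'   holds the covariate names.
#' @export
build_unit_table <- function(stack, forest_only = FALSE,
                             forest_threshold = 25,
                             covariates = matching_covariates()) {
  need <- c(covariates, "fire", "protection")
  missing <- setdiff(need, names(stack))
  if (length(missing))
    stop("stack lacks layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ref <- stack[[need[1]]]
  for (nm in need) stop_if_misaligned(ref, stack[[nm]], "stack layers")
  g <- ref$geometry
  cols <- lapply(stats::setNames(need, need),
                 function(nm) as.vector(stack[[nm]]$values))
  keep <- Reduce(`&`, lapply(cols, function(v) !is.na(v)))
  if (forest_only)
    keep <- keep & !is.na(cols$tree_cover) &
      cols$tree_cover >= forest_threshold
  idx <- which(keep)
  if (!length(idx)) stop("no valid units", call. = FALSE)
  out <- data.frame(
    unit_id = seq_along(idx),
    row = ((idx - 1L) %% g$n_rows) + 1L,
    col = ((idx - 1L) %/% g$n_rows) + 1L,
    T = as.integer(cols$protection[idx]),
    Y = as.integer(cols$fire[idx])
  )
  for (nm in covariates) out[[nm]] <- cols[[nm]][idx]
  if (!any(out$T == 1) || !any(out$T == 0))
    stop("unit table needs at least one treated and one control unit",
         call. = FALSE)
  attr(out, "covariates") <- covariates
  class(out) <- c("unit_table", "data.frame")
  out
}

#' Write / read a unit table as CSV
#'
#' @param units a `unit_table`.
#' @param path CSV path.
#' @return `read_unit_table()` returns a `unit_table`.
#' @export
write_unit_table <- function(units, path) {
  utils::write.csv(units, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_unit_table
#' @export
read_unit_table <- function(path) {
  df <- utils::read.csv(path)
  fixed <- c("unit_id", "row", "col", "T", "Y")
  stopifnot(all(fixed %in% names(df)))
  attr(df, "covariates") <- setdiff(names(df), fixed)
  class(df) <- c("unit_table", "data.frame")
  df
}

unit_covariate_matrix <- function(units, covariates = NULL) {
  if (is.null(covariates)) covariates <- attr(units, "covariates")
  as.matrix(units[, covariates, drop = FALSE])
}
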