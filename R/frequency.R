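#' Per-class frequency ratio table for one factor
#'
#' For each class i of a classed causative factor, the frequency ratio is the
#' share of fire cells falling in the class divided by the share of all cells
#' falling in the class:
#' \deqn{FR_i = (n_{fire,i} / N_{fire}) / (n_i / N)}
#' over valid (complete-case) cells in the stratum. An FR above 1 marks a
#' class with elevated fire propensity; below 1, depressed. Classes with no
#' cells are omitted; a class with cells but no fires has FR 0.
#'
#' @param fire binary `fire_raster` of fire presence/absence.
#' @param class_raster categorical `fire_raster` from [classify_factor()].
#' @param stratum_mask optional binary `fire_raster` restricting the
#'   computation to cells where the mask is 1 (e.g. protected areas).
#' @param factor_name name recorded in the output rows.
#' @param stratum label recorded in the output rows (default `"all"`).
#' @return `data.frame` with columns `factor`, `class_code`, `class_label`,
#'   `n_cells`, `n_fire_cells`, `fr`, `stratum`, plus attributes `N_cells`
#'   and `N_fire` (stratum totals over valid cells).
#' @export
frequency_ratio_table <- function(fire, class_raster, stratum_mask = NULL,
                                  factor_name = "factor", stratum = "all") {
  stop_if_misaligned(fire, class_raster)
  cls <- class_raster$values
  fv <- fire$values
  valid <- !is.na(cls) & !is.na(fv)
  if (!is.null(stratum_mask)) {
    stop_if_misaligned(fire, stratum_mask)
    sm <- stratum_mask$values
    valid <- valid & !is.na(sm) & sm == 1
  }
  N <- sum(valid)
  Nf <- sum(fv[valid] == 1)
  if (Nf == 0)
    stop("degenerate-stratum error: no fire cells in stratum '", stratum, "'",
         call. = FALSE)
  cl <- cls[valid]
  fi <- fv[valid]
  n_cells <- tapply(rep(1, length(cl)), cl, sum)
  n_fire <- tapply(fi, cl, sum)
  codes <- as.numeric(names(n_cells))
  fr <- (n_fire / Nf) / (n_cells / N)
  labels <- attr(class_raster, "labels")
  lab <- if (!is.null(labels)) unname(labels[as.character(codes)])
         else as.character(codes)
  out <- data.frame(factor = factor_name, class_code = codes,
                    class_label = lab, n_cells = as.integer(n_cells),
                    n_fire_cells = as.integer(n_fire), fr = as.numeric(fr),
                    stratum = stratum, row.names = NULL)
  attr(out, "N_cells") <- N
  attr(out, "N_fire") <- Nf
  out
}

#' Frequency ratio tables for every factor and stratum
#'
#' Convenience wrapper building one combined table across factors, computed
#' independently per stratum (protected / non-protected / all), matching the
#' stratified supplementary-table layout of the susceptibility analysis.
#'
#' @param fire binary fire raster.
#' @param class_rasters named list of class rasters from [classify_stack()].
#' @param protection optional binary protection raster; when supplied,
#'   strata `protected` and `nonprotected` are added alongside `all`.
#' @return Combined `data.frame` of [frequency_ratio_table()] rows.
#' @export
fr_tables <- function(fire, class_rasters, protection = NULL) {
  strata <- list(all = NULL)
  if (!is.null(protection)) {
    inv <- with_values(protection,
                       ifelse(is.na(protection$values), NA,
                              1 - protection$values), "binary")
    strata <- c(strata, list(protected = protection, nonprotected = inv))
  }
  out <- list()
  for (s in names(strata))
    for (f in names(class_rasters))
      out[[paste(s, f)]] <- frequency_ratio_table(
        fire, class_rasters[[f]], strata[[s]], factor_name = f, stratum = s)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fire susceptibility index map
#'
#' Per cell, the fire susceptibility index is the sum over factors of the
#' frequency ratio of the class the cell falls in (FSI = sum of FRs). Cells
#' where any factor is nodata are nodata (complete-case rule). The per-factor
#' FR rasters are returned alongside the FSI.
#'
#' @param frt frequency-ratio rows for one stratum (columns `factor`,
#'   `class_code`, `fr`), e.g. one stratum's slice of [fr_tables()].
#' @param class_rasters named list of class rasters; every class present in
#'   a raster must have an FR row, else a consistency error is raised.
#' @return List with `fsi` (continuous `fire_raster`) and `fr_rasters`
#'   (named list of continuous `fire_raster`s).
#' @export
fire_susceptibility_index <- function(frt, class_rasters) {
  stopifnot(is.data.frame(frt), length(class_rasters) >= 1)
  ref <- class_rasters[[1]]
  fsi <- matrix(0, ref$geometry$n_rows, ref$geometry$n_cols)
  fr_rasters <- list()
  for (f in names(class_rasters)) {
    cr <- class_rasters[[f]]
    stop_if_misaligned(ref, cr)
    rows <- frt[frt$factor == f, , drop = FALSE]
    if (!nrow(rows))
      stop("consistency error: no FR rows for factor '", f, "'",
           call. = FALSE)
    observed <- unique(cr$values[!is.na(cr$values)])
    missing <- setdiff(observed, rows$class_code)
    if (length(missing))
      stop("consistency error: factor '", f, "' has classes without FR rows: ",
           paste(missing, collapse = ", "), call. = FALSE)
    lut <- stats::setNames(rows$fr, rows$class_code)
    frv <- matrix(NA_real_, nrow(cr$values), ncol(cr$values))
    ok <- !is.na(cr$values)
    frv[ok] <- lut[as.character(cr$values[ok])]
    fr_rasters[[f]] <- with_values(cr, frv, "continuous")
    fsi <- fsi + frv
  }
  list(fsi = with_values(ref, fsi, "continuous"), fr_rasters = fr_rasters)
}

#' Rank causative factors within high-susceptibility pixels
#'
#' Selects the cells whose FSI reaches the given quantile of FSI within the
#' stratum, averages each factor's per-cell FR over the selected cells, and
#' ranks factors by that mean in descending order (ties broken
#' alphabetically). Factors with higher mean FR over the most susceptible
#' pixels are the dominant causative factors.
#'
#' @param smap result of [fire_susceptibility_index()].
#' @param selection_quantile fraction in (0, 1); cells with
#'   `FSI >= quantile(FSI, selection_quantile)` are selected (default 0.9).
#' @param stratum_mask optional binary raster restricting the stratum.
#' @return `data.frame` with columns `factor` and `mean_fr`, sorted
#'   descending, with attribute `n_selected`.
#' @export
rank_factors <- function(smap, selection_quantile = 0.9,
                         stratum_mask = NULL) {
  stopifnot(selection_quantile > 0, selection_quantile < 1)
  fsi <- smap$fsi$values
  valid <- !is.na(fsi)
  if (!is.null(stratum_mask)) {
    stop_if_misaligned(smap$fsi, stratum_mask)
    sm <- stratum_mask$values
    valid <- valid & !is.na(sm) & sm == 1
  }
  if (!any(valid)) stop("empty selection: no valid cells in stratum",
                        call. = FALSE)
  thr <- stats::quantile(fsi[valid], selection_quantile, names = FALSE)
  sel <- valid & fsi >= thr
  if (!any(sel)) stop("empty selection after quantile threshold",
                      call. = FALSE)
  mean_fr <- vapply(smap$fr_rasters, function(r) mean(r$values[sel]),
                    numeric(1))
  out <- data.frame(factor = names(mean_fr), mean_fr = unname(mean_fr))
  out <- out[order(-out$mean_fr, out$factor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_selected") <- sum(sel)
  out
}

#' Fire density within a stratum
#'
#' Number of fire cells per km2 of stratum area: the statistic behind the
#' protected versus non-protected fire density comparison.
#'
#' @param fire binary fire raster.
#' @param stratum_mask optional binary stratum raster (default: whole grid).
#' @return Fires per km2 (numeric scalar).
#' @export
fire_density <- function(fire, stratum_mask = NULL) {
  fv <- fire$values
  valid <- !is.na(fv)
  if (!is.null(stratum_mask)) {
    stop_if_misaligned(fire, stratum_mask)
    sm <- stratum_mask$values
    valid <- valid & !is.na(sm) & sm == 1
  }
  n <- sum(valid)
  if (n == 0) stop("empty stratum", call. = FALSE)
  area <- n * fire$geometry$cell_size^2
  sum(fv[valid] == 1) / area
}
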