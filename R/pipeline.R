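#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs. Synthetic mode generates its
#' inputs from a [landscape_config()]; file mode loads ASCII-grid layers and
#' a fire CSV from a directory (layer files `<name>.asc` for every layer of
#' [matching_covariates()] plus `land_cover.asc` and `protection.asc`, and
#' `fires.csv`).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param landscape a `landscape_config` (synthetic mode).
#' @param input_dir directory of input layers (file mode).
#' @param scheme a `factor_scheme`, or `NULL` for
#'   [default_factor_scheme()] with the land cover codes found in the data.
#' @param selection_quantile high-susceptibility selection quantile.
#' @param min_confidence fire-detection confidence threshold.
#' @param caliper_sd matching caliper in SD units.
#' @param forest_only restrict matching units to forested cells.
#' @param forest_threshold tree-cover floor defining forest.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       landscape = landscape_config(),
                       input_dir = NULL, scheme = NULL,
                       selection_quantile = 0.9, min_confidence = 95,
                       caliper_sd = 1, forest_only = TRUE,
                       forest_threshold = 25,
                       out_dir = "firescape_out", seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(input_dir))
    stop("file mode needs input_dir", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

stack_layer_kinds <- function() {
  c(tree_cover = "continuous", land_cover = "categorical",
    elevation = "continuous", slope = "continuous", aspect = "continuous",
    temperature = "continuous", population = "continuous",
    travel_time = "continuous", dist_road = "continuous",
    dist_edge = "continuous", protection = "binary")
}

#' Write / load a covariate stack as ASCII grids
#'
#' One `<layer>.asc` per raster; the loader reads every layer named by
#' `stack_layer_kinds()` that is present.
#'
#' @param stack named list of `fire_raster`s.
#' @param dir directory.
#' @return `load_stack_dir()` returns the named list of rasters.
#' @export
write_stack_dir <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(names(stack_layer_kinds()), names(stack)))
    write_raster_ascii(stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' @rdname write_stack_dir
#' @export
load_stack_dir <- function(dir) {
  kinds <- stack_layer_kinds()
  out <- list()
  for (nm in names(kinds)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    if (file.exists(f)) out[[nm]] <- read_raster_ascii(f, kinds[[nm]])
  }
  if (!length(out)) stop("no stack layers found in ", dir, call. = FALSE)
  attr(out, "geometry") <- out[[1]]$geometry
  out
}

#' Run the full analysis pipeline
#'
#' Executes: input assembly (synthetic generation or file loading) ->
#' fire rasterization (confidence filter) -> factor classification ->
#' stratified frequency-ratio tables -> stratified FSI map -> factor
#' ranking by stratum -> unit table -> correlation screen -> Mahalanobis
#' matching -> ATT and balance report. All outputs land in `out_dir` under
#' fixed names (`fr_protected.csv`, `fr_nonprotected.csv`, `fr_all.csv`,
#' `fsi.asc`, `ranking.csv`, `units.csv`, `correlation.csv`, `balance.csv`,
#' `effect.json`, `run_log.jsonl`, `summary.txt`). Any stage failure aborts
#' with the stage name and cause. Re-running overwrites; nothing is
#' appended.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the main in-memory results (`stack`,
#'   `fr`, `fsi`, `ranking`, `units`, `matches`, `effect`, `balance`,
#'   `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[length(log) + 1]] <<- list(stage = name,
                                    seconds = round(proc.time()[["elapsed"]]
                                                    - t0, 3))
    res
  }

  inputs <- stage("inputs", {
    if (config$mode == "synthetic") {
      lc <- config$landscape
      lc$seed <- config$seed
      stack <- generate_covariates(lc)
      fire0 <- generate_fires(stack, lc)
      csv <- file.path(config$out_dir, "fires.csv")
      emit_fire_csv(fire0, csv, seed = config$seed + 2L)
      list(stack = stack, fire_csv = csv, truth = attr(fire0, "truth"))
    } else {
      list(stack = load_stack_dir(config$input_dir),
           fire_csv = file.path(config$input_dir, "fires.csv"),
           truth = NULL)
    }
  })
  stack <- inputs$stack
  geom <- attr(stack, "geometry")

  fire <- stage("rasterize_fires", {
    pts <- read_fire_csv(inputs$fire_csv)
    rasterize_fires(pts, geom, config$min_confidence)
  })
  log[[length(log)]]$n_fire_cells <- sum(fire$values == 1)
  log[[length(log)]]$n_dropped_confidence <-
    attr(fire, "n_dropped_confidence")
  log[[length(log)]]$n_outside <- attr(fire, "n_outside")

  scheme <- config$scheme
  if (is.null(scheme)) {
    codes <- sort(unique(stack$land_cover$values[
      !is.na(stack$land_cover$values)]))
    scheme <- default_factor_scheme(landcover_codes = codes)
  }
  class_rasters <- stage("classify",
                         classify_stack(stack[names(scheme)], scheme))

  frt <- stage("frequency_ratio",
               fr_tables(fire, class_rasters, stack$protection))
  utils::write.csv(frt[frt$stratum == "protected", ],
                   file.path(config$out_dir, "fr_protected.csv"),
                   row.names = FALSE)
  utils::write.csv(frt[frt$stratum == "nonprotected", ],
                   file.path(config$out_dir, "fr_nonprotected.csv"),
                   row.names = FALSE)
  utils::write.csv(frt[frt$stratum == "all", ],
                   file.path(config$out_dir, "fr_all.csv"),
                   row.names = FALSE)

  fsi <- stage("fsi", {
    prot <- stack$protection$values
    ## restrict each stratum's class rasters to its own cells so that
    ## classes occurring only in the other stratum need no FR row
    mask_to <- function(cr, keep) {
      v <- cr$values
      v[!keep] <- NA
      r <- with_values(cr, v, "categorical")
      attr(r, "labels") <- attr(cr, "labels")
      r
    }
    keeps <- list(protected = !is.na(prot) & prot == 1,
                  nonprotected = !is.na(prot) & prot == 0)
    per_stratum <- lapply(names(keeps), function(s)
      fire_susceptibility_index(frt[frt$stratum == s, ],
                                lapply(class_rasters, mask_to,
                                       keep = keeps[[s]])))
    ## stratified default: each cell scored with its own stratum's FR table
    comb <- per_stratum[[1]]$fsi$values
    comb[prot == 0] <- per_stratum[[2]]$fsi$values[prot == 0]
    fr_comb <- lapply(names(class_rasters), function(f) {
      v <- per_stratum[[1]]$fr_rasters[[f]]$values
      v[prot == 0] <- per_stratum[[2]]$fr_rasters[[f]]$values[prot == 0]
      with_values(class_rasters[[f]], v, "continuous")
    })
    names(fr_comb) <- names(class_rasters)
    list(fsi = raster_layer(comb, geom, "continuous"), fr_rasters = fr_comb)
  })
  write_raster_ascii(fsi$fsi, file.path(config$out_dir, "fsi.asc"))

  ranking <- stage("rank", {
    inv <- with_values(stack$protection, 1 - stack$protection$values,
                       "binary")
    rk <- rbind(
      cbind(rank_factors(fsi, config$selection_quantile, stack$protection),
            stratum = "protected"),
      cbind(rank_factors(fsi, config$selection_quantile, inv),
            stratum = "nonprotected"))
    rk
  })
  utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                   row.names = FALSE)

  units <- stage("unit_table", {
    st <- stack
    st$fire <- fire
    build_unit_table(st, forest_only = config$forest_only,
                     forest_threshold = config$forest_threshold)
  })
  write_unit_table(units, file.path(config$out_dir, "units.csv"))
  log[[length(log)]]$n_units <- nrow(units)
  log[[length(log)]]$n_treated <- sum(units$T == 1)
  log[[length(log)]]$n_cells_total <- geom$n_rows * geom$n_cols
  log[[length(log)]]$n_cells_excluded <-
    geom$n_rows * geom$n_cols - nrow(units)

  screen <- stage("correlation_screen", correlation_screen(units))
  utils::write.csv(as.data.frame(screen$correlation),
                   file.path(config$out_dir, "correlation.csv"))

  matches <- stage("matching",
                   mahalanobis_match(units, caliper_sd = config$caliper_sd))
  log[[length(log)]]$n_excluded_caliper <- sum(matches$excluded)

  effect <- stage("att", att_estimate(units, matches))
  write_effect_json(effect, file.path(config$out_dir, "effect.json"))

  balance <- stage("balance", balance_report(units, matches))
  utils::write.csv(balance, file.path(config$out_dir, "balance.csv"),
                   row.names = FALSE)

  log_path <- file.path(config$out_dir, "run_log.jsonl")
  writeLines(vapply(log, function(l)
    jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA), character(1)),
    log_path)
  writeLines(c(
    sprintf("firescape run (seed %d, %s mode)", config$seed, config$mode),
    sprintf("grid: %d x %d cells", geom$n_rows, geom$n_cols),
    sprintf("fire cells: %d", sum(fire$values == 1)),
    sprintf("units: %d (%d treated)", nrow(units), sum(units$T == 1)),
    sprintf("ATT = %.4f (SE %.4f, t = %.2f)", effect$att, effect$se,
            effect$t_value),
    sprintf("caliper exclusions: %d", effect$n_excluded_caliper),
    "top factors (protected): ",
    paste(" ", utils::head(ranking$factor[ranking$stratum == "protected"],
                           5), collapse = "\n")
  ), file.path(config$out_dir, "summary.txt"))

  invisible(list(stack = stack, fire = fire, fr = frt, fsi = fsi,
                 ranking = ranking, units = units, matches = matches,
                 effect = effect, balance = balance, truth = inputs$truth,
                 log = log))
}
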