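#' Causative-factor classing scheme
#'
#' A factor scheme names each causative factor and fixes how its values are
#' divided into class intervals (continuous factors) or which category codes
#' it may take (categorical factors). Frequency ratios are computed per class
#' of this scheme.
#'
#' @param name factor name (unique within a scheme).
#' @param kind `"continuous"` or `"categorical"`.
#' @param breaks strictly increasing breakpoints for a continuous factor
#'   (defining `length(breaks) - 1` classes, binned left-closed/right-open
#'   with the last interval closed). `Inf` is allowed as the last break.
#' @param codes integer category codes for a categorical factor.
#' @return An object of class `factor_entry`.
#' @export
factor_entry <- function(name, kind = c("continuous", "categorical"),
                         breaks = NULL, codes = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    stopifnot(is.numeric(breaks), length(breaks) >= 3,
              all(diff(breaks) > 0))
    labels <- paste0(breaks[-length(breaks)], "-", breaks[-1])
  } else {
    stopifnot(is.numeric(codes), length(codes) >= 2,
              !anyDuplicated(codes))
    labels <- as.character(codes)
  }
  structure(list(name = name, kind = kind, breaks = breaks,
                 codes = codes, labels = labels),
            class = "factor_entry")
}

#' @rdname factor_entry
#' @param entries list of `factor_entry` objects with unique names.
#' @return `factor_scheme()` returns an object of class `factor_scheme`
#'   (a named list of entries).
#' @export
factor_scheme <- function(entries) {
  stopifnot(all(vapply(entries, inherits, logical(1), "factor_entry")))
  nm <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("factor names must be unique", call. = FALSE)
  names(entries) <- nm
  structure(entries, class = "factor_scheme")
}

#' Default causative-factor scheme
#'
#' Class intervals reconstructed from the intervals named in the source
#' study's results: tree cover 25-50/51-75/75-100 percent; elevation
#' 0-100/100-500/500-2000/>2000 m; slope in 5-degree bins to 90; aspect in
#' eight compass octants (flat cells, sentinel -1, fall outside the breaks
#' and are excluded); fire-season temperature in 10 degree C bins; population
#' density 0-25/25-50/50-75/75-150/150-300/>300 per km2; travel time in
#' hour bins; distances to road and forest edge 0-1/1-5/5-50/>50 km; land
#' cover as categorical codes. All intervals are config-overridable.
#'
#' @param landcover_codes integer codes present in the land cover layer.
#' @return A `factor_scheme`.
#' @export
default_factor_scheme <- function(landcover_codes = 1:8) {
  factor_scheme(list(
    factor_entry("tree_cover", "continuous", breaks = c(25, 51, 75, 100)),
    factor_entry("land_cover", "categorical", codes = landcover_codes),
    factor_entry("elevation", "continuous",
                 breaks = c(0, 100, 500, 2000, Inf)),
    factor_entry("slope", "continuous", breaks = seq(0, 90, by = 5)),
    factor_entry("aspect", "continuous", breaks = seq(0, 360, by = 45)),
    factor_entry("temperature", "continuous",
                 breaks = seq(-10, 50, by = 10)),
    factor_entry("population", "continuous",
                 breaks = c(0, 25, 50, 75, 150, 300, Inf)),
    factor_entry("travel_time", "continuous",
                 breaks = c(0, 1, 2, 3, 5, Inf)),
    factor_entry("dist_road", "continuous", breaks = c(0, 1, 5, 50, Inf)),
    factor_entry("dist_edge", "continuous", breaks = c(0, 1, 5, 50, Inf))
  ))
}

#' Classify a covariate raster into scheme classes
#'
#' Continuous values are binned left-closed/right-open against the entry's
#' breakpoints, with the final interval closed on the right; a value exactly
#' at an interior breakpoint belongs to the upper class. Values outside the
#' breakpoints become nodata and their count is attached as attribute
#' `n_out_of_range`. Categorical values keep their own codes; codes not in
#' the entry's list become nodata.
#'
#' @param x `fire_raster` of the factor's values.
#' @param entry the matching `factor_entry`.
#' @return Categorical `fire_raster` of class codes (1-based interval index
#'   for continuous factors, original codes for categorical factors) with a
#'   `labels` attribute naming each code.
#' @export
classify_factor <- function(x, entry) {
  stopifnot(inherits(x, "fire_raster"), inherits(entry, "factor_entry"))
  v <- x$values
  if (entry$kind == "continuous") {
    br <- entry$breaks
    k <- length(br) - 1L
    cls <- matrix(NA_real_, nrow(v), ncol(v))
    ok <- !is.na(v) & v >= br[1] & v <= br[k + 1]
    idx <- findInterval(v[ok], br, rightmost.closed = TRUE)
    cls[ok] <- idx
    codes <- seq_len(k)
  } else {
    cls <- ifelse(!is.na(v) & v %in% entry$codes, v, NA_real_)
    dim(cls) <- dim(v)
    ok <- !is.na(cls) | is.na(v)
    codes <- entry$codes
  }
  n_out <- sum(!is.na(v)) - sum(!is.na(cls))
  if (all(is.na(cls)))
    stop("empty-classification error: no value of '", entry$name,
         "' falls inside its classes", call. = FALSE)
  out <- with_values(x, cls, "categorical")
  attr(out, "labels") <- stats::setNames(entry$labels, codes)
  attr(out, "n_out_of_range") <- n_out
  out
}

#' Classify every factor of a stack
#'
#' @param stack named list of `fire_raster`s covering the scheme's factors.
#' @param scheme a `factor_scheme`.
#' @return Named list of categorical class rasters, one per factor.
#' @export
classify_stack <- function(stack, scheme) {
  stopifnot(inherits(scheme, "factor_scheme"))
  missing <- setdiff(names(scheme), names(stack))
  if (length(missing))
    stop("stack lacks factor layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(stats::setNames(names(scheme), names(scheme)), function(nm)
    classify_factor(stack[[nm]], scheme[[nm]]))
}

#' Read / write a factor scheme as JSON
#'
#' @param scheme a `factor_scheme`.
#' @param path JSON file path.
#' @return `read_scheme_json()` returns a `factor_scheme`.
#' @export
write_scheme_json <- function(scheme, path) {
  lst <- lapply(unclass(scheme), function(e)
    list(name = e$name, kind = e$kind,
         breaks = e$breaks, codes = e$codes))
  jsonlite::write_json(unname(lst), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  factor_scheme(lapply(lst, function(e) {
    br <- if (!is.null(e$breaks)) {
      b <- unlist(e$breaks)
      b[b == "Inf"] <- Inf
      as.numeric(b)
    }
    factor_entry(e$name, e$kind, breaks = br,
                 codes = if (!is.null(e$codes)) as.numeric(unlist(e$codes)))
  }))
}
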