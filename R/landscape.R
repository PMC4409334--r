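#' Synthetic landscape configuration
#'
#' Parameters of the synthetic covariate stack, confounded protection mask,
#' and Bernoulli fire process used for testing. The generator emulates the
#' statistical structure the analysis assumes: spatially autocorrelated
#' covariates, elevation-temperature anticorrelation via a lapse rate,
#' log-normal population density decreasing with elevation, road/city
#' networks feeding distance and travel-time layers, and protected-area
#' patches whose assignment odds are confounded with elevation and
#' population. Fire occurrence is Bernoulli with logit
#' `beta0 + sum(beta_j * z_j) + delta * T`, where `z_j` are the covariates
#' standardized over the landscape, so every downstream estimator can be
#' checked against closed-form counterfactual truth.
#'
#' Coefficients are per standard deviation of the covariate. The defaults
#' state a moderately confounded world: protection favours high-elevation,
#' low-population cells (as remote protected areas are in practice), fire is
#' driven up by population, temperature and road access and down by
#' elevation and tree cover, and protection lowers the fire logit by
#' `delta = -0.5` (an ATT near -0.1 at the default baseline rate).
#'
#' @param n_rows,n_cols grid dimensions (default 100 x 100 at 1 km).
#' @param cell_size cell size in km.
#' @param seed integer seed; every generator output is a pure function of
#'   (config, seed).
#' @param smoothing_scale spatial autocorrelation length in cells.
#' @param elevation_range range of elevation in metres.
#' @param t0 sea-level fire-season temperature, degrees C.
#' @param lapse_rate temperature decrease per metre of elevation (degrees
#'   C/m; 0.0065 is the standard environmental lapse rate).
#' @param temp_noise_sd temperature noise SD, degrees C.
#' @param pop_mean_log,pop_sd_log,pop_elev_coef log-normal population
#'   density parameters; `pop_elev_coef` multiplies standardized elevation
#'   on the log scale (negative: fewer people high up).
#' @param n_landcover_classes number of categorical land cover classes.
#' @param n_roads,n_cities counts of random road transects and city cells.
#' @param travel_speed_kmh converts distance to nearest city into travel
#'   time in hours.
#' @param forest_edge_threshold tree-cover percent defining the forest mask
#'   used only to build the distance-to-forest-edge layer.
#' @param protection list: `n_patches`, `radius_range` (cells),
#'   `base_logit`, `conf_elev`, `conf_pop` (confounding coefficients linking
#'   a candidate patch's acceptance odds to its mean standardized elevation
#'   and population; both 0 gives unconfounded protection).
#' @param fire_model list: `beta0` (intercept), `beta` (named per-SD
#'   coefficients over covariate layers), `delta` (protection effect on the
#'   logit).
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 100, n_cols = 100, cell_size = 1,
                             seed = 1L,
                             smoothing_scale = 8,
                             elevation_range = c(0, 2500),
                             t0 = 28, lapse_rate = 0.0065,
                             temp_noise_sd = 0.5,
                             pop_mean_log = log(30), pop_sd_log = 1,
                             pop_elev_coef = -0.8,
                             n_landcover_classes = 5,
                             n_roads = 5, n_cities = 5,
                             travel_speed_kmh = 30,
                             forest_edge_threshold = 60,
                             protection = list(n_patches = 25,
                                               radius_range = c(4, 10),
                                               base_logit = 0,
                                               conf_elev = 1,
                                               conf_pop = -1),
                             fire_model = list(
                               beta0 = -1.5,
                               beta = c(elevation = -0.5, temperature = 0.4,
                                        population = 0.5, tree_cover = -0.3,
                                        dist_road = -0.3, travel_time = -0.2,
                                        slope = 0, aspect = 0,
                                        dist_edge = -0.2),
                               delta = -0.5)) {
  stopifnot(n_rows >= 3, n_cols >= 3, cell_size > 0,
            protection$n_patches >= 1, n_roads >= 1, n_cities >= 1)
  structure(as.list(environment()), class = "landscape_config")
}

## stationary Gaussian random field: FFT-smoothed white noise on a torus,
## standardized to mean 0 / sd 1
gaussian_field <- function(n_rows, n_cols, scale) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale <= 0) return(w)
  di <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dj <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * scale^2))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

## mark the cells a segment (r0,c0)-(r1,c1) passes through
trace_line_cells <- function(m, r0, c0, r1, c1) {
  n <- max(2L, ceiling(4 * max(abs(r1 - r0), abs(c1 - c0))))
  t <- seq(0, 1, length.out = n)
  rr <- pmin(pmax(round(r0 + t * (r1 - r0)), 1), nrow(m))
  cc <- pmin(pmax(round(c0 + t * (c1 - c0)), 1), ncol(m))
  m[cbind(rr, cc)] <- 1
  m
}

zscore <- function(v) {
  s <- stats::sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) return(v * 0)
  (v - mean(v, na.rm = TRUE)) / s
}

#' Generate the synthetic covariate stack and protection mask
#'
#' Builds every layer the analysis consumes (see [landscape_config()] for the
#' stated world). Protection is assigned at the patch level: candidate disk
#' patches are accepted with probability
#' `plogis(base_logit + conf_elev * z_elev + conf_pop * z_pop)` of their mean
#' standardized elevation and population, so cell-level protection is
#' confounded with both. Patch metadata is attached as attribute `patches`.
#'
#' @param config a `landscape_config`.
#' @param seed RNG seed (default `config$seed`).
#' @return Named list of aligned `fire_raster`s: `tree_cover`, `land_cover`,
#'   `elevation`, `slope`, `aspect`, `temperature`, `population`,
#'   `travel_time`, `dist_road`, `dist_edge`, `protection`; attributes
#'   `patches` (patch metadata `data.frame`) and `geometry`.
#' @export
generate_covariates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(seed)
  nr <- config$n_rows; nc <- config$n_cols
  geom <- grid_geometry(nr, nc, config$cell_size)
  sc <- config$smoothing_scale

  elev_z <- gaussian_field(nr, nc, sc)
  er <- config$elevation_range
  elev <- er[1] + (er[2] - er[1]) * stats::pnorm(elev_z)
  elevation <- raster_layer(elev, geom, "continuous")
  sa <- slope_aspect(elevation)

  temp <- config$t0 - config$lapse_rate * elev +
    config$temp_noise_sd * gaussian_field(nr, nc, sc / 2)

  pop <- exp(config$pop_mean_log + config$pop_elev_coef * zscore(elev) +
               config$pop_sd_log * gaussian_field(nr, nc, sc))

  tree <- 25 + 75 * stats::pnorm(gaussian_field(nr, nc, sc))

  lc_latent <- gaussian_field(nr, nc, sc / 2)
  qs <- stats::quantile(lc_latent,
                        seq_len(config$n_landcover_classes - 1) /
                          config$n_landcover_classes)
  land <- matrix(findInterval(lc_latent, qs) + 1, nr, nc)

  roads <- matrix(0, nr, nc)
  for (i in seq_len(config$n_roads))
    roads <- trace_line_cells(roads, stats::runif(1, 1, nr),
                              stats::runif(1, 1, nc),
                              stats::runif(1, 1, nr), stats::runif(1, 1, nc))
  dist_road <- euclidean_distance(raster_layer(roads, geom, "binary"))

  cities <- matrix(0, nr, nc)
  cities[cbind(sample.int(nr, config$n_cities, replace = TRUE),
               sample.int(nc, config$n_cities, replace = TRUE))] <- 1
  travel <- euclidean_distance(raster_layer(cities, geom, "binary"))
  travel <- with_values(travel, travel$values / config$travel_speed_kmh,
                        "continuous")

  forest <- (tree >= config$forest_edge_threshold) * 1
  edge <- forest_edge_mask(forest)
  if (!any(edge == 1)) edge[which.min(tree)] <- 1  # degenerate all-forest case
  dist_edge <- euclidean_distance(raster_layer(edge, geom, "binary"))

  pr <- config$protection
  zc_elev <- zscore(elev); zc_pop <- zscore(log(pop))
  prot <- matrix(0, nr, nc)
  ctr_r <- stats::runif(pr$n_patches, 1, nr)
  ctr_c <- stats::runif(pr$n_patches, 1, nc)
  rad <- stats::runif(pr$n_patches, pr$radius_range[1], pr$radius_range[2])
  u <- stats::runif(pr$n_patches)
  patches <- vector("list", pr$n_patches)
  rows <- row(prot); cols <- col(prot)
  for (p in seq_len(pr$n_patches)) {
    inside <- (rows - ctr_r[p])^2 + (cols - ctr_c[p])^2 <= rad[p]^2
    me <- mean(zc_elev[inside]); mp <- mean(zc_pop[inside])
    p_acc <- stats::plogis(pr$base_logit + pr$conf_elev * me +
                             pr$conf_pop * mp)
    accepted <- u[p] < p_acc
    if (accepted) prot[inside] <- 1
    patches[[p]] <- data.frame(patch = p, center_row = ctr_r[p],
                               center_col = ctr_c[p], radius = rad[p],
                               mean_elev_z = me, mean_pop_z = mp,
                               p_accept = p_acc, accepted = accepted)
  }
  stack <- list(
    tree_cover = raster_layer(tree, geom, "continuous"),
    land_cover = raster_layer(land, geom, "categorical"),
    elevation = elevation,
    slope = sa$slope,
    aspect = sa$aspect,
    temperature = raster_layer(temp, geom, "continuous"),
    population = raster_layer(pop, geom, "continuous"),
    travel_time = travel,
    dist_road = dist_road,
    dist_edge = dist_edge,
    protection = raster_layer(prot, geom, "binary")
  )
  attr(stack, "patches") <- do.call(rbind, patches)
  attr(stack, "geometry") <- geom
  stack
}

## cells where the 4-neighbourhood mixes forest and non-forest
forest_edge_mask <- function(forest) {
  nr <- nrow(forest); nc <- ncol(forest)
  up <- rbind(forest[1, ], forest[-nr, ])
  dn <- rbind(forest[-1, ], forest[nr, ])
  lf <- cbind(forest[, 1], forest[, -nc])
  rt <- cbind(forest[, -1], forest[, nc])
  nbmin <- pmin(up, dn, lf, rt)
  nbmax <- pmax(up, dn, lf, rt)
  ((forest == 1 & nbmin == 0) | (forest == 0 & nbmax == 1)) * 1
}

## per-cell fire logits with and without protection, from stack + config
fire_logits <- function(stack, config) {
  fm <- config$fire_model
  logit0 <- matrix(fm$beta0, config$n_rows, config$n_cols)
  for (nm in names(fm$beta)) {
    if (fm$beta[[nm]] == 0) next
    if (is.null(stack[[nm]]))
      stop("fire model names unknown covariate '", nm, "'", call. = FALSE)
    logit0 <- logit0 + fm$beta[[nm]] * zscore(stack[[nm]]$values)
  }
  if (any(!is.finite(logit0)))
    stop("non-finite fire logits", call. = FALSE)
  logit0
}

#' Closed-form ground truth of the synthetic fire process
#'
#' Recomputes, deterministically from the emitted stack and config, the
#' counterfactual quantities of the generator: the true ATT over treated
#' cells (mean of `plogis(logit0 + delta) - plogis(logit0)` over protected
#' cells), expected fire rates by stratum, and the per-SD effect sizes.
#'
#' @param stack a stack from [generate_covariates()].
#' @param config the generating `landscape_config`.
#' @param subset optional logical or integer index over cells (in column-major
#'   cell order) restricting the treated set, e.g. to matched treated units.
#' @return List with `att_treated`, `rate_protected`, `rate_nonprotected`,
#'   `density_ratio` (non-protected over protected expected rate),
#'   `effect_sizes`.
#' @export
landscape_truth <- function(stack, config, subset = NULL) {
  logit0 <- fire_logits(stack, config)
  delta <- config$fire_model$delta
  p0 <- stats::plogis(logit0)
  p1 <- stats::plogis(logit0 + delta)
  prot <- stack$protection$values == 1
  treated <- prot
  if (!is.null(subset)) {
    sel <- matrix(FALSE, nrow(logit0), ncol(logit0))
    sel[subset] <- TRUE
    treated <- treated & sel
  }
  rate_p <- mean(p1[prot])
  rate_np <- mean(p0[!prot])
  list(att_treated = mean(p1[treated] - p0[treated]),
       rate_protected = rate_p,
       rate_nonprotected = rate_np,
       density_ratio = rate_np / rate_p,
       effect_sizes = config$fire_model$beta)
}

#' Draw Bernoulli fire occurrence from the synthetic fire model
#'
#' Per cell, fire ~ Bernoulli(plogis(beta0 + beta' z + delta T)). The truth
#' record of [landscape_truth()] is attached as attribute `truth`.
#'
#' @param stack a stack from [generate_covariates()].
#' @param config the `landscape_config` (its `fire_model` is used).
#' @param seed RNG seed (default `config$seed + 1`).
#' @return Binary `fire_raster` with attribute `truth`.
#' @export
generate_fires <- function(stack, config, seed = config$seed + 1L) {
  logit0 <- fire_logits(stack, config)
  p <- stats::plogis(logit0 + config$fire_model$delta *
                       (stack$protection$values == 1))
  set.seed(seed)
  fire <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
  r <- raster_layer(fire, attr(stack, "geometry"), "binary")
  attr(r, "truth") <- landscape_truth(stack, config)
  r
}

#' Generate a complete synthetic landscape
#'
#' Covariate stack, protection mask and fire raster in one call; the fire
#' layer is added to the stack under the name `fire`.
#'
#' @param config a `landscape_config`.
#' @return List with `stack` (including `fire`), `truth`, `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stack <- generate_covariates(config)
  fire <- generate_fires(stack, config)
  stack$fire <- fire
  list(stack = stack, truth = attr(fire, "truth"), config = config)
}

#' Emit fire detections as an MCD14ML-dialect CSV
#'
#' Writes one detection row per fire cell, located at the cell centre, with
#' the full MCD14ML column set plus the synthetic-dialect `x_km`/`y_km`
#' projected coordinates. Latitude/longitude are back-filled from a nominal
#' anchor (21 N, 96 E) purely to keep the columns plausible; ingestion uses
#' `x_km`/`y_km`. Confidence is drawn from a two-point distribution (default
#' values 80 and 100 with probabilities 0.25/0.75) so the high-confidence
#' filter path is exercised. Rasterizing the emitted CSV at
#' `min_confidence = 0` reproduces the source raster exactly.
#'
#' @param fire binary `fire_raster`.
#' @param path output CSV path.
#' @param confidence list with `values` and `probs` of the confidence
#'   distribution.
#' @param seed RNG seed for the confidence draw.
#' @return `path`, invisibly.
#' @export
emit_fire_csv <- function(fire, path,
                          confidence = list(values = c(80, 100),
                                            probs = c(0.25, 0.75)),
                          seed = 1L) {
  stopifnot(inherits(fire, "fire_raster"), fire$kind == "binary")
  g <- fire$geometry
  idx <- which(fire$values == 1, arr.ind = TRUE)
  x <- g$origin[1] + (idx[, 2] - 0.5) * g$cell_size
  y <- g$origin[2] - (idx[, 1] - 0.5) * g$cell_size
  set.seed(seed)
  conf <- confidence$values[sample.int(length(confidence$values), nrow(idx),
                                       replace = TRUE,
                                       prob = confidence$probs)]
  df <- data.frame(
    latitude = 21 + y / 111.32,
    longitude = 96 + x / (111.32 * cos(21 * pi / 180)),
    brightness = round(stats::runif(nrow(idx), 310, 360), 1),
    scan = 1.0, track = 1.0,
    acq_date = "2005-03-15",
    acq_time = sprintf("%04d", sample(0:2359, nrow(idx), replace = TRUE)),
    satellite = sample(c("T", "A"), nrow(idx), replace = TRUE),
    confidence = conf,
    version = "5.1",
    x_km = x, y_km = y
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
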