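cls_raster <- function(m) raster_layer(m, kind = "categorical")
bin_raster <- function(m) raster_layer(m, kind = "binary")

test_that("frequency ratio reproduces the hand-counted example", {
  # 10 cells: class 1 has 4 cells / 2 fires, class 2 has 6 cells / 1 fire
  cls <- cls_raster(matrix(c(rep(1, 4), rep(2, 6)), 2, 5))
  fire <- bin_raster(matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0), 2, 5))
  frt <- frequency_ratio_table(fire, cls)
  expect_equal(frt$fr[frt$class_code == 1], (2 / 3) / (4 / 10),
               tolerance = 1e-12)
  expect_equal(frt$fr[frt$class_code == 2], (1 / 3) / (6 / 10),
               tolerance = 1e-12)
  expect_equal(frt$n_cells, c(4L, 6L))
  expect_equal(frt$n_fire_cells, c(2L, 1L))
})

test_that("uniform fire gives fr = 1 and all-fire classes exceed 1", {
  cls <- cls_raster(matrix(sample(1:3, 100, TRUE), 10, 10))
  allfire <- bin_raster(matrix(1, 10, 10))
  frt <- frequency_ratio_table(allfire, cls)
  expect_equal(frt$fr, rep(1, nrow(frt)), tolerance = 1e-12)

  # a minority class holding every fire has fr > 1 (elevated propensity)
  cls2 <- cls_raster(matrix(c(rep(1, 3), rep(2, 97)), 10, 10))
  fire2 <- bin_raster(matrix(c(rep(1, 3), rep(0, 97)), 10, 10))
  frt2 <- frequency_ratio_table(fire2, cls2)
  expect_gt(frt2$fr[frt2$class_code == 1], 1)
  expect_equal(frt2$fr[frt2$class_code == 2], 0)
})

test_that("frequency ratio matches the brute-force oracle with strata", {
  set.seed(23)
  for (rep in 1:10) {
    cls <- matrix(sample(1:5, 400, TRUE), 20, 20)
    fire <- matrix(rbinom(400, 1, 0.3), 20, 20)
    mask <- matrix(rbinom(400, 1, 0.5), 20, 20)
    cls[sample(400, 20)] <- NA
    if (sum(fire[mask == 1 & !is.na(cls)] == 1, na.rm = TRUE) == 0) next
    frt <- frequency_ratio_table(bin_raster(fire), cls_raster(cls),
                                 bin_raster(mask))
    orc <- oracle_fr(fire, cls, mask)
    expect_equal(frt$class_code, orc$class_code)
    expect_equal(frt$n_cells, orc$n_cells)
    expect_equal(frt$n_fire_cells, orc$n_fire_cells)
    expect_equal(frt$fr, orc$fr, tolerance = 1e-12)
  }
})

test_that("degenerate stratum without fires errors with the stratum name", {
  cls <- cls_raster(matrix(1:2, 2, 2))
  fire <- bin_raster(matrix(0, 2, 2))
  expect_error(frequency_ratio_table(fire, cls, stratum = "protected"),
               "degenerate-stratum.*protected")
})

test_that("FR conservation identity holds on random grids", {
  set.seed(29)
  for (rep in 1:5) {
    cls <- cls_raster(matrix(sample(1:6, 2500, TRUE), 50, 50))
    fire <- bin_raster(matrix(rbinom(2500, 1, 0.2), 50, 50))
    frt <- frequency_ratio_table(fire, cls)
    expect_equal(sum(frt$fr * frt$n_cells / attr(frt, "N_cells")), 1,
                 tolerance = 1e-12)
  }
})

test_that("FR table is invariant to rescaling a covariate and its breaks", {
  set.seed(37)
  v <- matrix(runif(400, 0, 100), 20, 20)
  fire <- bin_raster(matrix(rbinom(400, 1, 0.25), 20, 20))
  br <- c(0, 20, 55, 100)
  c1 <- classify_factor(raster_layer(v, kind = "continuous"),
                        factor_entry("a", "continuous", breaks = br))
  c2 <- classify_factor(raster_layer(v * 3.7, kind = "continuous"),
                        factor_entry("a", "continuous", breaks = br * 3.7))
  f1 <- frequency_ratio_table(fire, c1)
  f2 <- frequency_ratio_table(fire, c2)
  expect_equal(f1$fr, f2$fr)
  expect_equal(f1$n_cells, f2$n_cells)
})

test_that("FSI sums per-cell factor FRs and handles identities", {
  set.seed(41)
  cls <- lapply(1:3, function(i)
    cls_raster(matrix(sample(1:4, 400, TRUE), 20, 20)))
  names(cls) <- c("f1", "f2", "f3")
  fire <- bin_raster(matrix(rbinom(400, 1, 0.3), 20, 20))
  frt <- do.call(rbind, lapply(names(cls), function(f)
    frequency_ratio_table(fire, cls[[f]], factor_name = f)))
  smap <- fire_susceptibility_index(frt, cls)

  # brute-force per-cell lookup-and-sum oracle
  expected <- matrix(0, 20, 20)
  for (f in names(cls)) {
    rows <- frt[frt$factor == f, ]
    lut <- setNames(rows$fr, rows$class_code)
    expected <- expected + matrix(lut[as.character(values_of(cls[[f]]))],
                                  20, 20)
  }
  expect_equal(values_of(smap$fsi), expected, tolerance = 1e-12)

  # all-unit-FR factors sum to the factor count
  allfire <- bin_raster(matrix(1, 20, 20))
  frt_u <- do.call(rbind, lapply(names(cls)[1:2], function(f)
    frequency_ratio_table(allfire, cls[[f]], factor_name = f)))
  smap_u <- fire_susceptibility_index(frt_u, cls[1:2])
  expect_equal(values_of(smap_u$fsi), matrix(2, 20, 20), tolerance = 1e-12)

  # single factor: FSI equals that factor's FR raster
  smap_1 <- fire_susceptibility_index(frt[frt$factor == "f1", ], cls[1])
  expect_equal(values_of(smap_1$fsi), values_of(smap_1$fr_rasters$f1))

  # appending a unit-FR factor raises FSI by exactly 1 everywhere
  frt_plus <- rbind(frt, frequency_ratio_table(allfire, cls$f1,
                                               factor_name = "f4"))
  cls_plus <- c(cls, list(f4 = cls$f1))
  smap_plus <- fire_susceptibility_index(frt_plus, cls_plus)
  expect_equal(values_of(smap_plus$fsi), values_of(smap$fsi) + 1,
               tolerance = 1e-12)
})

test_that("FSI flags classes without FR rows", {
  cls <- list(f1 = cls_raster(matrix(1:2, 2, 2)))
  frt <- data.frame(factor = "f1", class_code = 1, fr = 1)
  expect_error(fire_susceptibility_index(frt, cls), "consistency")
})

test_that("nodata in any factor propagates to the FSI", {
  m <- matrix(sample(1:2, 16, TRUE), 4, 4)
  m2 <- m; m2[2, 2] <- NA
  cls <- list(f1 = cls_raster(m), f2 = cls_raster(m2))
  fire <- bin_raster(matrix(rbinom(16, 1, 0.5), 4, 4))
  frt <- do.call(rbind, lapply(names(cls), function(f)
    frequency_ratio_table(fire, cls[[f]], factor_name = f)))
  smap <- fire_susceptibility_index(frt, cls)
  expect_true(is.na(values_of(smap$fsi)[2, 2]))
  expect_equal(sum(is.na(values_of(smap$fsi))), 1)
})

test_that("rank_factors orders by masked mean FR with alphabetical ties", {
  set.seed(43)
  cls <- list(b = cls_raster(matrix(sample(1:3, 100, TRUE), 10, 10)),
              a = cls_raster(matrix(sample(1:3, 100, TRUE), 10, 10)))
  fire <- bin_raster(matrix(rbinom(100, 1, 0.4), 10, 10))
  frt <- do.call(rbind, lapply(names(cls), function(f)
    frequency_ratio_table(fire, cls[[f]], factor_name = f)))
  smap <- fire_susceptibility_index(frt, cls)
  rk <- rank_factors(smap, 0.8)

  fsi <- values_of(smap$fsi)
  thr <- quantile(fsi, 0.8, names = FALSE)
  sel <- fsi >= thr
  for (f in names(cls))
    expect_equal(rk$mean_fr[rk$factor == f],
                 mean(values_of(smap$fr_rasters[[f]])[sel]))
  expect_equal(rk$mean_fr, sort(rk$mean_fr, decreasing = TRUE))

  # single factor is trivially rank 1
  rk1 <- rank_factors(fire_susceptibility_index(frt[frt$factor == "a", ],
                                                cls["a"]), 0.5)
  expect_equal(rk1$factor, "a")

  # exact ties resolve alphabetically
  allfire <- bin_raster(matrix(1, 10, 10))
  frt_t <- do.call(rbind, lapply(names(cls), function(f)
    frequency_ratio_table(allfire, cls[[f]], factor_name = f)))
  rk_t <- rank_factors(fire_susceptibility_index(frt_t, cls), 0.5)
  expect_equal(rk_t$factor, c("a", "b"))
})

test_that("fire density is fires per km2 of stratum", {
  fire <- bin_raster(matrix(c(rep(1, 5), rep(0, 95)), 10, 10))
  expect_equal(fire_density(fire), 0.05)
  expect_equal(fire_density(bin_raster(matrix(1, 4, 4))), 1)
  mask <- bin_raster(matrix(c(rep(1, 50), rep(0, 50)), 10, 10))
  expect_equal(fire_density(fire, mask), 5 / 50)
  empty <- bin_raster(matrix(0, 10, 10))
  expect_error(fire_density(fire, empty), "empty")
  # cell size scales the area
  f2 <- raster_layer(matrix(c(1, 0, 0, 0), 2, 2), grid_geometry(2, 2, 2),
                     "binary")
  expect_equal(fire_density(f2), 1 / 16)
})
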