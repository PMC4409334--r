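test_that("unit table counts, complete cases and the forest rule", {
  set.seed(51)
  cfg <- landscape_config(n_rows = 20, n_cols = 20, seed = 3,
                          smoothing_scale = 4)
  L <- generate_landscape(cfg)
  u <- build_unit_table(L$stack, forest_only = FALSE)
  expect_equal(nrow(u), 400)
  expect_equal(sum(u$T), sum(values_of(L$stack$protection)))
  expect_equal(sum(u$Y), sum(values_of(L$stack$fire)))

  # nodata elevation drops exactly that cell
  st2 <- L$stack
  st2$elevation$values[5, 5] <- NA
  u2 <- build_unit_table(st2, forest_only = FALSE)
  expect_equal(nrow(u2), 399)
  expect_false(any(u2$row == 5 & u2$col == 5))

  # forest restriction equals a brute-force mask intersection
  u3 <- build_unit_table(L$stack, forest_only = TRUE, forest_threshold = 60)
  tc <- values_of(L$stack$tree_cover)
  expect_equal(nrow(u3), sum(tc >= 60))
  expect_true(all(tc[cbind(u3$row, u3$col)] >= 60))
})

test_that("identity covariance reduces Mahalanobis matching to Euclidean", {
  set.seed(53)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2)
  X <- scale(X %*% solve(chol(cov(X))))  # exactly whitened
  colnames(X) <- c("x1", "x2")
  Tr <- rep(c(1, 0), c(15, n - 15))
  u <- make_units(X, Tr, rbinom(n, 1, 0.5))
  m <- mahalanobis_match(u, caliper_sd = Inf)
  co <- which(Tr == 0)
  for (i in seq_along(m$treated)) {
    d <- sqrt(colSums((t(X[co, ]) - X[m$treated[i], ])^2))
    expect_true(all(m$matches[[i]] %in% co[d <= min(d) + 1e-8]))
  }
})

test_that("exact covariate twins match at distance zero", {
  set.seed(59)
  Xt <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X <- rbind(Xt, Xt, matrix(rnorm(60), 30, 2, dimnames = list(NULL, NULL)))
  colnames(X) <- c("a", "b")
  Tr <- rep(c(1, 0), c(20, 50))
  u <- make_units(X, Tr, rbinom(70, 1, 0.5))
  m <- mahalanobis_match(u)
  for (i in 1:20) {
    expect_equal(m$matches[[i]], 20 + i)
    expect_equal(m$distances[[i]], 0)
  }
})

test_that("matching equals the all-pairs brute-force scan", {
  set.seed(61)
  for (rep in 1:15) {
    n <- sample(20:80, 1)
    d <- sample(2:4, 1)
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, paste0("x", 1:d)))
    Tr <- rbinom(n, 1, 0.3)
    if (sum(Tr) < 1 || sum(Tr) > n - 1) next
    cal <- sample(c(0.5, 1, Inf), 1)
    u <- make_units(X, Tr, rbinom(n, 1, 0.5))
    got <- tryCatch(mahalanobis_match(u, caliper_sd = cal),
                    error = function(e) e)
    want <- oracle_match(X, Tr, cal)
    if (inherits(got, "error")) {
      expect_true(all(lengths(want) == 0))
      next
    }
    for (i in seq_along(got$treated)) {
      expect_equal(sort(got$matches[[i]]), want[[i]])
      if (length(got$matches[[i]])) {
        expect_equal(got$weights[[i]],
                     rep(1 / length(want[[i]]), length(want[[i]])))
      } else expect_true(got$excluded[i])
    }
  }
})

test_that("matches are invariant under invertible affine maps of X", {
  set.seed(67)
  for (rep in 1:5) {
    n <- 80
    X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    Tr <- rbinom(n, 1, 0.3)
    if (sum(Tr) < 2 || sum(Tr) > n - 2) next
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    X2 <- X %*% A + matrix(rnorm(3), n, 3, byrow = TRUE)
    colnames(X2) <- colnames(X)
    u1 <- make_units(X, Tr, rbinom(n, 1, 0.5))
    u2 <- make_units(X2, Tr, u1$Y)
    m1 <- mahalanobis_match(u1, caliper_sd = Inf)
    m2 <- mahalanobis_match(u2, caliper_sd = Inf)
    for (i in seq_along(m1$treated))
      expect_equal(sort(m1$matches[[i]]), sort(m2$matches[[i]]))
  }
})

test_that("matching commutes with unit reordering", {
  set.seed(71)
  n <- 50
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  Tr <- rep(c(1, 0), c(12, 38))
  u <- make_units(X, Tr, rbinom(n, 1, 0.5))
  m <- mahalanobis_match(u, caliper_sd = Inf)
  perm <- sample(n)
  u2 <- make_units(X[perm, ], Tr[perm], u$Y[perm])
  m2 <- mahalanobis_match(u2, caliper_sd = Inf)
  inv <- match(seq_len(n), perm)   # old index -> new index
  for (i in seq_along(m$treated)) {
    j <- which(m2$treated == inv[m$treated[i]])
    expect_equal(sort(inv[m$matches[[i]]]), sort(m2$matches[[j]]))
  }
})

test_that("caliper exclusions count and error when total", {
  X <- matrix(c(0, 0, 100, 1, 1.1, 0.9), ncol = 1,
              dimnames = list(NULL, "a"))
  Tr <- c(1, 1, 1, 0, 0, 0)
  u <- make_units(X, Tr, c(1, 0, 1, 0, 1, 0))
  m <- mahalanobis_match(u, caliper_sd = 0.5)
  expect_equal(sum(m$excluded), 1)  # the treated unit at 100

  Xfar <- matrix(c(0, 0, 10, 10.5), ncol = 1, dimnames = list(NULL, "a"))
  ufar <- make_units(Xfar, c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_error(mahalanobis_match(ufar, caliper_sd = 0.1), "caliper")
})

test_that("ATT: null effect, constructed constant effect, duplicate controls", {
  set.seed(73)
  Xt <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  X <- rbind(Xt, Xt)
  colnames(X) <- c("a", "b")
  Tr <- rep(c(1, 0), each = 15)
  ytw <- rbinom(15, 1, 0.5)

  # outcomes identical to matches -> ATT 0
  u0 <- make_units(X, Tr, c(ytw, ytw))
  m0 <- mahalanobis_match(u0)
  expect_equal(att_estimate(u0, m0)$att, 0)

  # deterministic shift: treated outcome = twin outcome + 1
  u1 <- make_units(X, Tr, c(rep(1, 15), rep(0, 15)))
  m1 <- mahalanobis_match(u1)
  e1 <- att_estimate(u1, m1)
  expect_equal(e1$att, 1)
  expect_equal(e1$n_treated_matched, 15)

  # replacement semantics: duplicating controls leaves the ATT unchanged
  Xd <- rbind(X, Xt)
  colnames(Xd) <- c("a", "b")
  ud <- make_units(Xd, c(Tr, rep(0, 15)), c(rep(1, 15), rep(0, 30)))
  md <- mahalanobis_match(ud, caliper_sd = Inf)
  expect_equal(att_estimate(ud, md)$att, 1)

  expect_error(att_estimate(u0, structure(list(
    treated = 1L, matches = list(2L), weights = list(1), distances = list(0),
    excluded = FALSE, covariates = c("a", "b"),
    covariance = diag(2), ridge = 0), class = "matched_sample")),
    "fewer than 2")
})

test_that("Abadie-Imbens SE is positive and the t ratio consistent", {
  set.seed(79)
  n <- 400
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  Tr <- rbinom(n, 1, 0.3)
  Y <- rbinom(n, 1, plogis(X[, 1]))
  u <- make_units(X, Tr, Y)
  m <- mahalanobis_match(u)
  e <- att_estimate(u, m)
  expect_gt(e$se, 0)
  expect_equal(e$t_value, e$att / e$se)
})

test_that("balance report: twin perfection, before-invariance, weighted oracle", {
  set.seed(83)
  Xt <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  Xc <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  X <- rbind(Xt, Xt, Xc)
  colnames(X) <- c("a", "b")
  Tr <- rep(c(1, 0), c(20, 60))
  u <- make_units(X, Tr, rbinom(80, 1, 0.4))
  m <- mahalanobis_match(u)
  b <- balance_report(u, m)
  expect_equal(b$variance_ratio_after, rep(1, 2))
  expect_equal(b$mean_treatment, b$mean_control_after)
  expect_equal(b$smd_after, rep(0, 2))

  # before columns do not depend on the match set
  m2 <- mahalanobis_match(u, caliper_sd = 0.2)
  b2 <- balance_report(u, m2)
  expect_equal(b2$mean_control_before, b$mean_control_before)
  expect_equal(b2$variance_ratio_before, b$variance_ratio_before)

  # weighted control moments equal the brute-force weighted oracle
  K <- numeric(nrow(u))
  for (i in seq_along(m$treated)) {
    mi <- m$matches[[i]]
    K[mi] <- K[mi] + m$weights[[i]]
  }
  used <- which(K > 0)
  om <- oracle_weighted_moments(X[used, "a"], K[used])
  expect_equal(b$mean_control_after[b$covariate == "a"], unname(om["mean"]))
  expect_equal(b$variance_ratio_after[b$covariate == "a"],
               unname(var(X[Tr == 1, "a"]) / om["var"]))
})

test_that("propensity model: null world, recovery, replication invariance", {
  set.seed(89)
  n <- 3000
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  # T independent of X
  u0 <- make_units(X, rbinom(n, 1, 0.4), rbinom(n, 1, 0.3))
  p0 <- fit_propensity(u0)
  expect_true(all(abs(p0$coefficients[-1]) < 0.15))
  expect_equal(mean(p0$scores), mean(u0$T), tolerance = 0.02)

  # known logistic model recovered within 3 SE at n = 20000
  set.seed(97)
  n2 <- 20000
  X2 <- matrix(rnorm(3 * n2), n2, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(-0.5, 0.8, -0.4, 0.2)
  T2 <- rbinom(n2, 1, plogis(beta[1] + X2 %*% beta[-1]))
  u2 <- make_units(X2, T2, rbinom(n2, 1, 0.3))
  p2 <- fit_propensity(u2)
  se <- sqrt(diag(p2$vcov))
  expect_true(all(abs(p2$coefficients - beta) <= 3 * se))
  expect_true(p2$converged)
  expect_true(all(p2$scores > 0 & p2$scores < 1))

  # duplicating every row leaves coefficients identical
  ud <- make_units(rbind(X, X), rep(u0$T, 2), rep(u0$Y, 2))
  pd <- fit_propensity(ud)
  expect_equal(pd$coefficients, p0$coefficients, tolerance = 1e-6)
})

test_that("separation is flagged and scores clipped", {
  X <- matrix(c(rep(1, 10), rep(-1, 10)), ncol = 1,
              dimnames = list(NULL, "a"))
  u <- make_units(X, rep(c(1, 0), each = 10), rbinom(20, 1, 0.5))
  expect_warning(p <- fit_propensity(u), "separation")
  expect_true(all(p$scores >= 1e-6 & p$scores <= 1 - 1e-6))
  expect_true(p$separation)
})

test_that("correlation screen flags only pairs at the threshold", {
  set.seed(101)
  n <- 500
  a <- rnorm(n)
  X <- cbind(a = a, b = a + rnorm(n, sd = 0.01), c = rnorm(n),
             d = -0.8 * a + 0.6 * rnorm(n), e = rep(2, n))
  u <- make_units(X, rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  expect_warning(sc <- correlation_screen(u), "constant")
  expect_equal(sc$constant, "e")
  expect_true(nrow(sc$flagged) == 1 &&
                all(sort(unlist(sc$flagged[1, 1:2])) == c("a", "b")))
  # strong but sub-threshold anticorrelation (the elevation-temperature
  # pattern) is not flagged
  r_ad <- sc$correlation["a", "d"]
  expect_lt(r_ad, -0.5)
  expect_false(any(sc$flagged$var1 == "d" | sc$flagged$var2 == "d"))
  expect_equal(diag(sc$correlation), rep(1, 4), ignore_attr = TRUE)
  # matrix equals direct computation
  expect_equal(sc$correlation, cor(X[, 1:4]), tolerance = 1e-12)
})
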