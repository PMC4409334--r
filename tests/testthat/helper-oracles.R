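# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops and stats::mahalanobis.

# lowest-code modal value of a vector, NA-excluded
oracle_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}

# per-block histogram majority aggregation of matrix m by factor k
oracle_block_mode <- function(m, k) {
  nr <- nrow(m) %/% k
  nc <- ncol(m) %/% k
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- oracle_mode(m[((i - 1) * k + 1):(i * k),
                               ((j - 1) * k + 1):(j * k)])
  out
}

# all-pairs Euclidean distance transform of a binary matrix, in cells
oracle_edt <- function(mask) {
  src <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    out[i, j] <- sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2))
  out
}

# per-class fire counts and frequency ratios by explicit looping
oracle_fr <- function(fire, cls, mask = NULL) {
  valid <- !is.na(cls) & !is.na(fire)
  if (!is.null(mask)) valid <- valid & !is.na(mask) & mask == 1
  N <- sum(valid)
  Nf <- sum(fire[valid] == 1)
  codes <- sort(unique(cls[valid]))
  do.call(rbind, lapply(codes, function(cd) {
    inc <- valid & cls == cd
    n <- sum(inc)
    nf <- sum(fire[inc] == 1)
    data.frame(class_code = cd, n_cells = n, n_fire_cells = nf,
               fr = (nf / Nf) / (n / N))
  }))
}

# linear-scan binning against breakpoints (left-closed, last closed)
oracle_bin <- function(v, breaks) {
  k <- length(breaks) - 1
  out <- rep(NA_real_, length(v))
  for (i in seq_along(v)) {
    if (is.na(v[i]) || v[i] < breaks[1] || v[i] > breaks[k + 1]) next
    for (b in seq_len(k)) {
      hi_ok <- if (b == k) v[i] <= breaks[b + 1] else v[i] < breaks[b + 1]
      if (v[i] >= breaks[b] && hi_ok) { out[i] <- b; break }
    }
  }
  out
}

# all-pairs Mahalanobis matching scan mirroring the documented contract:
# pooled covariance, relative tie tolerance, per-covariate SD caliper on the
# tied-best set
oracle_match <- function(X, Tr, caliper_sd = 1) {
  S <- cov(X)
  S <- S + diag(if (rcond(S) < 1e-10) 1e-8 * sum(diag(S)) / ncol(X) else 0,
                ncol(X))
  sds <- apply(X, 2, sd)
  tr <- which(Tr == 1); co <- which(Tr == 0)
  lapply(tr, function(t) {
    d2 <- apply(X[co, , drop = FALSE], 1, function(xc)
      stats::mahalanobis(xc, X[t, ], S))
    m <- min(d2)
    cand <- co[d2 <= m + 1e-8 * (1 + abs(m))]
    if (is.finite(caliper_sd)) {
      ok <- vapply(cand, function(cidx) {
        dd <- abs(X[cidx, ] - X[t, ])
        all(dd <= caliper_sd * sds | dd == 0)
      }, logical(1))
      cand <- cand[ok]
    }
    sort(cand)
  })
}

# small helper: unit table from raw pieces, bypassing raster plumbing
make_units <- function(X, Tr, Y) {
  df <- data.frame(unit_id = seq_len(nrow(X)), row = 1L, col = 1L,
                   T = Tr, Y = Y)
  df <- cbind(df, as.data.frame(X))
  attr(df, "covariates") <- colnames(X)
  class(df) <- c("unit_table", "data.frame")
  df
}

# weighted control mean/variance with frequency-weight normalization
oracle_weighted_moments <- function(x, w) {
  mw <- sum(w * x) / sum(w)
  vw <- sum(w * (x - mw)^2) / (sum(w) - 1)
  c(mean = mw, var = vw)
}

rand_binary_raster <- function(nr, nc, p = 0.1) {
  raster_layer(matrix(rbinom(nr * nc, 1, p), nr, nc), kind = "binary")
}
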