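#' Mahalanobis-distance matching with replacement and caliper
#'
#' Matches every treated unit (protected cell) to the control unit(s)
#' minimizing the Mahalanobis distance
#' \deqn{d(x_t, x_c) = \sqrt{(x_t - x_c)^\top S^{-1} (x_t - x_c)}}
#' where S is the pooled sample covariance of the covariates over all units.
#' Matching is with replacement: controls may serve several treated units.
#' Exact ties (to a small relative tolerance) are all retained with equal
#' weights, so results do not depend on input order. A caliper is applied
#' per covariate in standard-deviation units: a treated unit whose tied-best
#' matches all differ from it by more than `caliper_sd` sample standard
#' deviations on some covariate is left unmatched and counted.
#'
#' If S is numerically singular a ridge of `1e-8 * trace(S)/d` is added to
#' the diagonal (recorded in the result).
#'
#' @param units a `unit_table` from [build_unit_table()].
#' @param caliper_sd per-covariate caliper in SD units (default 1);
#'   `Inf` disables the caliper.
#' @param with_replacement must be `TRUE` (the supported design); matching
#'   without replacement is not implemented.
#' @param covariates covariate columns to match on (default: the table's
#'   covariate attribute).
#' @return An object of class `matched_sample`: list with `treated`
#'   (unit row indices of all treated units), `matches` (list of control row
#'   index vectors, `integer(0)` when excluded), `weights`, `distances`,
#'   `excluded` (logical per treated unit), `covariance`, `ridge`,
#'   `covariates`, `caliper_sd`, `sds` (covariate SDs used by the caliper).
#' @export
mahalanobis_match <- function(units, caliper_sd = 1, with_replacement = TRUE,
                              covariates = NULL) {
  stopifnot(inherits(units, "data.frame"))
  if (!isTRUE(with_replacement))
    stop("only matching with replacement is supported", call. = FALSE)
  if (is.null(covariates)) covariates <- attr(units, "covariates")
  X <- unit_covariate_matrix(units, covariates)
  tr <- which(units$T == 1)
  co <- which(units$T == 0)
  if (!length(co)) stop("no control units", call. = FALSE)
  S <- stats::cov(X)
  ridge <- 0
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps * sum(diag(S)))) {
    ridge <- 1e-8 * sum(diag(S)) / ncol(X)
    R <- chol(S + diag(ridge, ncol(X)))
  }
  W <- backsolve(R, diag(ncol(X)))
  Z <- X %*% W  # Euclidean in Z == Mahalanobis in X
  sds <- apply(X, 2, stats::sd)
  nn <- nearest_controls(Z[tr, , drop = FALSE], Z[co, , drop = FALSE])
  matches <- vector("list", length(tr))
  weights <- vector("list", length(tr))
  dists <- vector("list", length(tr))
  excluded <- logical(length(tr))
  for (i in seq_along(tr)) {
    cand <- co[nn$ties[[i]]]
    if (is.finite(caliper_sd)) {
      diffs <- abs(sweep(X[cand, , drop = FALSE], 2, X[tr[i], ]))
      okc <- apply(sweep(diffs, 2, caliper_sd * sds, `<=`) |
                     sweep(diffs, 2, 0, `==`), 1, all)
      cand <- cand[okc]
    }
    if (!length(cand)) {
      excluded[i] <- TRUE
      matches[[i]] <- integer(0)
      weights[[i]] <- numeric(0)
      dists[[i]] <- numeric(0)
    } else {
      matches[[i]] <- cand
      weights[[i]] <- rep(1 / length(cand), length(cand))
      ## recompute via the difference form: exact 0 for covariate twins
      diffw <- sweep(X[cand, , drop = FALSE], 2, X[tr[i], ]) %*% W
      dists[[i]] <- sqrt(rowSums(diffw^2))
    }
  }
  if (all(excluded))
    stop("all treated units excluded by the caliper", call. = FALSE)
  structure(list(treated = tr, matches = matches, weights = weights,
                 distances = dists, excluded = excluded,
                 covariance = S, ridge = ridge, covariates = covariates,
                 caliper_sd = caliper_sd, sds = sds),
            class = "matched_sample")
}

## For each row of Zt, indices (into rows of Zc) of all controls tied for the
## minimum squared Euclidean distance, with a small relative tie tolerance.
## Chunked so the n_t x n_c distance matrix never exceeds ~2e6 entries.
nearest_controls <- function(Zt, Zc, chunk = max(1L, 2e6 %/% nrow(Zc))) {
  nt <- nrow(Zt)
  cc2 <- rowSums(Zc^2)
  ties <- vector("list", nt)
  d2min <- numeric(nt)
  for (start in seq(1L, nt, by = chunk)) {
    ii <- start:min(start + chunk - 1L, nt)
    D2 <- outer(rowSums(Zt[ii, , drop = FALSE]^2), cc2, `+`) -
      2 * Zt[ii, , drop = FALSE] %*% t(Zc)
    for (k in seq_along(ii)) {
      d2 <- D2[k, ]
      m <- min(d2)
      tol <- 1e-8 * (1 + abs(m))
      ties[[ii[k]]] <- which(d2 <= m + tol)
      d2min[ii[k]] <- m
    }
  }
  list(ties = ties, d2min = d2min)
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf(paste0("<matched_sample> %d treated, %d matched, ",
                     "%d excluded by caliper (%.3g SD)\n"),
              length(x$treated), sum(!x$excluded), sum(x$excluded),
              x$caliper_sd))
  invisible(x)
}

## summed match weight per unit row (nonzero only for used controls)
control_reuse_weights <- function(units, matches) {
  K <- numeric(nrow(units))
  Q <- numeric(nrow(units))
  for (i in seq_along(matches$treated)) {
    m <- matches$matches[[i]]
    w <- matches$weights[[i]]
    if (length(m)) {
      K[m] <- K[m] + w
      Q[m] <- Q[m] + w^2
    }
  }
  list(K = K, Q = Q)
}
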