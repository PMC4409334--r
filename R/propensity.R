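#' Fit the propensity model Pr(T = 1 | X)
#'
#' Diagnostic logistic regression of treatment (protection) on the matching
#' covariates, fit by iteratively reweighted least squares (Newton steps) to
#' convergence tolerance 1e-10 or 100 iterations. The matching itself is on
#' Mahalanobis distance; the propensity model supports the correlation
#' screen and overlap diagnostics. Under perfect separation the fit is
#' flagged and scores are clipped to `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @param units a `unit_table`.
#' @param covariates covariate columns (default: the table's attribute).
#' @return An object of class `propensity_model`: list with `coefficients`,
#'   `scores` (per unit, strictly inside (0,1)), `converged`, `separation`.
#' @export
fit_propensity <- function(units, covariates = NULL) {
  if (is.null(covariates)) covariates <- attr(units, "covariates")
  X <- unit_covariate_matrix(units, covariates)
  df <- data.frame(T = units$T, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(T ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  scores <- stats::fitted(fit)
  if (sep || any(scores <= 1e-8) || any(scores >= 1 - 1e-8)) {
    sep <- TRUE
    warning("possible separation in the propensity model; scores clipped",
            call. = FALSE)
  }
  scores <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  structure(list(coefficients = stats::coef(fit),
                 scores = unname(scores),
                 converged = fit$converged,
                 separation = sep,
                 vcov = stats::vcov(fit)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> logistic Pr(T=1|X)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Covariate correlation screen
#'
#' Pearson correlation matrix over the matching covariates, flagging pairs
#' whose absolute correlation reaches the collinearity threshold (default
#' 0.95, the screen applied before the matching analysis). Constant
#' covariates have undefined correlations: they are excluded from the matrix
#' with a named warning and listed in the result.
#'
#' @param units a `unit_table` (>= 3 units).
#' @param threshold absolute-correlation flag level (default 0.95).
#' @param covariates covariate columns (default: the table's attribute).
#' @return List with `correlation` (matrix), `flagged` (`data.frame` of
#'   pairs `var1`, `var2`, `r` with `|r| >= threshold`), `constant`
#'   (character vector of excluded constant covariates), `threshold`.
#' @export
correlation_screen <- function(units, threshold = 0.95, covariates = NULL) {
  if (is.null(covariates)) covariates <- attr(units, "covariates")
  stopifnot(nrow(units) >= 3)
  X <- unit_covariate_matrix(units, covariates)
  sds <- apply(X, 2, stats::sd)
  constant <- colnames(X)[sds == 0]
  if (length(constant))
    warning("constant covariate(s) excluded from correlation screen: ",
            paste(constant, collapse = ", "), call. = FALSE)
  X <- X[, sds > 0, drop = FALSE]
  cm <- stats::cor(X)
  ut <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(cm)[ut[, 1]],
                        var2 = colnames(cm)[ut[, 2]],
                        r = cm[ut])
  list(correlation = cm, flagged = flagged, constant = constant,
       threshold = threshold)
}
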