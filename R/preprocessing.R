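#' Yeo-Johnson power transformation
#'
#' The piecewise power transform defined on all reals, used to reduce
#' skewness before multivariate analysis:
#' for `x >= 0`, `((x + 1)^lambda - 1) / lambda` (`lambda != 0`) or
#' `log(x + 1)` (`lambda == 0`); for `x < 0`,
#' `-((-x + 1)^(2 - lambda) - 1) / (2 - lambda)` (`lambda != 2`) or
#' `-log(-x + 1)` (`lambda == 2`). Continuous and monotone in `x` for any
#' fixed `lambda`; `lambda = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param lambda Transformation parameter.
#' @return Transformed vector.
#' @seealso [yeo_johnson_inverse()], [fit_lambda()]
#' @references Yeo, I-K. & Johnson, R. A. (2000) A new family of power
#'   transformations to improve normality or symmetry. Biometrika 87, 954-959.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Inverse Yeo-Johnson transformation
#'
#' @param y Numeric vector on the transformed scale.
#' @inheritParams yeo_johnson
#' @return Vector on the original scale; `yeo_johnson_inverse(yeo_johnson(x,
#'   l), l)` recovers `x` to floating-point accuracy.
#' @export
yeo_johnson_inverse <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- !is.na(y) & y >= 0
  neg <- !is.na(y) & y < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- (y[pos] * lambda + 1)^(1 / lambda) - 1
  } else {
    out[pos] <- expm1(y[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- 1 - (1 - y[neg] * (2 - lambda))^(1 / (2 - lambda))
  } else {
    out[neg] <- -expm1(-y[neg])
  }
  out[is.na(y)] <- NA_real_
  out
}

# profile log-likelihood of lambda under the normal model on the transformed
# scale, with the Jacobian term (lambda - 1) * sum sgn(x) log(1 + |x|)
yj_loglik <- function(lambda, x) {
  n <- length(x)
  z <- yeo_johnson(x, lambda)
  s2 <- sum((z - mean(z))^2) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Maximum-likelihood lambda for the Yeo-Johnson transformation
#'
#' Profile log-likelihood maximisation over a bounded interval using golden
#' section search ([stats::optimize()]).
#'
#' @param x Numeric vector with at least 3 distinct values.
#' @param interval Search bounds for lambda (default `c(-5, 5)`).
#' @return The fitted lambda.
#' @export
fit_lambda <- function(x, interval = c(-5, 5)) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 3)
    stopf("need at least 3 distinct values to fit lambda")
  opt <- optimize(yj_loglik, interval = interval, x = x, maximum = TRUE,
                  tol = 1e-6)
  opt$maximum
}

#' Robust multivariate outlier flags
#'
#' Flags rows whose squared robust Mahalanobis distance — computed from a
#' minimum-covariance-determinant (MCD) location and scatter — exceeds the
#' chi-square quantile at probability `quantile` with `ncol` degrees of
#' freedom.
#'
#' @param table Data frame or matrix of numeric columns (rows = calls).
#' @param quantile Chi-square flagging quantile (default 0.975).
#' @param mcd_alpha Fraction of the data the MCD subset covers (default
#'   0.75, the usual robustness/efficiency compromise; 0.5 gives maximal
#'   breakdown but flags mixture tails aggressively).
#' @param seed Integer seed for the MCD subsampling (flags are reproducible
#'   given the seed).
#' @return Logical vector, `TRUE` for flagged rows.
#' @export
detect_outliers <- function(table, quantile = 0.975, mcd_alpha = 0.75,
                            seed = 1) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stopf("outlier screening needs numeric columns only")
  d <- ncol(X)
  if (nrow(X) <= 2 * d)
    stopf("need more than 2 x columns rows for a stable robust fit")
  quan <- max(floor(mcd_alpha * nrow(X)), floor((nrow(X) + d + 1) / 2))
  fit <- with_seed(seed, tryCatch(
    MASS::cov.rob(X, method = "mcd", quantile.used = quan),
    error = function(e) stopf(paste(
      "robust scatter estimation failed (%s);",
      "drop collinear columns before outlier screening"), conditionMessage(e))))
  d2 <- mahalanobis(X, fit$center, fit$cov)
  d2 > qchisq(quantile, df = d)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` is from the linear regression of
#' column `j` on all other columns. Perfectly collinear columns yield
#' `Inf` rather than an error.
#'
#' @param table Data frame or matrix with at least 2 numeric columns and
#'   more rows than columns.
#' @return Named numeric vector of VIFs (each `>= 1`).
#' @export
vif <- function(table) {
  X <- as.matrix(table)
  p <- ncol(X)
  if (p < 2) stopf("VIF needs at least 2 columns")
  if (nrow(X) <= p) stopf("VIF needs more rows than columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(pmax(out, 1), colnames(X))
}

#' Stepwise collinearity elimination by VIF
#'
#' While any variable has VIF above `threshold`: find the pair of remaining
#' variables with maximum absolute Pearson correlation and drop the member
#' with the larger VIF; ties are broken by column order. The trace records
#' each step.
#'
#' @inheritParams vif
#' @param threshold VIF threshold (default 2).
#' @return List with `retained` (column names), `trace` (data frame with one
#'   row per dropped variable: `dropped`, `vif`, `partner`, `correlation`).
#' @export
stepwise_vif_elimination <- function(table, threshold = 2) {
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  trace <- data.frame(dropped = character(0), vif = numeric(0),
                      partner = character(0), correlation = numeric(0))
  while (ncol(X) >= 2) {
    v <- vif(X)
    if (all(v <= threshold, na.rm = TRUE)) break
    C <- abs(cor(X))
    diag(C) <- 0
    idx <- which(C == max(C), arr.ind = TRUE)[1, ]
    pair <- sort(idx)
    # drop the pair member with larger VIF; column order breaks ties
    drop_j <- if (isTRUE(v[pair[2]] > v[pair[1]])) pair[2] else pair[1]
    keep_j <- setdiff(pair, drop_j)
    trace <- rbind(trace, data.frame(
      dropped = colnames(X)[drop_j], vif = unname(v[drop_j]),
      partner = colnames(X)[keep_j],
      correlation = unname(cor(X[, drop_j], X[, keep_j]))))
    X <- X[, -drop_j, drop = FALSE]
  }
  list(retained = colnames(X), trace = trace)
}

#' Preprocess a feature table for discriminant analysis
#'
#' Runs the fixed pipeline: per-variable Yeo-Johnson transformation (lambda
#' fitted by maximum likelihood on the full table), robust multivariate
#' outlier removal, and stepwise VIF elimination on the surviving rows.
#'
#' @param features Feature table data frame; acoustic parameter columns are
#'   auto-detected as the numeric columns other than `rank`.
#' @param columns Optional explicit character vector of parameter columns.
#' @param vif_threshold VIF threshold for elimination (default 2).
#' @param outlier_quantile Chi-square quantile for outlier flagging
#'   (default 0.975).
#' @param mcd_alpha MCD coverage fraction, see [detect_outliers()].
#' @param seed Seed for the robust scatter estimator.
#' @return List of class `preprocess_result`: `table` (transformed, cleaned,
#'   reduced feature table with label columns preserved), `report` (lambdas,
#'   outlier count, VIF trace, retained variables).
#' @export
preprocess_features <- function(features, columns = NULL, vif_threshold = 2,
                                outlier_quantile = 0.975, mcd_alpha = 0.75,
                                seed = 1) {
  labels <- intersect(c("caller", "sex", "rank", "bout_id"), names(features))
  if (is.null(columns)) {
    numeric_cols <- names(features)[vapply(features, is.numeric, logical(1))]
    columns <- setdiff(numeric_cols, c("rank"))
  }
  if (!all(columns %in% names(features)))
    stopf("missing feature column(s): %s",
          paste(setdiff(columns, names(features)), collapse = ", "))
  X <- features[, columns, drop = FALSE]
  if (any(!complete.cases(X))) stopf("feature table has missing values")
  lambdas <- vapply(columns, function(cn) fit_lambda(X[[cn]]), numeric(1))
  for (cn in columns) X[[cn]] <- yeo_johnson(X[[cn]], lambdas[[cn]])
  flags <- detect_outliers(X, quantile = outlier_quantile,
                           mcd_alpha = mcd_alpha, seed = seed)
  Xc <- X[!flags, , drop = FALSE]
  elim <- stepwise_vif_elimination(Xc, threshold = vif_threshold)
  out <- cbind(features[!flags, labels, drop = FALSE],
               Xc[, elim$retained, drop = FALSE])
  rownames(out) <- NULL
  structure(list(
    table = out,
    report = list(lambda_per_variable = lambdas,
                  n_outliers_removed = sum(flags),
                  outlier_flags = flags,
                  vif_elimination_trace = elim$trace,
                  retained_variables = elim$retained)),
    class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("Preprocessing: %d outliers removed, %d variable(s) dropped\n",
              r$n_outliers_removed, nrow(r$vif_elimination_trace)))
  cat("  retained:", paste(r$retained_variables, collapse = ", "), "\n")
  invisible(x)
}
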