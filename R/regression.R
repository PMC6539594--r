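#' Ordinary least squares with classical standard errors
#'
#' Fits `y = b0 + X b + e` by OLS (via [stats::lm()]), reporting
#' coefficients, classical standard errors
#' `SE(b_j) = sqrt(sigma2 * [(X'X)^-1]_jj)` with
#' `sigma2 = RSS / (n - p - 1)`, R-squared and adjusted R-squared. This is
#' the model class behind both structure-activity models: the
#' single-variable distance correlation and the three-variable equation with
#' the normalised distance and the two binary indicators.
#'
#' @param X Data frame or matrix of predictor columns (no intercept column).
#' @param y Numeric response (percent inhibition at 10 uM).
#' @return Object of class `sar_ols` with elements `coefficients`, `se`,
#'   `sigma`, `r.squared`, `adj.r.squared`, `n`, `p`, `residuals`, `fitted`,
#'   `xnames` and the underlying `lm` fit.
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) stop("X has no columns", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("X and y sizes differ", call. = FALSE)
  if (n <= p + 1) {
    stop("fit refused: need n > p + 1 (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("collinear predictors: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  structure(list(
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    sigma = sm$sigma,
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    n = n, p = p,
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    xnames = colnames(X),
    lm = fit), class = "sar_ols")
}

#' @export
print.sar_ols <- function(x, digits_coef = 1, digits_r2 = 2, ...) {
  cat("OLS fit, n =", x$n, "\n")
  tab <- data.frame(coef = round(x$coefficients, digits_coef),
                    se = round(x$se, digits_coef))
  print(tab)
  cat(sprintf("R^2 = %.*f, adjusted R^2 = %.*f\n",
              digits_r2, x$r.squared, digits_r2, x$adj.r.squared))
  invisible(x)
}

#' Predict from a fitted structure-activity model
#'
#' @param object A `sar_ols` fit.
#' @param newdata Data frame containing every predictor column of the fit.
#' @param ... Unused.
#' @return Numeric vector of predicted inhibition values.
#' @export
predict.sar_ols <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$xnames, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  b <- object$coefficients
  drop(as.matrix(newdata[, object$xnames, drop = FALSE]) %*%
         b[object$xnames] + b["(Intercept)"])
}

#' Exhaustive best-subset model search
#'
#' Fits every predictor subset of size 1 to `k_max` and ranks the fits by
#' adjusted R-squared (raw R-squared is reported alongside, so the
#' fit-versus-size tradeoff stays visible). Subsets whose fit fails (e.g.
#' collinear columns) are skipped with a warning.
#'
#' @param X Data frame of candidate predictors.
#' @param y Numeric response.
#' @param k_max Largest subset size to consider.
#' @return Object of class `sar_subsets`: a data frame (`rank`, `size`,
#'   `variables`, `r.squared`, `adj.r.squared`) with the fitted models in
#'   attribute `fits` (keyed by the `variables` string).
#' @export
best_subset <- function(X, y, k_max = ncol(X)) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) stop("X has no columns", call. = FALSE)
  if (k_max < 1 || k_max > ncol(X)) {
    stop("k_max must be between 1 and ncol(X)", call. = FALSE)
  }
  rows <- list()
  fits <- list()
  for (k in seq_len(k_max)) {
    for (idx in utils::combn(ncol(X), k, simplify = FALSE)) {
      vars <- names(X)[idx]
      key <- paste(vars, collapse = "+")
      fit <- tryCatch(ols_fit(X[, idx, drop = FALSE], y), error = function(e) {
        warning("skipping subset {", key, "}: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, variables = key, r.squared = fit$r.squared,
        adj.r.squared = fit$adj.r.squared, stringsAsFactors = FALSE)
      fits[[key]] <- fit
    }
  }
  if (length(rows) == 0) stop("no subset could be fitted", call. = FALSE)
  out <- do.call(rbind, rows)
  ord <- order(-out$adj.r.squared, out$size, out$variables)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, fits = fits, class = c("sar_subsets", "data.frame"))
}
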