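# Ordinary least squares with the diagnostic report used throughout the
# package: per-coefficient estimate / std. error / t statistic / two-sided
# p-value, R-squared, adjusted R-squared and residual RMSE.
#
# The solve goes through QR (base lm.fit): the TPM design basis
# {ln q, (ln q)^2, q*d} is strongly correlated and the normal equations
# square its condition number.

#' Ordinary least squares fit with diagnostics
#'
#' Minimises the residual sum of squares of `y` on the columns of `X` via QR
#' factorisation.  Standard errors use the residual variance with `n - p`
#' denominator and the diagonal of `(X'X)^-1`; p-values are two-sided from
#' the t distribution on `n - p` degrees of freedom; RMSE is
#' `sqrt(SSR / (n - p))` on the scale of `y`.  An exact (zero-residual) fit
#' reports standard errors of 0 with infinite t statistics.
#'
#' @param X Numeric design matrix, full column rank, more rows than columns.
#' @param y Numeric response vector.
#' @return A list with `coefficients` (named vector) and `report`, a
#'   `fit_report` object: a coefficient table plus `r_squared`,
#'   `adj_r_squared`, `rmse`, `n_obs`, `n_params`.
#' @export
#' @examples
#' X <- cbind(1, 1:5)
#' ols_fit(X, c(1.1, 1.9, 3.2, 3.8, 5.1))$coefficients
ols_fit <- function(X, y) {
  X <- as.matrix(X); y <- as.double(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_data("length(y) != nrow(X)")
  if (n <= p) stop_data("need more observations (", n, ") than parameters (", p, ")")
  if (anyNA(X) || anyNA(y)) stop_data("NA in design or response")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  fit <- lm.fit(X, y)
  if (fit$rank < p) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop_data("design matrix is rank deficient; collinear column(s): ",
              paste(dropped, collapse = ", "),
              class = c("puffyield_singular_error", "puffyield_data_error"))
  }
  beta <- fit$coefficients
  res <- fit$residuals
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df <- n - p
  sigma2 <- ssr / df
  # (X'X)^-1 from the R factor of the QR decomposition
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  xtx_inv <- chol2inv(R)
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))

  exact <- ssr <= 1e-24 * max(1, sum(y^2))
  if (exact) se[] <- 0
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- ifelse(is.finite(tval), 2 * pt(-abs(tval), df), 0)

  r2 <- if (sst > 0) 1 - ssr / sst else 1
  report <- structure(list(
    coefficients = cbind(Estimate = beta, `Std. Error` = se,
                         tStat = tval, pValue = pval),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p),
    rmse = sqrt(sigma2),
    n_obs = n, n_params = p,
    residuals = res, fitted = drop(X %*% beta), exact_fit = exact),
    class = "fit_report")
  list(coefficients = beta, report = report)
}

#' @export
print.fit_report <- function(x, digits = 6, ...) {
  cat(sprintf("OLS fit: %d observations, %d parameters\n", x$n_obs, x$n_params))
  printCoefmat(format_coef_table(x$coefficients, digits), digits = digits,
               P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("R-squared %.4f, adjusted %.4f, RMSE %.6g\n",
              x$r_squared, x$adj_r_squared, x$rmse))
  if (!is.null(x$rmse_natural))
    cat(sprintf("RMSE on the natural (back-transformed) scale %.6g\n",
                x$rmse_natural))
  invisible(x)
}

format_coef_table <- function(tab, digits) {
  tab[!is.finite(tab[, "tStat"]), "tStat"] <- NA  # exact fit: t undefined
  tab
}
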