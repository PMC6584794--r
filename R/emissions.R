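# Empirical emissions models.
#
# TPM concentration model: a log-quadratic surface in puff flow rate q
# [mL/s] and puff duration d [s],
#
#   ln(C_TPM) = b1 + b2 ln(q) + b3 d + b4 (ln q)^2 + b5 ln(d/1000) + b6 q*d
#
# with C_TPM in mg of particulate per mL of aerosol drawn.  The ln(d/1000)
# term is kept literally (d in seconds divided by 1000): mathematically it
# only re-intercepts ln(d), but the published coefficient convention is
# bound to this form, so b1 is only comparable across fits that share it.
#
# Nicotine mass-ratio model: f_NIC = beta1 + beta2 q, the ratio of nicotine
# mass to TPM mass [mg/mg], fitted on trials with a nicotine measurement.

tpm_coef_names <- c("b1", "b2", "b3", "b4", "b5", "b6")
nic_coef_names <- c("beta1", "beta2")

#' Design row of the TPM concentration model
#'
#' Regressors for one puff condition, in fixed column order:
#' `[1, ln q, d, (ln q)^2, ln(d/1000), q*d]` with natural logarithms.
#'
#' @param q Puff flow rate, mL/s (> 0). Vectorised.
#' @param d Puff duration, s (> 0). Vectorised, recycled against `q`.
#' @return A numeric matrix with one row per (q, d) pair and 6 columns
#'   named `b1`..`b6`.
#' @export
#' @examples
#' tpm_design_row(exp(1), 1000)
tpm_design_row <- function(q, d) {
  if (!is.numeric(q) || !is.numeric(d) || anyNA(q) || anyNA(d) ||
      any(!is.finite(q)) || any(!is.finite(d)))
    stop_domain("q and d must be finite numerics")
  if (any(q <= 0)) stop_domain("q must be > 0 (got ", min(q), ")")
  if (any(d <= 0)) stop_domain("d must be > 0 (got ", min(d), ")")
  n <- max(length(q), length(d))
  q <- rep_len(as.double(q), n); d <- rep_len(as.double(d), n)
  X <- cbind(1, log(q), d, log(q)^2, log(d / 1000), q * d)
  colnames(X) <- tpm_coef_names
  X
}

#' TPM concentration model from coefficients
#'
#' @param b Numeric vector of 6 coefficients (intercept, ln q, d, (ln q)^2,
#'   ln(d/1000), q*d), all finite.
#' @param envelope Optional list with `q` and `d` ranges of the fitted
#'   design; predictions outside it are flagged as extrapolations.
#' @return A `tpm_model` object.
#' @export
tpm_model <- function(b, envelope = NULL) {
  b <- as.double(b)
  if (length(b) != 6L || anyNA(b) || any(!is.finite(b)))
    stop_data("b must be 6 finite coefficients")
  names(b) <- tpm_coef_names
  structure(list(b = b, envelope = envelope), class = "tpm_model")
}

#' Nicotine mass-ratio model from coefficients
#'
#' @param beta Numeric vector `(beta1, beta2)`: intercept \[mg/mg\] and flow
#'   slope \[mg/mg per mL/s\].
#' @param envelope Optional list with the `q` range of the fitted design.
#' @return A `nic_model` object.
#' @export
nic_model <- function(beta, envelope = NULL) {
  beta <- as.double(beta)
  if (length(beta) != 2L || anyNA(beta) || any(!is.finite(beta)))
    stop_data("beta must be 2 finite coefficients")
  names(beta) <- nic_coef_names
  structure(list(beta = beta, envelope = envelope), class = "nic_model")
}

#' @export
coef.tpm_model <- function(object, ...) object$b

#' @export
coef.nic_model <- function(object, ...) object$beta

#' Predict TPM concentration
#'
#' Evaluates the fitted log-quadratic surface and exponentiates:
#' `C_TPM = exp(b . x(q, d))`, mg/mL, strictly positive.
#'
#' @param object A `tpm_model`.
#' @param newdata Data frame with columns `q` (mL/s) and `d` (s); or pass
#'   `q` and `d` directly.
#' @param q,d Alternative to `newdata`.
#' @param ... Unused.
#' @return Numeric vector of concentrations, mg/mL, with attribute
#'   `extrapolated` (logical) when the model carries a design envelope.
#' @export
#' @examples
#' m <- reference_model()$tpm
#' predict(m, data.frame(q = 30.4, d = 2.3))
predict.tpm_model <- function(object, newdata = NULL, q = NULL, d = NULL, ...) {
  if (!is.null(newdata)) { q <- newdata$q; d <- newdata$d }
  if (is.null(q) || is.null(d)) stop_data("supply newdata or q and d")
  X <- tpm_design_row(q, d)
  out <- exp(drop(X %*% object$b))
  if (!is.null(object$envelope)) {
    env <- object$envelope
    attr(out, "extrapolated") <-
      q < env$q[1] | q > env$q[2] | d < env$d[1] | d > env$d[2]
  }
  out
}

#' Predict nicotine mass ratio
#'
#' `f_NIC = beta1 + beta2 * q`, mg nicotine per mg TPM.  A warning is
#' issued if any prediction falls outside (0, 1); values are returned
#' unclipped.
#'
#' @param object A `nic_model`.
#' @param newdata Data frame with column `q`, or pass `q` directly.
#' @param q Puff flow rate(s), mL/s (>= 0).
#' @param ... Unused.
#' @return Numeric vector of mass ratios, mg/mg.
#' @export
predict.nic_model <- function(object, newdata = NULL, q = NULL, ...) {
  if (!is.null(newdata)) q <- newdata$q
  if (is.null(q)) stop_data("supply newdata or q")
  if (!is.numeric(q) || anyNA(q) || any(!is.finite(q)) || any(q < 0))
    stop_domain("q must be finite and >= 0")
  out <- object$beta[[1L]] + object$beta[[2L]] * as.double(q)
  if (any(out <= 0 | out >= 1))
    warning("predicted nicotine mass ratio outside (0, 1)")
  out
}

#' @export
print.tpm_model <- function(x, ...) {
  cat("TPM concentration model: ln(C_TPM) = b . [1, ln q, d, (ln q)^2, ln(d/1000), q d]\n")
  print(signif(x$b, 7))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' @export
print.nic_model <- function(x, ...) {
  cat("Nicotine mass-ratio model: f_NIC = beta1 + beta2 q\n")
  print(signif(x$beta, 7))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' @export
summary.tpm_model <- function(object, ...) {
  print(object)
  invisible(object$fit)
}

#' @export
summary.nic_model <- function(object, ...) {
  print(object)
  invisible(object$fit)
}

#' @export
residuals.tpm_model <- function(object, ...) {
  if (is.null(object$fit)) stop_data("model was not fitted to data")
  object$fit$residuals   # ln-scale residuals
}

#' @export
residuals.nic_model <- function(object, ...) {
  if (is.null(object$fit)) stop_data("model was not fitted to data")
  object$fit$residuals
}

#' @export
plot.tpm_model <- function(x, ...) {
  if (is.null(x$fit)) stop_data("model was not fitted to data")
  plot(x$fit$fitted, x$fit$fitted + x$fit$residuals,
       xlab = "fitted ln(C_TPM)", ylab = "observed ln(C_TPM)",
       main = "TPM concentration model", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

trial_columns <- c("condition_id", "q_ml_s", "d_s", "n_puffs",
                   "total_volume_ml", "tpm_mass_mg", "nicotine_mass_mg")

validate_trials <- function(trials) {
  trials <- as.data.frame(trials)
  need <- setdiff(trial_columns, "nicotine_mass_mg")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_data("trial table missing column(s): ", paste(miss, collapse = ", "))
  if (!"nicotine_mass_mg" %in% names(trials)) trials$nicotine_mass_mg <- NA_real_
  for (cc in c("q_ml_s", "d_s", "total_volume_ml"))
    if (any(!is.finite(trials[[cc]]) | trials[[cc]] <= 0))
      stop_data("column ", cc, " must be positive and finite")
  trials
}

#' Read / write an emissions-trial table
#'
#' CSV dialect: header
#' `condition_id,q_ml_s,d_s,n_puffs,total_volume_ml,tpm_mass_mg,nicotine_mass_mg`;
#' the nicotine column may be empty for trials whose pad was not assayed.
#'
#' @param path CSV path.
#' @return Data frame of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  validate_trials(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trials
#' @param trials Trial table to write.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  write.csv(trials[trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Fit the TPM concentration model to emissions trials
#'
#' Each trial's measured concentration `C_TPM = tpm_mass / total_volume`
#' \[mg/mL\] is log-transformed and regressed on the design row of its
#' observed (q, d) by OLS.  The fit report carries the RMSE on the ln
#' regression scale, and additionally a back-transformed residual RMSE on
#' the mg/mL scale (`rmse_natural`), because concentrations — not their
#' logs — are the physically meaningful quantity.
#'
#' @param trials Trial table (see [read_trials()]): at least 7 trials, all
#'   with positive TPM mass.
#' @return A `tpm_fit` object (inherits `tpm_model`): coefficients `b`,
#'   design `envelope`, fit report in `$fit`, training data in `$data`.
#' @export
fit_tpm_model <- function(trials) {
  trials <- validate_trials(trials)
  if (nrow(trials) < 7L)
    stop_data("need at least 7 trials to fit 6 coefficients, got ", nrow(trials))
  ctpm <- trials$tpm_mass_mg / trials$total_volume_ml
  bad <- which(!is.finite(ctpm) | ctpm <= 0)
  if (length(bad))
    stop_data("non-positive TPM concentration in trial(s): ",
              paste(head(trials$condition_id[bad], 5L), collapse = ", "))
  X <- tpm_design_row(trials$q_ml_s, trials$d_s)
  y <- log(ctpm)
  fit <- ols_fit(X, y)
  rep <- fit$report
  chat <- exp(rep$fitted)
  rep$rmse_natural <- sqrt(sum((ctpm - chat)^2) / (rep$n_obs - rep$n_params))
  m <- tpm_model(fit$coefficients,
                 envelope = list(q = range(trials$q_ml_s),
                                 d = range(trials$d_s)))
  m$fit <- rep
  m$data <- trials
  class(m) <- c("tpm_fit", class(m))
  m
}

#' Fit the nicotine mass-ratio model
#'
#' Regresses the measured mass ratio `f_NIC = nicotine_mass / tpm_mass` on
#' `[1, q]` by OLS, using the trials that carry a nicotine measurement
#' (typically the screening arm of the design).
#'
#' @param trials Trial table; at least 3 rows must have `nicotine_mass_mg`.
#' @return A `nic_fit` object (inherits `nic_model`).
#' @export
fit_nic_model <- function(trials) {
  trials <- validate_trials(trials)
  keep <- is.finite(trials$nicotine_mass_mg)
  trials <- trials[keep, , drop = FALSE]
  if (nrow(trials) < 3L)
    stop_data("need at least 3 trials with nicotine mass, got ", nrow(trials))
  f <- trials$nicotine_mass_mg / trials$tpm_mass_mg
  bad <- which(!is.finite(f) | f <= 0 | f >= 1)
  if (length(bad))
    stop_data("nicotine mass ratio outside (0, 1) in trial(s): ",
              paste(head(trials$condition_id[bad], 5L), collapse = ", "))
  X <- cbind(1, trials$q_ml_s)
  colnames(X) <- nic_coef_names
  fit <- ols_fit(X, f)
  m <- nic_model(fit$coefficients,
                 envelope = list(q = range(trials$q_ml_s)))
  m$fit <- fit$report
  m$data <- trials
  class(m) <- c("nic_fit", class(m))
  m
}

#' Read / write a model pair as JSON
#'
#' Format: `{"tpm": {"b": [6]}, "nic": {"beta": [2]}, "meta": {...}}`.
#'
#' @param path JSON path.
#' @return A list with elements `tpm` ([tpm_model()]), `nic`
#'   ([nic_model()]) and `meta`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$tpm$b) || is.null(j$nic$beta))
    stop_data(path, ": not a model file (need tpm$b and nic$beta)")
  env <- j$meta$envelope
  envt <- if (!is.null(env)) list(q = as.double(env$q), d = as.double(env$d))
  envn <- if (!is.null(env)) list(q = as.double(env$q))
  list(tpm = tpm_model(as.double(j$tpm$b), envelope = envt),
       nic = nic_model(as.double(j$nic$beta), envelope = envn),
       meta = j$meta)
}

#' @rdname read_model
#' @param tpm,nic Models to write.
#' @param meta Optional metadata list.
#' @export
write_model <- function(tpm, nic, path, meta = list()) {
  stopifnot(inherits(tpm, "tpm_model"), inherits(nic, "nic_model"))
  obj <- list(tpm = list(b = unname(tpm$b)),
              nic = list(beta = unname(nic$beta)),
              meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
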