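# Agreement between predicted and observed yields across repeated playback
# trials: slope m, Pearson's r, and R-squared.

#' Agreement statistics for predicted vs observed yields
#'
#' The headline slope `m` is the least-squares slope through the origin,
#' `m = sum(pred * obs) / sum(pred^2)`: agreement is judged against the
#' ideal 1:1 line, and a through-origin slope of 1 means predictions match
#' observations with no multiplicative bias.  The OLS slope and intercept
#' of the line with intercept are reported alongside, as is `r_squared`
#' (the squared Pearson correlation, i.e. the R-squared of the OLS line
#' with intercept) and `r_squared_identity`, the coefficient of
#' determination about the 1:1 line itself (which can be negative when
#' predictions are biased).
#'
#' @param predicted,observed Paired yield values, mg, at least 3 pairs,
#'   finite and non-negative.
#' @return An `agreement_report`: list with `slope_through_origin`,
#'   `slope_ols`, `intercept_ols`, `pearson_r`, `r_squared`,
#'   `r_squared_identity`, `n_pairs`.
#' @export
#' @examples
#' compare_yields(1:5, (1:5) * 2)
compare_yields <- function(predicted, observed) {
  predicted <- as.double(predicted); observed <- as.double(observed)
  if (length(predicted) != length(observed))
    stop_data("predicted and observed must be paired")
  n <- length(predicted)
  if (n < 3L) stop_data("need at least 3 pairs, got ", n)
  if (anyNA(predicted) || anyNA(observed) ||
      any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop_data("non-finite yield values")
  if (any(predicted < 0) || any(observed < 0))
    stop_data("yields must be non-negative")
  if (var(predicted) == 0)
    stop_data("degenerate comparison: all predicted values are equal")

  m0 <- sum(predicted * observed) / sum(predicted^2)
  b <- cov(observed, predicted) / var(predicted)
  a <- mean(observed) - b * mean(predicted)
  r <- if (var(observed) == 0) NA_real_ else cor(predicted, observed)
  sst <- sum((observed - mean(observed))^2)
  r2id <- if (sst > 0) 1 - sum((observed - predicted)^2) / sst else 1
  structure(list(slope_through_origin = m0, slope_ols = b, intercept_ols = a,
                 pearson_r = r,
                 r_squared = if (is.na(r)) NA_real_ else r^2,
                 r_squared_identity = r2id,
                 n_pairs = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Agreement over %d pairs: m = %.3f (through origin), r = %.3f, R^2 = %.3f\n",
    x$n_pairs, x$slope_through_origin, x$pearson_r, x$r_squared))
  cat(sprintf("  OLS line: slope %.3f, intercept %.4g; R^2 about 1:1 line %.3f\n",
              x$slope_ols, x$intercept_ols, x$r_squared_identity))
  invisible(x)
}

#' Read / write an observed-yield table
#'
#' CSV dialect: header `session_id,replicate,y_tpm_mg,y_nic_mg` — one row
#' per playback replicate of each session; `y_nic_mg` may be empty.
#'
#' @param path CSV path.
#' @return Data frame of observed yields.
#' @export
read_observed_yields <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "replicate", "y_tpm_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("observed-yield table missing column(s): ",
              paste(miss, collapse = ", "))
  if (!"y_nic_mg" %in% names(df)) df$y_nic_mg <- NA_real_
  df
}

#' @rdname read_observed_yields
#' @param observed Table to write.
#' @export
write_observed_yields <- function(observed, path) {
  write.csv(observed[c("session_id", "replicate", "y_tpm_mg", "y_nic_mg")],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate fitted models against repeated playback observations
#'
#' Computes the model-predicted yield once per session (the prediction is
#' deterministic), pairs it against every observed replicate of that
#' session, and reports agreement statistics for TPM and — when nicotine
#' observations are present — for nicotine.
#'
#' @param sessions List of [puff_session()] objects.
#' @param tpm,nic Fitted or reference models.
#' @param observed Observed-yield table (see [read_observed_yields()]); one
#'   row per (session, replicate).
#' @return A `validation_report`: list with `tpm` and `nic`
#'   [compare_yields()] reports (`nic` is `NULL` without nicotine data),
#'   `pairs` (the paired table) and `per_session` (one prediction row per
#'   session).
#' @export
run_validation <- function(sessions, tpm, nic = NULL, observed) {
  if (inherits(sessions, "puff_session")) sessions <- list(sessions)
  ids <- vapply(sessions, function(s) s$session_id, character(1L))
  if (anyDuplicated(ids)) stop_data("duplicate session ids")
  missing_obs <- setdiff(ids, observed$session_id)
  missing_ses <- setdiff(observed$session_id, ids)
  if (length(missing_obs) || length(missing_ses))
    stop_data("session/observation pairing gaps: ",
              paste(c(if (length(missing_obs))
                        paste("no observations for", paste(missing_obs, collapse = ", ")),
                      if (length(missing_ses))
                        paste("no session for", paste(missing_ses, collapse = ", "))),
                    collapse = "; "))

  pred <- lapply(sessions, predict_session_yield, tpm = tpm, nic = nic,
                 per_puff = FALSE)
  per_session <- data.frame(
    session_id = ids,
    yhat_tpm_mg = vapply(pred, `[[`, double(1L), "y_tpm"),
    yhat_nic_mg = vapply(pred, `[[`, double(1L), "y_nic"))

  pairs <- merge(observed, per_session, by = "session_id", sort = TRUE)
  tpm_rep <- compare_yields(pairs$yhat_tpm_mg, pairs$y_tpm_mg)
  nic_rep <- NULL
  if (!is.null(nic) && any(is.finite(pairs$y_nic_mg))) {
    keep <- is.finite(pairs$y_nic_mg) & is.finite(pairs$yhat_nic_mg)
    nic_rep <- compare_yields(pairs$yhat_nic_mg[keep], pairs$y_nic_mg[keep])
  }
  structure(list(tpm = tpm_rep, nic = nic_rep, pairs = pairs,
                 per_session = per_session),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("TPM yield ")
  print(x$tpm)
  if (!is.null(x$nic)) { cat("Nicotine yield "); print(x$nic) }
  invisible(x)
}
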