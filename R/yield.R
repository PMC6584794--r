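# Per-session yield prediction.
#
# The continuous-time yield of an aerosol constituent is the integral of
# (mass ratio) x (TPM concentration) x (flow rate) over the session.  With
# the emissions models expressed per puff, the integral discretises to a
# sum over detected puffs: each puff contributes C_TPM(q_n, d_n) * v_n mg
# of particulate, and f_NIC(q_n) times that of nicotine, where the puff's
# within-flow variation is collapsed to its volume-weighted mean flow
# q_n = v_n / d_n before model evaluation.

#' Predict TPM and nicotine yield for a session
#'
#' Sums per-puff contributions: `y_tpm = sum C(q_n, d_n) v_n`,
#' `y_nic = sum f(q_n) C(q_n, d_n) v_n` (mg).
#'
#' @param session A [puff_session()].
#' @param tpm A [tpm_model()].
#' @param nic A [nic_model()], or `NULL` to predict TPM only.
#' @param per_puff Keep the per-puff breakdown? Default `TRUE`.
#' @return A `session_yield`: list with `y_tpm` (mg), `y_nic` (mg or `NA`),
#'   `session_id`, and (when requested) `per_puff`, a data frame with one
#'   row per puff: predicted concentration `c_tpm` (mg/mL), mass ratio
#'   `f_nic`, contributions `tpm_mg` / `nic_mg`, and an `extrapolated` flag
#'   for puffs whose (q, d) fall outside the model's fitted design envelope.
#' @export
#' @examples
#' ref <- reference_model()
#' s <- puff_session(data.frame(start = 0, duration = 2, volume = 60,
#'                              mean_flow = 30))
#' predict_session_yield(s, ref$tpm, ref$nic)
predict_session_yield <- function(session, tpm, nic = NULL, per_puff = TRUE) {
  stopifnot(inherits(session, "puff_session"), inherits(tpm, "tpm_model"))
  p <- session$puffs
  bad <- which(p$mean_flow <= 0 | p$duration <= 0)
  if (length(bad))
    stop_domain("puff ", bad[1L], " of session ", session$session_id,
                " has non-positive flow or duration")
  ct <- predict(tpm, q = p$mean_flow, d = p$duration)
  extrap <- attr(ct, "extrapolated") %||% rep(FALSE, nrow(p))
  ct <- as.double(ct)
  tpm_mg <- ct * p$volume
  if (!is.null(nic)) {
    stopifnot(inherits(nic, "nic_model"))
    f <- predict(nic, q = p$mean_flow)
    nic_mg <- f * tpm_mg
  } else {
    f <- rep(NA_real_, nrow(p)); nic_mg <- rep(NA_real_, nrow(p))
  }
  out <- list(y_tpm = sum(tpm_mg),
              y_nic = if (is.null(nic)) NA_real_ else sum(nic_mg),
              session_id = session$session_id)
  if (per_puff)
    out$per_puff <- data.frame(puff = seq_len(nrow(p)),
                               q = p$mean_flow, d = p$duration, v = p$volume,
                               c_tpm = ct, f_nic = f,
                               tpm_mg = tpm_mg, nic_mg = nic_mg,
                               extrapolated = extrap)
  structure(out, class = "session_yield")
}

#' @export
print.session_yield <- function(x, ...) {
  cat(sprintf("Session '%s': predicted TPM yield %.3f mg", x$session_id, x$y_tpm))
  if (is.finite(x$y_nic)) cat(sprintf(", nicotine yield %.4f mg", x$y_nic))
  cat("\n")
  if (!is.null(x$per_puff) && any(x$per_puff$extrapolated))
    cat(sprintf("  note: %d of %d puffs outside the fitted design envelope\n",
                sum(x$per_puff$extrapolated), nrow(x$per_puff)))
  invisible(x)
}

#' Yield directly from a flow trace
#'
#' Realises the continuous-time yield integral on a raw topography trace:
#' detects puffs, then evaluates the per-puff sum with the concentration
#' and mass ratio held constant within each puff at its (q, d).
#'
#' @param trace A [flow_trace()].
#' @inheritParams predict_session_yield
#' @param threshold,min_duration,min_gap Puff-detection settings, see
#'   [detect_puffs()].
#' @param session_id Label for the returned yield.
#' @return A `session_yield`; zero yields for a trace with no puffs.
#' @export
integrate_yield_trace <- function(trace, tpm, nic = NULL, threshold = 1.0,
                                  min_duration = 0.1, min_gap = 0.3,
                                  per_puff = TRUE, session_id = "trace") {
  puffs <- detect_puffs(trace, threshold, min_duration, min_gap)
  if (nrow(puffs) == 0L)
    return(structure(list(y_tpm = 0, y_nic = if (is.null(nic)) NA_real_ else 0,
                          session_id = session_id, per_puff = NULL),
                     class = "session_yield"))
  predict_session_yield(puff_session(puffs, session_id), tpm, nic,
                        per_puff = per_puff)
}
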