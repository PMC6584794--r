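# Independent oracles and small fixture builders used across the suite.

# Brute-force normal-equations OLS solve: the independent reference for the
# package's QR-based fit.  Deliberately naive.
ne_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(beta = drop(beta), se = se)
}

# Rectangular-pulse trace: flow = q on [t0, t0 + d], else 0, sampled at `hz`.
rect_trace <- function(pulses, hz = 100, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(pulses$t0 + pulses$d) + 1
  tg <- seq(0, t_end, by = 1 / hz)
  flow <- numeric(length(tg))
  for (i in seq_len(nrow(pulses))) {
    k <- tg >= pulses$t0[i] & tg <= pulses$t0[i] + pulses$d[i]
    flow[k] <- pulses$q[i]
  }
  flow_trace(tg, flow)
}

# Minimal valid emissions-trial table from explicit vectors.
make_trials <- function(q, d, c_tpm, f_nic = NA_real_, n_puffs = 10) {
  vol <- n_puffs * q * d
  f_nic <- rep_len(f_nic, length(q))
  data.frame(condition_id = sprintf("T%02d", seq_along(q)),
             q_ml_s = q, d_s = d, n_puffs = n_puffs,
             total_volume_ml = vol,
             tpm_mass_mg = c_tpm * vol,
             nicotine_mass_mg = f_nic * c_tpm * vol)
}

# Session with explicitly constructed puffs.
make_session <- function(d, q, start = NULL, id = "s1") {
  if (is.null(start)) start <- cumsum(c(0, head(d, -1) + 5))
  puff_session(data.frame(start = start, duration = d, volume = q * d,
                          mean_flow = q), session_id = id)
}
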