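# Synthetic data generation.
#
# Everything the pipeline consumes can be generated here: the machine-
# puffing design grid (a screening arm at nominally constant puff volume
# plus a full flow-rate x duration grid), emissions trials drawn from known
# TPM / nicotine models, heterogeneous topography sessions rendered as
# flow-rate traces, and observed playback yields.  Defaults reproduce the
# study geometry the models were developed under: 34 flow conditions
# (10 screening + 24 full) x 6 replicate trials = 204 trials, mean session
# volume ~740 mL with every trial in [522, 1000] mL, and 7 playback
# sessions x 6 replicates = 42 validation pairs.

#' Design specification for emissions trials
#'
#' @param n_conditions Total flow conditions (default 34).
#' @param reps_per_condition Replicate trials per condition (default 6).
#' @param q_range Puff flow-rate range, mL/s (default 10–100, spanning
#'   natural-environment puffing).
#' @param d_range Puff duration range, s (default 1–5).
#' @param target_session_volume Per-trial cumulative aerosol volume target,
#'   mL (default 740).
#' @param session_volume_range Admissible per-trial volume window, mL
#'   (default 522–1000).
#' @param screening_fraction Fraction of conditions in the screening arm,
#'   where q and d vary inversely at nominally constant puff volume
#'   (default 10/34).
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_conditions = 34L, reps_per_condition = 6L,
                        q_range = c(10, 100), d_range = c(1, 5),
                        target_session_volume = 740,
                        session_volume_range = c(522, 1000),
                        screening_fraction = 10 / 34) {
  stopifnot(n_conditions >= 2, reps_per_condition >= 1,
            all(q_range > 0), all(d_range > 0),
            q_range[2] > q_range[1], d_range[2] > d_range[1],
            target_session_volume > 0,
            session_volume_range[1] < session_volume_range[2],
            screening_fraction >= 0, screening_fraction < 1)
  structure(list(n_conditions = as.integer(n_conditions),
                 reps_per_condition = as.integer(reps_per_condition),
                 q_range = as.double(q_range), d_range = as.double(d_range),
                 target_session_volume = as.double(target_session_volume),
                 session_volume_range = as.double(session_volume_range),
                 screening_fraction = screening_fraction),
            class = "design_spec")
}

# closest-to-square factor pair (nq >= nd) for the full grid
grid_dims <- function(n) {
  nd <- max(which(seq_len(floor(sqrt(n))) %in%
                    seq_len(n)[n %% seq_len(n) == 0]))
  c(nq = n %/% nd, nd = nd)
}

#' Generate the emissions-trial design
#'
#' Screening conditions hold puff volume q*d nominally constant while q and
#' d vary inversely across the duration range; full conditions tile the
#' q x d range on a log-spaced grid.  The per-condition puff count is
#' chosen so the cumulative trial volume `n_puffs * q * d` lands as close
#' to the target as an integer count allows while staying inside the
#' admissible volume window.
#'
#' @param spec A [design_spec()].
#' @return Data frame with one row per flow condition: `condition_id`,
#'   `arm` ("screening"/"full"), `q` (mL/s), `d` (s), `n_puffs`,
#'   `session_volume` (mL).  The replicate count travels in the
#'   `reps_per_condition` attribute.  Construction is deterministic.
#' @export
#' @examples
#' d <- generate_design(design_spec())
#' nrow(d)                       # 34 conditions
#' sum(attr(d, "reps_per_condition") == 6)
generate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  n_scr <- round(spec$n_conditions * spec$screening_fraction)
  n_full <- spec$n_conditions - n_scr
  qr <- spec$q_range; dr <- spec$d_range

  rows <- list()
  if (n_scr > 0) {
    # nominally constant puff volume at the geometric centre of the design
    vp <- sqrt(prod(qr) * prod(dr))
    # restrict the screening durations so q = vp / d stays inside q_range
    ds_lo <- max(dr[1], vp / qr[2]); ds_hi <- min(dr[2], vp / qr[1])
    if (!(ds_lo < ds_hi))
      stop_data("infeasible screening arm: constant-volume flow rates leave q_range")
    d <- exp(seq(log(ds_lo), log(ds_hi), length.out = n_scr))
    q <- vp / d
    rows$screening <- data.frame(arm = "screening", q = q, d = d)
  }
  if (n_full > 0) {
    dims <- grid_dims(n_full)
    qg <- exp(seq(log(qr[1]), log(qr[2]), length.out = dims[["nq"]]))
    dg <- exp(seq(log(dr[1]), log(dr[2]), length.out = dims[["nd"]]))
    g <- expand.grid(q = qg, d = dg)[seq_len(n_full), ]
    rows$full <- data.frame(arm = "full", q = g$q, d = g$d)
  }
  out <- do.call(rbind, rows)
  vp <- out$q * out$d
  vr <- spec$session_volume_range
  n_lo <- ceiling(vr[1] / vp - 1e-9); n_hi <- floor(vr[2] / vp + 1e-9)
  if (any(n_lo > n_hi))
    stop_data("infeasible design: no integer puff count reaches the session ",
              "volume window for puff volume ", signif(max(vp), 4), " mL")
  np <- pmin(pmax(round(spec$target_session_volume / vp), n_lo), n_hi)
  out$n_puffs <- as.integer(np)
  out$session_volume <- np * vp
  out$condition_id <- sprintf("C%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[c("condition_id", "arm", "q", "d", "n_puffs", "session_volume")]
  attr(out, "reps_per_condition") <- rep(spec$reps_per_condition, nrow(out))
  attr(out, "spec") <- spec
  out
}

#' Simulate emissions trials from known models
#'
#' The data-generating process inverts the emissions models: for each
#' replicate trial of each condition, observed (q, d) are the nominal
#' condition perturbed by a small lognormal machine-control jitter;
#' `ln C_TPM` is drawn Normal(model surface, `noise_ln_sd`); TPM mass is
#' concentration times cumulative trial volume; the nicotine mass ratio is
#' drawn Normal(model line, `noise_f_sd`) truncated to (0, 1) and applied
#' to the trials designated for nicotine assay (the screening arm by
#' default, mirroring which filter pads get constituent analysis).
#'
#' @param design Output of [generate_design()].
#' @param tpm,nic Generating models (e.g. [reference_model()]).
#' @param noise_ln_sd SD of ln-scale concentration noise (default 0.15,
#'   calibrated so a refit over the default design lands near R^2 = 0.9).
#' @param noise_f_sd SD of mass-ratio noise, mg/mg (default 0.0025).
#' @param condition_jitter_cv Lognormal CV of observed-vs-nominal (q, d)
#'   (default 0.02).
#' @param reps Replicates per condition; default from the design.
#' @param nicotine_arm Which trials carry a nicotine measurement:
#'   "screening" (default), "all" or "none".
#' @param seed Integer seed; same seed, same table.
#' @return An emissions-trial data frame (see [read_trials()]).
#' @export
simulate_emissions <- function(design, tpm, nic, noise_ln_sd = 0.15,
                               noise_f_sd = 0.0025,
                               condition_jitter_cv = 0.02,
                               reps = NULL,
                               nicotine_arm = c("screening", "all", "none"),
                               seed = NULL) {
  stopifnot(inherits(tpm, "tpm_model"), inherits(nic, "nic_model"))
  nicotine_arm <- match.arg(nicotine_arm)
  check_number(noise_ln_sd, "noise_ln_sd", non_negative = TRUE)
  check_number(noise_f_sd, "noise_f_sd", non_negative = TRUE)
  check_number(condition_jitter_cv, "condition_jitter_cv", non_negative = TRUE)
  if (is.null(reps)) {
    reps <- attr(design, "reps_per_condition")
    if (is.null(reps)) reps <- 6L
  }
  reps <- rep_len(as.integer(reps), nrow(design))

  with_seed(seed, {
    idx <- rep(seq_len(nrow(design)), reps)
    n <- length(idx)
    q <- design$q[idx] * exp(rnorm(n, 0, condition_jitter_cv))
    d <- design$d[idx] * exp(rnorm(n, 0, condition_jitter_cv))
    np <- design$n_puffs[idx]
    vol <- np * q * d
    lnc <- log(predict(tpm, q = q, d = d)) + rnorm(n, 0, noise_ln_sd)
    tpm_mass <- exp(as.double(lnc)) * vol

    assay <- switch(nicotine_arm,
                    screening = design$arm[idx] == "screening",
                    all = rep(TRUE, n),
                    none = rep(FALSE, n))
    f <- rep(NA_real_, n)
    if (any(assay)) {
      mu <- predict(nic, q = q[assay])
      fa <- rnorm(sum(assay), mu, noise_f_sd)
      for (k in which(fa <= 0 | fa >= 1))   # truncate to (0,1) by redraw
        repeat { fa[k] <- rnorm(1L, mu[k], noise_f_sd); if (fa[k] > 0 && fa[k] < 1) break }
      f[assay] <- fa
    }
    rep_no <- sequence(reps)
    data.frame(condition_id = paste0(design$condition_id[idx], "-r", rep_no),
               q_ml_s = q, d_s = d, n_puffs = np, total_volume_ml = vol,
               tpm_mass_mg = tpm_mass,
               nicotine_mass_mg = f * tpm_mass)
  })
}

#' Session specification for topography simulation
#'
#' Puff durations and mean flows are drawn independently from lognormal
#' distributions (a positive, right-skewed stand-in for natural-environment
#' puffing; the field's empirical distribution family is not settled).
#'
#' @param n_puffs Number of puffs.
#' @param duration_meanlog,duration_sdlog Lognormal parameters of puff
#'   duration, s.
#' @param flow_meanlog,flow_sdlog Lognormal parameters of puff mean flow,
#'   mL/s.
#' @param interval_meanlog,interval_sdlog Lognormal parameters of the
#'   inter-puff interval, s (defaults centre near 20 s).
#' @param sample_rate Trace sampling rate, Hz (default 100).
#' @param rise Pulse rise/fall time, s (default 0.1).
#' @param session_id,participant_id Labels for the generated session.
#' @return A `session_spec` list.
#' @export
session_spec <- function(n_puffs = 12L,
                         duration_meanlog = log(2), duration_sdlog = 0.3,
                         flow_meanlog = log(30), flow_sdlog = 0.3,
                         interval_meanlog = log(20), interval_sdlog = 0.5,
                         sample_rate = 100, rise = 0.1,
                         session_id = "synthetic", participant_id = "synthetic") {
  stopifnot(n_puffs >= 1, duration_sdlog >= 0, flow_sdlog >= 0,
            interval_sdlog >= 0, sample_rate > 0, rise > 0)
  structure(list(n_puffs = as.integer(n_puffs),
                 duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
                 flow_meanlog = flow_meanlog, flow_sdlog = flow_sdlog,
                 interval_meanlog = interval_meanlog, interval_sdlog = interval_sdlog,
                 sample_rate = sample_rate, rise = rise,
                 session_id = session_id, participant_id = participant_id),
            class = "session_spec")
}

#' Simulate a puffing session and its rendered flow trace
#'
#' Draws per-puff (duration, mean flow) pairs from the spec's lognormals,
#' lays the puffs out with lognormal inter-puff gaps (gaps below 0.5 s are
#' redrawn so pulses never run together), and renders each puff as a
#' smoothed trapezoid pulse — linear rise and fall of `rise` seconds inside
#' the puff window, plateau height set so the pulse area equals the puff
#' volume q*d exactly — sampled at `sample_rate`.  Durations are floored
#' at `3 * rise` so every pulse has a plateau.
#'
#' @param spec A [session_spec()].
#' @param seed Integer seed.
#' @return List with `session` (the ground-truth [puff_session()]) and
#'   `trace` (the rendered [flow_trace()]).
#' @export
#' @examples
#' st <- simulate_session(session_spec(n_puffs = 3), seed = 1)
#' session_summary(st$session)
simulate_session <- function(spec = session_spec(), seed = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  with_seed(seed, {
    n <- spec$n_puffs
    d <- pmax(rlnorm(n, spec$duration_meanlog, spec$duration_sdlog), 3 * spec$rise)
    q <- rlnorm(n, spec$flow_meanlog, spec$flow_sdlog)
    gap <- rlnorm(n, spec$interval_meanlog, spec$interval_sdlog)
    redraws <- 0L
    while (any(gap < 0.5)) {         # re-space puffs that would overlap/merge
      k <- gap < 0.5
      gap[k] <- rlnorm(sum(k), spec$interval_meanlog, spec$interval_sdlog)
      redraws <- redraws + sum(k)
      if (redraws > 1000L) { gap[gap < 0.5] <- 0.5; break }
    }
    start <- 1 + cumsum(c(0, d[-n] + gap[-n]))

    dt <- 1 / spec$sample_rate
    t_end <- start[n] + d[n] + 1
    tg <- seq(0, t_end, by = dt)
    flow <- numeric(length(tg))
    r <- spec$rise
    for (i in seq_len(n)) {
      peak <- q[i] * d[i] / (d[i] - r)    # trapezoid area = q*d exactly
      xs <- start[i] + c(0, r, d[i] - r, d[i])
      ys <- c(0, peak, peak, 0)
      k <- tg >= start[i] & tg <= start[i] + d[i]
      flow[k] <- flow[k] + approx(xs, ys, xout = tg[k], rule = 2)$y
    }
    puffs <- data.frame(start = start, duration = d, volume = q * d,
                        mean_flow = q)
    list(session = puff_session(puffs, spec$session_id, spec$participant_id),
         trace = flow_trace(tg, flow))
  })
}

#' Reference playback topography profiles
#'
#' Seven exemplar single-session natural-environment puffing profiles, one
#' per participant, characterised by mean puff duration, mean puff flow
#' rate and total session volume.  Values are transcribed from a published
#' summary table whose typography runs the columns together; the parse
#' adopted here is the self-consistent one (implied puff counts of 10–42
#' per session) and the table should be read as a fixture, not as
#' re-published data.
#'
#' @return Data frame with columns `profile_id`, `mean_d` (s), `mean_q`
#'   (mL/s), `volume` (mL), `n_puffs` (implied integer count).
#' @export
playback_profiles <- function() {
  p <- data.frame(
    profile_id = c("OS3-01", "OS3-06", "OS3-10", "OS3-12", "OS3-14",
                   "OS3-26", "OS3-28"),
    mean_d = c(1.2, 1.2, 3.0, 1.2, 1.2, 2.3, 4.4),
    mean_q = c(50.6, 18.4, 16.1, 30.8, 16.7, 30.4, 62.6),
    volume = c(1007, 830, 503, 1004, 748, 605, 360))
  p$n_puffs <- as.integer(round(p$volume / (p$mean_d * p$mean_q)))
  p
}

#' Session spec targeting a playback profile's summary statistics
#'
#' Builds a [session_spec()] whose lognormal draws have arithmetic means
#' equal to the profile's mean duration and mean flow (meanlog =
#' log(target) - sdlog^2/2) and whose puff count makes the expected total
#' volume match the profile's.
#'
#' @param profile One row of [playback_profiles()] (or any list with
#'   `profile_id`, `mean_d`, `mean_q`, `n_puffs`).
#' @param sdlog Within-session heterogeneity of duration and flow
#'   (default 0.15).
#' @return A `session_spec`.
#' @export
session_spec_from_profile <- function(profile, sdlog = 0.15) {
  session_spec(
    n_puffs = profile$n_puffs,
    duration_meanlog = log(profile$mean_d) - sdlog^2 / 2,
    duration_sdlog = sdlog,
    flow_meanlog = log(profile$mean_q) - sdlog^2 / 2,
    flow_sdlog = sdlog,
    session_id = profile$profile_id,
    participant_id = sub("-.*", "", profile$profile_id))
}

#' Simulate observed playback yields
#'
#' Stands in for machine-playback measurements: each session's observed
#' yield per replicate is the model-predicted yield times a lognormal
#' multiplicative error, `observed = predicted * exp(N(0, obs_noise_cv))`,
#' applied independently to TPM and nicotine.
#'
#' @param sessions List of [puff_session()] objects.
#' @param tpm,nic Models used for the underlying predictions.
#' @param n_reps Replicates per session (default 6).
#' @param obs_noise_cv Lognormal sigma of the measurement error
#'   (default 0.2).
#' @param seed Integer seed.
#' @return Observed-yield data frame (see [read_observed_yields()]).
#' @export
simulate_observed_yields <- function(sessions, tpm, nic = NULL, n_reps = 6L,
                                     obs_noise_cv = 0.2, seed = NULL) {
  if (inherits(sessions, "puff_session")) sessions <- list(sessions)
  check_number(obs_noise_cv, "obs_noise_cv", non_negative = TRUE)
  stopifnot(n_reps >= 1)
  pred <- lapply(sessions, predict_session_yield, tpm = tpm, nic = nic,
                 per_puff = FALSE)
  with_seed(seed, {
    rows <- lapply(pred, function(p) {
      data.frame(session_id = p$session_id, replicate = seq_len(n_reps),
                 y_tpm_mg = p$y_tpm * exp(rnorm(n_reps, 0, obs_noise_cv)),
                 y_nic_mg = if (is.finite(p$y_nic))
                   p$y_nic * exp(rnorm(n_reps, 0, obs_noise_cv))
                 else NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate emissions trials from a fitted model
#'
#' `simulate()` method for `tpm_fit`: redraws the trial table the model was
#' fitted to, with new concentration noise at the fit's residual scale.
#'
#' @param object A `tpm_fit`.
#' @param nsim Number of tables to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` trial tables.
#' @export
simulate.tpm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data)) stop_data("model carries no training data")
  tr <- object$data
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    lnc <- log(predict(object, q = tr$q_ml_s, d = tr$d_s)) +
      rnorm(nrow(tr), 0, object$fit$rmse)
    tr$tpm_mass_mg <- exp(as.double(lnc)) * tr$total_volume_ml
    tr
  }))
}
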