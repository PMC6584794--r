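# Synthetic-data generators: design grid, emissions trials, rendered
# sessions, observed yields.

test_that("default design has 34 conditions replicating to 204 trials", {
  d <- generate_design(design_spec())
  expect_equal(nrow(d), 34L)
  expect_equal(sum(d$arm == "screening"), 10L)
  expect_equal(sum(d$arm == "full"), 24L)
  expect_equal(sum(attr(d, "reps_per_condition")), 204L)
})

test_that("screening arm holds puff volume constant to within 1%", {
  d <- generate_design(design_spec())
  vp <- with(d[d$arm == "screening", ], q * d)
  expect_lt(diff(range(vp)) / mean(vp), 0.01)
})

test_that("every design condition's session volume is inside the window", {
  d <- generate_design(design_spec())
  expect_true(all(d$session_volume >= 522 - 1e-6))
  expect_true(all(d$session_volume <= 1000 + 1e-6))
  expect_lt(abs(mean(d$session_volume) - 740) / 740, 0.15)
})

test_that("infeasible design ranges are refused", {
  expect_error(generate_design(design_spec(q_range = c(500, 600),
                                           d_range = c(4, 5),
                                           session_volume_range = c(522, 1000))),
               "infeasible")
})

test_that("simulated emissions are reproducible per seed and sized 204", {
  ref <- reference_model()
  d <- generate_design(design_spec())
  a <- simulate_emissions(d, ref$tpm, ref$nic, seed = 9)
  b <- simulate_emissions(d, ref$tpm, ref$nic, seed = 9)
  c2 <- simulate_emissions(d, ref$tpm, ref$nic, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_equal(nrow(a), 204L)
  # nicotine assays confined to the screening arm by default
  expect_equal(sum(is.finite(a$nicotine_mass_mg)), 60L)
})

test_that("noise-free simulated trials close the loop to the generating models", {
  ref <- reference_model()
  d <- generate_design(design_spec())
  tr <- simulate_emissions(d, ref$tpm, ref$nic, noise_ln_sd = 0,
                           noise_f_sd = 0, seed = 5)
  tf <- fit_tpm_model(tr)
  nf <- fit_nic_model(tr)
  expect_equal(unname(coef(tf)), unname(coef(ref$tpm)), tolerance = 1e-8)
  expect_equal(unname(coef(nf)), unname(coef(ref$nic)), tolerance = 1e-8)
})

test_that("refit R^2 matches the variance decomposition implied by the design", {
  # with ln-noise sigma, E[R^2] ~ Vs / (Vs + sigma^2) where Vs is the
  # brute-force signal variance of the generated design's linear predictor
  ref <- reference_model()
  d <- generate_design(design_spec())
  sigma <- 0.15
  lnc <- log(as.double(predict(ref$tpm, q = d$q, d = d$d)))
  vs <- mean((lnc - mean(lnc))^2)      # replication-weighted: equal reps
  expected_r2 <- vs / (vs + sigma^2)
  r2 <- vapply(1:30, function(s) {
    tr <- simulate_emissions(d, ref$tpm, ref$nic, noise_ln_sd = sigma,
                             condition_jitter_cv = 0, seed = 1000 + s)
    fit_tpm_model(tr)$fit$r_squared
  }, double(1L))
  expect_lt(abs(mean(r2) - expected_r2), 0.01)
})

test_that("rendered sessions reproduce a playback profile's summary statistics", {
  profs <- playback_profiles()
  os3_10 <- profs[profs$profile_id == "OS3-10", ]
  st <- simulate_session(session_spec_from_profile(os3_10), seed = 22)
  s <- session_summary(st$session)
  expect_lt(abs(s[["mean_d"]] - 3.0) / 3.0, 0.10)
  expect_lt(abs(s[["mean_q"]] - 16.1) / 16.1, 0.10)
  expect_lt(abs(s[["total_volume"]] - 503) / 503, 0.10)
})

test_that("a one-puff spec renders a trace with exactly one detected puff", {
  st <- simulate_session(session_spec(n_puffs = 1), seed = 23)
  expect_equal(nrow(detect_puffs(st$trace)), 1L)
})

test_that("detection recovers ground truth on rendered traces across random specs", {
  set.seed(407)
  for (k in 1:50) {
    spec <- session_spec(n_puffs = sample(2:6, 1),
                         duration_meanlog = log(runif(1, 1.2, 3.5)),
                         duration_sdlog = runif(1, 0.05, 0.3),
                         flow_meanlog = log(runif(1, 15, 60)),
                         flow_sdlog = runif(1, 0.05, 0.3))
    st <- simulate_session(spec, seed = 2000 + k)
    puffs <- detect_puffs(st$trace)
    truth <- st$session$puffs
    expect_equal(nrow(puffs), nrow(truth))
    expect_lt(max(abs(puffs$duration - truth$duration)), 0.06)
    expect_lt(max(abs(puffs$volume - truth$volume) / truth$volume), 0.03)
    expect_lt(max(abs(puffs$mean_flow - truth$mean_flow) / truth$mean_flow), 0.05)
  }
})

test_that("generators are bit-reproducible given (spec, seed)", {
  s1 <- simulate_session(session_spec(n_puffs = 5), seed = 31)
  s2 <- simulate_session(session_spec(n_puffs = 5), seed = 31)
  expect_identical(s1, s2)
  ref <- reference_model()
  o1 <- simulate_observed_yields(list(s1$session), ref$tpm, ref$nic, seed = 8)
  o2 <- simulate_observed_yields(list(s2$session), ref$tpm, ref$nic, seed = 8)
  expect_identical(o1, o2)
})

test_that("substream seeds are deterministic, distinct and within integer range", {
  a <- substream_seed(1234, 1); b <- substream_seed(1234, 2)
  expect_identical(a, substream_seed(1234, 1))
  expect_false(a == b)
  expect_true(a >= 0 && a < 2^31)
})

test_that("zero observation noise gives observed equal to predicted", {
  ref <- reference_model()
  st <- simulate_session(session_spec(n_puffs = 5), seed = 32)
  y <- predict_session_yield(st$session, ref$tpm, ref$nic)
  obs <- simulate_observed_yields(list(st$session), ref$tpm, ref$nic,
                                  n_reps = 3, obs_noise_cv = 0, seed = 3)
  expect_equal(obs$y_tpm_mg, rep(y$y_tpm, 3), tolerance = 1e-12)
  expect_equal(obs$y_nic_mg, rep(y$y_nic, 3), tolerance = 1e-12)
})
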