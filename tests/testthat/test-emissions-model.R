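# Design rows, model evaluation, and OLS fitting with diagnostics.

table2_b <- c(9.513425, 1.312385, -0.448513, -0.581447, 1.775869, 0.007221)
table3_beta <- c(0.009809, -0.000005)

test_that("TPM design row reproduces log identities", {
  expect_equal(drop(tpm_design_row(exp(1), 1000)),
               c(b1 = 1, b2 = 1, b3 = 1000, b4 = 1, b5 = 0, b6 = 1000 * exp(1)))
  expect_equal(drop(tpm_design_row(1, 1)),
               c(b1 = 1, b2 = 0, b3 = 1, b4 = 0, b5 = -log(1000), b6 = 1))
})

test_that("TPM design row matches the frozen independent evaluation at (30.4, 2.3)", {
  # computed once with an independent symbolic/arithmetic oracle
  expect_equal(drop(tpm_design_row(30.4, 2.3)),
               c(b1 = 1, b2 = 3.414442608412176, b3 = 2.3,
                 b4 = 11.658418326140543, b5 = -6.074846156047033, b6 = 69.92),
               tolerance = 1e-12)
})

test_that("design row rejects non-positive flow or duration", {
  expect_error(tpm_design_row(0, 1), "q must be > 0")
  expect_error(tpm_design_row(10, -2), "d must be > 0")
})

test_that("concentration prediction is exp of the linear predictor", {
  m <- tpm_model(table2_b)
  qs <- c(5, 30.4, 80); ds <- c(0.5, 2.3, 4)
  expect_equal(log(as.double(predict(m, q = qs, d = ds))),
               drop(tpm_design_row(qs, ds) %*% table2_b), tolerance = 1e-12)
  # frozen regression fixture, independent evaluation of the reference surface
  expect_equal(as.double(predict(m, q = 30.4, d = 2.3)),
               0.016587885385054048, tolerance = 1e-12)
  expect_true(all(predict(m, q = runif(20, 1, 100), d = runif(20, 0.2, 6)) > 0))
})

test_that("shifting the intercept by ln 2 doubles every prediction", {
  m <- tpm_model(table2_b)
  m2 <- tpm_model(table2_b + c(log(2), 0, 0, 0, 0, 0))
  q <- runif(10, 5, 90); d <- runif(10, 0.5, 5)
  expect_equal(as.double(predict(m2, q = q, d = d)),
               2 * as.double(predict(m, q = q, d = d)), tolerance = 1e-12)
})

test_that("nicotine mass-ratio prediction is the fitted line", {
  expect_equal(predict(nic_model(c(0.0098, 0)), q = c(0, 17, 99)),
               rep(0.0098, 3))
  m <- nic_model(table3_beta)
  expect_equal(predict(m, q = 0), table3_beta[1])
  expect_equal(predict(m, q = 50), 0.009559, tolerance = 1e-12)  # frozen
  expect_warning(predict(nic_model(c(0.5, 0.1)), q = 10), "outside")
})

test_that("reference-model mass ratio stays below the un-puffed e-liquid fraction", {
  ref <- reference_model()
  f <- predict(ref$nic, q = seq(0, 100, by = 0.5))
  expect_true(all(f < 0.0140))
  expect_true(all(f > 0))
})

test_that("ols_fit handles exact fits and recovers 2-point lines", {
  X <- cbind(1, c(1, 2, 3, 4))
  y <- drop(X %*% c(2, -0.5))
  f <- ols_fit(X, y)
  expect_equal(unname(f$coefficients), c(2, -0.5), tolerance = 1e-12)
  expect_equal(f$report$r_squared, 1)
  expect_equal(unname(f$report$coefficients[, "Std. Error"]), c(0, 0))
  expect_true(all(is.infinite(f$report$coefficients[, "tStat"])))

  X2 <- cbind(1, c(0, 1, 2))
  f2 <- ols_fit(X2, c(1, 3, 5))
  expect_equal(unname(f2$coefficients), c(1, 2), tolerance = 1e-12)
})

test_that("ols_fit agrees with the brute-force normal-equations oracle", {
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(8:20, 1); p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    got <- ols_fit(X, y)
    want <- ne_ols(X, y)
    expect_equal(unname(got$coefficients), unname(want$beta), tolerance = 1e-8)
    expect_equal(unname(got$report$coefficients[, "Std. Error"]),
                 unname(want$se), tolerance = 1e-8)
  }
})

test_that("ols_fit names collinear columns on rank deficiency", {
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(ols_fit(X, rnorm(10)), "collinear column\\(s\\): c",
               class = "puffyield_singular_error")
})

test_that("fit report satisfies its internal identities", {
  set.seed(403)
  X <- cbind(1, rnorm(30), rnorm(30))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(30, 0, 0.5)
  rep <- ols_fit(X, y)$report
  tab <- rep$coefficients
  expect_equal(tab[, "tStat"], tab[, "Estimate"] / tab[, "Std. Error"],
               tolerance = 1e-9)
  expect_equal(rep$adj_r_squared,
               1 - (1 - rep$r_squared) * (rep$n_obs - 1) / (rep$n_obs - rep$n_params),
               tolerance = 1e-12)
  expect_gte(rep$r_squared, 0); expect_lte(rep$r_squared, 1)
  expect_equal(rep$rmse, sqrt(sum(rep$residuals^2) / (30 - 3)), tolerance = 1e-12)
})

test_that("noise-free trials are refit to the generating TPM model exactly", {
  gen <- tpm_model(table2_b)
  set.seed(404)
  q <- runif(15, 10, 90); d <- runif(15, 1, 5)
  trials <- make_trials(q, d, c_tpm = as.double(predict(gen, q = q, d = d)))
  fit <- fit_tpm_model(trials)
  expect_equal(unname(coef(fit)), table2_b, tolerance = 1e-8)
  expect_equal(fit$fit$r_squared, 1)
})

test_that("noise-free constant mass ratio gives beta1 = constant, beta2 = 0", {
  q <- c(10, 30, 50, 70)
  trials <- make_trials(q, d = 2, c_tpm = 0.02, f_nic = 0.0098)
  fit <- fit_nic_model(trials)
  expect_equal(unname(coef(fit)), c(0.0098, 0), tolerance = 1e-10)
})

test_that("fitting errors name the offending trial and respect minimum sizes", {
  trials <- make_trials(runif(8, 10, 60), runif(8, 1, 4), c_tpm = 0.02)
  trials$tpm_mass_mg[3] <- 0
  expect_error(fit_tpm_model(trials), "T03")
  expect_error(fit_tpm_model(make_trials(30, 2, 0.02)), "at least 7")
  expect_error(fit_nic_model(make_trials(30, 2, 0.02)), "at least 3")
})

test_that("the ln(d/1000) column is a pure reparameterization of ln(d)", {
  # swapping ln(d/1000) for ln(d) while shifting the intercept by
  # -b5 * ln(1000) leaves every prediction unchanged
  set.seed(405)
  b <- table2_b
  q <- runif(25, 5, 95); d <- runif(25, 0.5, 5.5)
  X_alt <- cbind(1, log(q), d, log(q)^2, log(d), q * d)
  b_alt <- b; b_alt[1] <- b[1] - b[5] * log(1000)
  expect_equal(drop(X_alt %*% b_alt),
               drop(tpm_design_row(q, d) %*% b), tolerance = 1e-9)
  # and refitting noise-free data in either basis gives identical fits
  y <- drop(tpm_design_row(q, d) %*% b)
  refit_alt <- ols_fit(X_alt, y)$coefficients
  expect_equal(unname(refit_alt[1]), b[1] - b[5] * log(1000), tolerance = 1e-6)
  expect_equal(unname(refit_alt[-1]), unname(b[-1]), tolerance = 1e-7)
})

test_that("trial tables round-trip through the CSV dialect", {
  trials <- make_trials(c(20, 40), c(2, 3), c_tpm = c(0.02, 0.03),
                        f_nic = c(0.01, NA))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, p)
  back <- read_trials(p)
  expect_equal(back$q_ml_s, trials$q_ml_s)
  expect_equal(back$tpm_mass_mg, trials$tpm_mass_mg, tolerance = 1e-12)
  expect_true(is.na(back$nicotine_mass_mg[2]))
})

test_that("model JSON round-trips coefficients exactly", {
  p <- withr::local_tempfile(fileext = ".json")
  write_model(tpm_model(table2_b), nic_model(table3_beta), p,
              meta = list(envelope = list(q = c(10, 100), d = c(1, 5))))
  m <- read_model(p)
  expect_identical(unname(coef(m$tpm)), table2_b)
  expect_identical(unname(coef(m$nic)), table3_beta)
  expect_equal(m$tpm$envelope$q, c(10, 100))
})
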