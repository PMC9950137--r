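log_time_grid <- function(n = 150, t0 = 0.001, t1 = 600) {
  10^seq(log10(t0), log10(t1), length.out = n)
}

test_that("noiseless exponential traces are recovered exactly", {
  t <- seq(0, 20, 0.05)
  fit <- fit_single_exponential(t, 0.3 + 0.7 * exp(-0.25 * t))
  expect_equal(fit$k, 0.25, tolerance = 1e-8)
  expect_equal(fit$A_inf, 0.3, tolerance = 1e-8)
})

test_that("reduction-rate recovery from noisy traces stays within 3 SE", {
  tr <- simulate_trace_exponential(k = 0.25, A0 = 1, A_inf = 0.2,
                                   time = seq(0, 25, length.out = 400),
                                   noise_sd = 0.02 * 0.8, seed = 5)
  fit <- fit_single_exponential(tr$time, tr$absorbance)
  expect_lt(abs(fit$k - 0.25), 3 * fit$k_se)
})

test_that("biphasic traces trigger the runs-test diagnostic", {
  t <- log_time_grid(200, 0.001, 400)
  A <- 0.4 * exp(-3 * t) + 0.6 * exp(-0.01 * t)
  expect_warning(fit <- fit_single_exponential(t, A), "sequential")
  expect_true(fit$biphasic_warning)
})

test_that("sequential concentration profiles obey closed-form identities", {
  t <- seq(0, 100, 0.5)
  C <- sequential_concentrations(t, 3.2, 0.0065)
  expect_lt(max(abs(rowSums(C) - 1)), 1e-12)
  expect_equal(C[1, ], c(a = 1, b = 0, c = 0))
  # intermediate maximum at the closed-form extremum
  tmax <- intermediate_tmax(3.2, 0.0065)
  cb <- function(x) sequential_concentrations(x, 3.2, 0.0065)[, "b"]
  expect_gt(cb(tmax), cb(tmax * 0.9))
  expect_gt(cb(tmax), cb(tmax * 1.1))
  # confluent limit agrees with nearby distinct rates
  C1 <- sequential_concentrations(t, 1, 1 - 1e-9)[, "b"]
  expect_lt(max(abs(C1 - t * exp(-t))), 1e-6)
})

test_that("noiseless matrices round-trip through the sequential fit", {
  t <- log_time_grid()
  wl <- seq(320, 520, 4)
  sf <- simulate_stopped_flow(3.2, 0.0065, t, wl, noise_sd = 0)
  fit <- fit_sequential_two_step(sf$time, sf$wavelength, sf$A)
  expect_lt(abs(fit$k1 - 3.2) / 3.2, 1e-6)
  expect_lt(abs(fit$k2 - 0.0065) / 0.0065, 1e-6)
  expect_equal(fit$lambda_max_b, 380)
  # recovered spectra match the generating ones up to numerical noise
  expect_lt(max(abs(fit$spectra - sf$truth$spectra)), 1e-8)
})

test_that("the k1 > k2 identifiability convention always holds", {
  t <- log_time_grid(120)
  wl <- seq(340, 500, 8)
  for (seed in 1:3) {
    sf <- simulate_stopped_flow(2, 0.05, t, wl, noise_sd = 2e-4, seed = seed)
    fit <- fit_sequential_two_step(sf$time, sf$wavelength, sf$A)
    expect_gt(fit$k1, fit$k2)
  }
})

test_that("vanishing k2 collapses to the single-exponential fit", {
  # with k2 ~ 0 the data are a single exponential; which of the two fitted
  # rates carries it is not identifiable (free spectra absorb the rest), so
  # the check is that one rate matches and the data are reproduced exactly
  t <- log_time_grid(200, 0.001, 5)
  wl <- 450
  spectra <- matrix(c(0.01, 0.05, 0.0501), 1, 3)
  sf <- simulate_stopped_flow(2.5, 1e-7, t, wl, spectra = spectra,
                              noise_sd = 0)
  fit2 <- fit_sequential_two_step(sf$time, sf$wavelength, sf$A)
  fit1 <- suppressWarnings(fit_single_exponential(t, as.numeric(sf$A)))
  expect_lt(min(abs(c(fit2$k1, fit2$k2) - fit1$k)) / fit1$k, 1e-4)
  expect_lt(fit2$residual_norm, 1e-8)
})

test_that("single-wavelength mode degenerates to one column", {
  t <- log_time_grid(100, 0.001, 600)
  sf <- simulate_stopped_flow(3.2, 0.0065, t, 450, noise_sd = 0)
  expect_equal(ncol(sf$A), 1)
  fit <- fit_sequential_two_step(sf$time, 450, sf$A)
  expect_lt(abs(fit$k1 - 3.2) / 3.2, 1e-4)
})

test_that("sequential fit validates its inputs", {
  t <- log_time_grid(50)
  wl <- seq(340, 500, 20)
  sf <- simulate_stopped_flow(1, 0.01, t, wl)
  expect_error(fit_sequential_two_step(t[-1], wl, sf$A), "time grid")
  expect_error(fit_sequential_two_step(rev(t), wl, sf$A),
               "strictly increasing")
  Abad <- sf$A; Abad[1, 1] <- NA
  expect_error(fit_sequential_two_step(t, wl, Abad), "non-finite")
})
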