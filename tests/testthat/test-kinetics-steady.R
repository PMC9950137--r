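test_that("noiseless Michaelis-Menten data are recovered exactly", {
  conc <- c(5, 10, 25, 50, 100, 200)
  v <- 2 * conc / (50 + conc)
  fit <- fit_michaelis_menten(conc, v)
  expect_equal(fit$K_M, 50, tolerance = 1e-8)
  expect_equal(fit$V_max, 2, tolerance = 1e-8)
})

test_that("K_M is recovered within 3 SE at the coenzyme-saturation design", {
  d <- simulate_initial_rates(K_M = 15.7, V_max = 1.5,
                              conc = c(2, 5, 10, 20, 40, 80, 140, 200),
                              n_rep = 3, noise_frac = 0.05, seed = 11)
  fit <- fit_michaelis_menten(d$conc, d$rate)
  expect_lt(abs(fit$K_M - 15.7), 3 * fit$K_M_se)
})

test_that("designs far below K_M carry little Fisher information", {
  # true K_M 500: the design spans only 0.1-2% of it
  set.seed(4)
  conc <- rep(c(0.5, 1, 2, 3, 5, 7, 10, 12), each = 3)
  v <- 2 * conc / (500 + conc) * (1 + rnorm(length(conc), 0, 0.01))
  fit <- fit_michaelis_menten(conc, v)
  expect_true(any(grepl("low information", fit$warnings)))
  # SE is a large fraction of the estimate in this regime
  expect_gt(fit$K_M_se / fit$K_M, 0.2)

  # a sparse noisy realization in the same regime can place the optimum at
  # negative parameters; that is reported as a flagged failure, not silence
  set.seed(4)
  c4 <- c(0.5, 1, 1.5, 2)
  v4 <- 2 * c4 / (500 + c4) * (1 + rnorm(4, 0, 0.02))
  expect_error(fit_michaelis_menten(c4, v4),
               "flagged fit failure|failed to converge")
})

test_that("catalytic efficiency is k_cat/K_M in s^-1 mM^-1", {
  conc <- c(50, 100, 250, 500, 1000, 2000, 4000)  # uM
  kcat <- 0.98; km <- 1000                        # ratio 0.98 s^-1 mM^-1
  v <- 2 * kcat * conc / (km + conc)              # [E] = 2 uM, raw rate
  fit <- fit_michaelis_menten(conc, v, enzyme_conc = 2, conc_unit = "uM")
  expect_equal(fit$k_cat, kcat, tolerance = 1e-6)
  expect_equal(fit$efficiency, 0.98, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_michaelis_menten(c(-1, 2, 3, 4), c(1, 2, 3, 4)),
               "negative")
})

test_that("A340 slopes convert to turnover rates via Beer-Lambert", {
  t <- seq(0, 10, 0.1)
  # dA/dt = -0.00622 A/s, eps 6.22 mM^-1 cm^-1, path 1 cm, [E] 1 uM -> 1 s^-1
  res <- rate_from_A340(t, 1 - 0.00622 * t, enzyme_conc = 1)
  expect_equal(res$rate, 1, tolerance = 1e-8)

  flat <- rate_from_A340(t, rep(0.8, length(t)), enzyme_conc = 1)
  expect_equal(flat$rate, 0)
})

test_that("the initial-rate window stops before substrate depletion curvature", {
  # exponential consumption: initial slope -k*A0; curvature after ~10%
  k <- 0.05; A0 <- 1
  t <- seq(0, 60, 0.25)
  A <- A0 * exp(-k * t)
  res <- rate_from_A340(t, A, enzyme_conc = 1)
  true_rate <- k * A0 / 6.22 * 1000
  expect_lt(abs(res$rate - true_rate) / true_rate, 0.02)
})

test_that("oxygen affinity fits the hyperbola and flags saturation", {
  o2 <- c(0.13, 0.31, 0.61, 0.96)  # mM, the after-mixing design
  kobs <- 4 * o2 / (0.020 + o2)    # K = 20 uM
  fit <- fit_oxygen_affinity(o2, kobs)
  expect_equal(fit$K_M_O2, 0.020, tolerance = 1e-6)
  expect_false(fit$saturated)

  set.seed(2)
  flatk <- 4 * o2 / (0.0005 + o2) * (1 + rnorm(4, 0, 0.01))
  fit2 <- fit_oxygen_affinity(o2, flatk)
  expect_true(fit2$saturated)
  expect_lt(fit2$K_M_O2, min(o2))
})

test_that("oxygen-affinity recovery at the four-level design", {
  set.seed(21)
  ok <- 0L
  for (i in 1:20) {
    d <- simulate_initial_rates(K_M = 0.015, V_max = 3,
                                conc = c(0.13, 0.31, 0.61, 0.96),
                                n_rep = 2, noise_frac = 0.05,
                                seed = 1000 + i)
    fit <- fit_oxygen_affinity(d$conc, d$rate)
    if (abs(fit$K_M_O2 - 0.015) <= 3 * fit$K_M_O2_se) ok <- ok + 1L
  }
  expect_gte(ok, 18L)   # ±3 SE should cover virtually always
})

test_that("conversions follow substrate depletion normalized to the standard", {
  expect_equal(conversion_percent(100, 20, 100, 20), 0)
  expect_equal(conversion_percent(0, 20, 100, 20), 100)
  expect_equal(conversion_percent(85, 20, 100, 20), 15)
  # invariance under a common rescaling of all areas
  expect_equal(conversion_percent(85 * 3.7, 20 * 3.7, 100 * 3.7, 20 * 3.7),
               15)
  expect_error(conversion_percent(1, 0, 1, 1), "internal-standard")
  expect_warning(conversion_percent(120, 20, 100, 20), "clamped")
})

test_that("holoenzyme concentration is Beer-Lambert arithmetic", {
  expect_equal(holoenzyme_concentration(0.113, 1), 10)
  expect_equal(holoenzyme_concentration(0, 1), 0)
  expect_equal(holoenzyme_concentration(0.113, 0.2), 50)
  expect_error(holoenzyme_concentration(-0.1), "negative")
})

test_that("melting temperatures come from the derivative peak", {
  mc <- simulate_melt_curve(T_m = 60, slope = 2, noise_sd = 0)
  tm <- melting_temperature(mc$temperature, mc$fluorescence)
  expect_false(tm$no_transition)
  expect_lt(abs(tm$T_m - 60), 0.2)

  flat <- melting_temperature(seq(25, 95, 0.5),
                              rep(1, length(seq(25, 95, 0.5))))
  expect_true(flat$no_transition)

  two <- simulate_melt_curve(T_m = 55, slope = 1.5, amplitude = 1,
                             second = list(T_m = 75, amplitude = 0.5,
                                           slope = 1.5), noise_sd = 0)
  tm2 <- melting_temperature(two$temperature, two$fluorescence)
  expect_lt(abs(tm2$T_m - 55), 0.5)        # taller transition wins
  expect_lt(abs(tm2$secondary_T_m - 75), 0.5)
})
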