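test_that("dwell generator is seeded, unbiased, and exponential", {
  d1 <- simulate_dwell_times(10, 10000, seed = 42)
  d2 <- simulate_dwell_times(10, 10000, seed = 42)
  expect_identical(d1$duration_ns, d2$duration_ns)
  expect_false(any(d1$censored))

  # mean of Exp(k) dwells is 1000/k ns; allow 4 standard errors
  expect_lt(abs(mean(d1$duration_ns) - 100), 4 * 100 / sqrt(10000))

  # Kolmogorov-Smirnov distance against the target exponential CDF
  x <- sort(d1$duration_ns)
  ecdf_hi <- seq_along(x) / length(x)
  ecdf_lo <- ecdf_hi - 1 / length(x)
  F <- 1 - exp(-x / 100)
  ks <- max(pmax(abs(ecdf_hi - F), abs(ecdf_lo - F)))
  expect_lt(ks, 0.02)

  expect_error(simulate_dwell_times(0, 10), class = "lipidex_error_parameter")
  expect_error(simulate_dwell_times(10, 0), class = "lipidex_error_parameter")
})

test_that("closed-form exponential MLE recovers the generator's rate", {
  d <- simulate_dwell_times(8, 2000, seed = 1)
  oracle <- oracle_mle_koff(d$duration_ns)
  # oracle itself is consistent: within 4 relative standard errors of truth
  expect_lt(abs(oracle - 8) / 8, 4 / sqrt(2000))
  # the estimator path must agree with the closed form on uncensored data
  est <- estimate_koff(d, n_boot = 0)
  expect_equal(est$k_off, oracle, tolerance = 1e-12)
})

test_that("contact traces honour degenerate and stationary limits", {
  tr0 <- simulate_contact_trace(k_on = 0, k_off = 10, duration_ns = 1000,
                                dt_ns = 1, seed = 5)
  expect_true(all(tr0$state == 0))

  tr <- simulate_contact_trace(k_on = 20, k_off = 20, duration_ns = 2e5,
                               dt_ns = 1, seed = 6)
  expect_lt(abs(site_occupancy(tr)$occupancy - 0.5), 0.02)

  # same seed, same trace
  tr2 <- simulate_contact_trace(k_on = 20, k_off = 20, duration_ns = 2e5,
                                dt_ns = 1, seed = 6)
  expect_identical(tr$state, tr2$state)

  expect_warning(
    simulate_contact_trace(k_on = 5, k_off = 5, duration_ns = 1e5, dt_ns = 150,
                           seed = 1),
    "coarse"
  )
  expect_error(
    simulate_contact_trace(k_on = 5, k_off = 5, duration_ns = 50, dt_ns = 1),
    class = "lipidex_error_parameter"
  )
})

test_that("trace occupancy matches k_on/(k_on+k_off) within binomial error", {
  cases <- list(c(30, 10), c(10, 30), c(50, 50))
  for (i in seq_along(cases)) {
    k_on <- cases[[i]][1]
    k_off <- cases[[i]][2]
    dur <- 1e5
    tr <- simulate_contact_trace(k_on, k_off, dur, dt_ns = 1, seed = 100 + i)
    p <- k_on / (k_on + k_off)
    ess <- dur * (k_on + k_off) / 1000
    se <- sqrt(p * (1 - p) / ess)
    expect_lt(abs(site_occupancy(tr)$occupancy - p), 3 * se)
  }
})

test_that("a lipid-free single-charge spectrum has one apex at (M+zH)/z", {
  fx <- spectrum_fixture(
    protein = protein_species("P33", 33000, 11, 11),
    lipids = tibble::tibble(name = "POPE", mass = 718.01, lipid_class = "PE",
                            conc = 0, n_sites = 1, K_L = 50, K_D = 0.05,
                            protected = FALSE),
    detergent = detergent_species("NG", 306.4, 0.1),
    envelope = list(center = 11, width = 0.5),
    peak_fwhm_mz = 4, noise_sd = 0, mz_min = 2900, mz_max = 3200,
    mz_step = 0.25
  )
  s <- simulate_spectrum(fx, 0)
  pk <- pick_peaks(s, min_spacing_mz = 2)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - (33000 + 11 * 1.00728) / 11), 0.25)
})

test_that("adduct peak spacing equals the lipid formula mass over z", {
  pope_mass <- formula_mass("C39H76NO8P")
  fx <- spectrum_fixture(
    protein = protein_species("PSH", 33000, 11, 11),
    lipids = tibble::tibble(name = "POPE", mass = pope_mass, lipid_class = "PE",
                            conc = 50, n_sites = 1, K_L = 50, K_D = 0.05,
                            protected = FALSE),
    detergent = detergent_species("NG", 306.4, 0.1),
    envelope = list(center = 11, width = 0.5),
    peak_fwhm_mz = 4, noise_sd = 0, mz_min = 2900, mz_max = 3200,
    mz_step = 0.25
  )
  s <- simulate_spectrum(fx, 0)
  pk <- pick_peaks(s, min_spacing_mz = 2)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(diff(pk$mz) - pope_mass / 11), 0.05)
})

test_that("noiseless spectra conserve total configured amplitude", {
  fx <- single_lipid_fixture(noise_sd = 0)
  s <- simulate_spectrum(fx, 0)
  integral <- sum(diff(s$mz) * (s$intensity[-1] + s$intensity[-nrow(s)]) / 2)
  # amplitudes are envelope weight x composition probability, totalling 1
  expect_lt(abs(integral - 1), 1e-3)
})

test_that("a grid that misses a theoretical peak fails loudly", {
  fx <- single_lipid_fixture(noise_sd = 0)
  fx$mz_max <- 3100 # the 3-adduct z=10 peak now falls off-grid
  expect_error(simulate_spectrum(fx, 0), "does not cover",
               class = "lipidex_error_parameter")
})

test_that("titration truth is monotone for exchangeable, flat for protected", {
  fx <- single_lipid_fixture(noise_sd = 0.005)
  sim <- simulate_titration(fx, c(0.1, 0.1), seed = 1)
  # equal concentrations give identical true occupancies
  expect_equal(sim$series$bound_fraction[sim$series$point == 1],
               sim$series$bound_fraction[sim$series$point == 2])

  sim2 <- simulate_titration(fx, c(0, 0.5, 5, 500), seed = 1)
  theta <- sim2$series$bound_fraction
  expect_true(all(diff(theta) <= 1e-12))
  expect_lt(theta[length(theta)], 1e-3) # huge detergent removes everything

  fxp <- fx
  fxp$lipids$protected <- TRUE
  simp <- simulate_titration(fxp, c(0, 0.5), seed = 1)
  expect_equal(simp$series$bound_fraction[1], simp$series$bound_fraction[2])

  expect_error(simulate_titration(fx, numeric(0)),
               class = "lipidex_error_parameter")
  expect_error(simulate_titration(fx, c(0.5, 0.2)),
               class = "lipidex_error_parameter")
})
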