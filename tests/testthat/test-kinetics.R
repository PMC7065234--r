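make_binary_trace <- function(states, dt = 1, site_id = "s") {
  lipidex:::new_contact_trace(
    tibble::tibble(frame = seq_along(states) - 1L,
                   time_ns = (seq_along(states) - 1) * dt,
                   site_id = site_id, state = as.integer(states)),
    dt_ns = dt
  )
}

make_distance_trace <- function(d, dt = 1, site_id = "s") {
  lipidex:::new_contact_trace(
    tibble::tibble(frame = seq_along(d) - 1L, time_ns = (seq_along(d) - 1) * dt,
                   site_id = site_id, distance_nm = d),
    dt_ns = dt
  )
}

test_that("dual-cutoff binarization applies hysteresis", {
  tr <- make_distance_trace(rep(0.3, 50))
  expect_true(all(binarize_contacts(tr)$state == 1))

  # oscillation inside the hysteresis band after first entry stays bound
  osc <- make_distance_trace(c(0.3, rep(c(0.6, 0.9), 20), 1.2, 0.9))
  b <- binarize_contacts(osc, d_on = 0.55, d_off = 1.0)
  expect_true(all(b$state[1:41] == 1))
  expect_true(all(b$state[42:43] == 0)) # exit only above d_off; stays out in-band

  expect_error(binarize_contacts(osc, d_on = 1.0, d_off = 0.5),
               class = "lipidex_error_parameter")
})

test_that("dual-cutoff dwells are no shorter than single-cutoff dwells", {
  tr <- simulate_contact_trace(k_on = 40, k_off = 10, duration_ns = 5e4,
                               dt_ns = 0.5, rattle_rate = 30, rattle_mean = 1,
                               seed = 77, output = "distance",
                               distance_sd = 0.12)
  dual <- extract_dwells(binarize_contacts(tr, 0.55, 1.0), gap_tolerance_ns = 0)
  single <- extract_dwells(binarize_contacts(tr, 0.55, 0.55), gap_tolerance_ns = 0)
  expect_gt(mean(dual$duration_ns), mean(single$duration_ns))
})

test_that("dwell extraction merges small gaps and flags trace-end censoring", {
  tr <- make_binary_trace(c(rep(0, 5), rep(1, 100), rep(0, 5)))
  d <- extract_dwells(tr)
  expect_equal(d$duration_ns, 100)
  expect_false(d$censored)

  tr_end <- make_binary_trace(c(rep(0, 5), rep(1, 10)))
  expect_true(extract_dwells(tr_end)$censored)

  # two runs split by a 3 ns gap merge under a 5 ns tolerance
  tr_gap <- make_binary_trace(c(0, rep(1, 10), rep(0, 3), rep(1, 10), 0))
  merged <- extract_dwells(tr_gap, gap_tolerance_ns = 5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_ns, 23)
  split2 <- extract_dwells(tr_gap, gap_tolerance_ns = 2)
  expect_equal(nrow(split2), 2)

  empty <- extract_dwells(make_binary_trace(integer(0)))
  expect_equal(nrow(empty), 0)
})

test_that("rattling is absorbed when gaps fit inside the merge tolerance", {
  base <- list(k_on = 20, k_off = 10, duration_ns = 4e5, dt_ns = 0.5)
  quiet <- simulate_contact_trace(base$k_on, base$k_off, base$duration_ns,
                                  base$dt_ns, rattle_rate = 0, seed = 88)
  noisy <- simulate_contact_trace(base$k_on, base$k_off, base$duration_ns,
                                  base$dt_ns, rattle_rate = 10,
                                  rattle_mean = 2, seed = 88)
  d_quiet <- extract_dwells(quiet, gap_tolerance_ns = 5)
  d_noisy <- extract_dwells(noisy, gap_tolerance_ns = 5)
  expect_lt(abs(mean(d_noisy$duration_ns) - mean(d_quiet$duration_ns)) /
              mean(d_quiet$duration_ns), 0.10)
  # and the k_off estimates agree within 10 %
  k_q <- estimate_koff(d_quiet, n_boot = 0)$k_off
  k_n <- estimate_koff(d_noisy, n_boot = 0)$k_off
  expect_lt(abs(k_n - k_q) / k_q, 0.10)
})

test_that("survival curves count dwells at risk, censoring-aware", {
  d <- lipidex:::new_dwell_times(tibble::tibble(
    site_id = "s", duration_ns = c(10, 20, 30), censored = FALSE))
  sc <- survival_curve(d)
  expect_equal(survival_at(sc, 0), 1)
  expect_equal(survival_at(sc, 15), 2 / 3)
  expect_equal(survival_at(sc, 25), 1 / 3)

  all_cens <- lipidex:::new_dwell_times(tibble::tibble(
    site_id = "s", duration_ns = c(10, 20), censored = TRUE))
  expect_error(survival_curve(all_cens), "longer traces",
               class = "lipidex_error_input")

  # DKW-style agreement with the generating exponential at n = 5000
  dd <- simulate_dwell_times(20, 5000, seed = 9)
  sc2 <- survival_curve(dd)
  expect_lt(max(abs(sc2$survival - exp(-20 / 1000 * sc2$time_ns))), 0.03)
})

test_that("censored exponential MLE handles exact and censored dwells", {
  d100 <- lipidex:::new_dwell_times(tibble::tibble(
    site_id = "s", duration_ns = rep(100, 20), censored = FALSE))
  expect_equal(estimate_koff(d100, n_boot = 0)$k_off, 10)

  # censored dwells add observation time but no event:
  # 10 x (100 ns event) + 10 x (100 ns censored) -> 10/2000 ns = 5 /us
  mix <- lipidex:::new_dwell_times(tibble::tibble(
    site_id = "s", duration_ns = rep(100, 20),
    censored = rep(c(FALSE, TRUE), 10)))
  expect_equal(estimate_koff(mix, n_boot = 0)$k_off, 5)

  few <- lipidex:::new_dwell_times(tibble::tibble(
    site_id = "s", duration_ns = rep(10, 9), censored = FALSE))
  expect_error(estimate_koff(few, n_boot = 0), class = "lipidex_error_input")

  # bootstrap CI brackets the point estimate and is seed-stable
  d <- simulate_dwell_times(10, 500, seed = 3)
  e1 <- estimate_koff(d, n_boot = 200, seed = 4)
  e2 <- estimate_koff(d, n_boot = 200, seed = 4)
  expect_identical(e1, e2)
  expect_lte(e1$ci_low, e1$k_off)
  expect_gte(e1$ci_high, e1$k_off)
})

test_that("the censoring-aware MLE avoids the drop-censored upward bias", {
  k_true <- 10
  full <- simulate_dwell_times(k_true, 4000, seed = 15)
  cutoff <- 150 # truncate long events as a trace end would
  trunc <- lipidex:::new_dwell_times(tibble::tibble(
    site_id = "s",
    duration_ns = pmin(full$duration_ns, cutoff),
    censored = full$duration_ns > cutoff
  ))
  n_unc <- sum(!trunc$censored)
  se <- k_true / sqrt(n_unc)

  k_mle <- estimate_koff(trunc, n_boot = 0)$k_off
  expect_lt(abs(k_mle - k_true), 2 * se)

  # the naive estimator (discard censored, invert the mean) is biased high
  k_naive <- oracle_mle_koff(trunc$duration_ns[!trunc$censored])
  expect_gt(k_naive - k_true, 2 * se)
})

test_that("log-survival slope agrees with the MLE on exponential dwells", {
  d <- simulate_dwell_times(32.5, 5000, seed = 12)
  k_mle <- estimate_koff(d, n_boot = 0)$k_off
  k_surv <- koff_from_survival(survival_curve(d))$k_off
  expect_lt(abs(k_surv - k_mle) / k_mle, 0.15)
})

test_that("site comparison orders by k_off and flags unresolved pairs", {
  est <- tibble::tibble(
    site_id = c("fast", "slow"), k_off = c(30, 10),
    ci_low = c(28, 9), ci_high = c(32, 11),
    n_events = c(100, 100), n_censored = c(0, 0),
    mean_dwell_ns = 1000 / c(30, 10), method = "mle_censored"
  )
  cmp <- compare_sites(est)
  expect_equal(cmp$sites$site_id, c("slow", "fast"))
  expect_equal(cmp$pairs$fold, 3)
  expect_false(cmp$pairs$ci_overlap)

  tie <- est
  tie$k_off <- c(10, 10)
  tie$ci_low <- c(9, 9)
  tie$ci_high <- c(11, 11)
  cmp2 <- compare_sites(tie)
  expect_equal(cmp2$pairs$fold, 1)
  expect_true(cmp2$pairs$ci_overlap)
})

test_that("occupancy and contact frequency count frames in contact", {
  expect_equal(site_occupancy(make_binary_trace(rep(1, 100)))$occupancy, 1)
  expect_equal(site_occupancy(make_binary_trace(rep_len(c(0, 1), 100)))$occupancy,
               0.5)

  contacts <- tibble::tibble(
    state = rep(c("inward", "outward"), each = 10),
    residue = "R24", frame = rep(1:10, 2),
    distance_nm = c(rep(0.4, 10), rep(1.2, 10))
  )
  prof <- contact_frequency(contacts, d_contact = 0.7)
  expect_equal(prof$contact_frequency[prof$state == "inward"], 1)
  expect_equal(prof$contact_frequency[prof$state == "outward"], 0)
  # absent cells stay absent, they are not reported as zero
  expect_equal(nrow(prof), 2)
  expect_false("inward-closed" %in% prof$state)
})
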