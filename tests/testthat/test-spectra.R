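gaussian_spectrum <- function(centres, heights = 1, sigma = 2,
                              mz = seq(900, 1100, 0.2)) {
  y <- rowSums(sapply(seq_along(centres), function(i) {
    rep(heights, length.out = length(centres))[i] *
      exp(-(mz - centres[i])^2 / (2 * sigma^2))
  }))
  mass_spectrum(mz, y)
}

test_that("pick_peaks finds isolated Gaussians and tolerates flat input", {
  s1 <- gaussian_spectrum(1000)
  pk1 <- pick_peaks(s1, min_spacing_mz = 2)
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$mz - 1000), 0.2)

  s2 <- gaussian_spectrum(c(980, 1020))
  expect_equal(nrow(pick_peaks(s2, min_spacing_mz = 2)), 2)

  flat <- mass_spectrum(seq(900, 1000, 0.5), rep(1, 201))
  expect_equal(nrow(pick_peaks(flat)), 0)

  # two apexes closer than min_spacing: the taller one wins
  s3 <- gaussian_spectrum(c(1000, 1004), heights = c(1, 0.6))
  pk3 <- pick_peaks(s3, min_spacing_mz = 10)
  expect_equal(nrow(pk3), 1)
  expect_lt(abs(pk3$mz - 1000), 0.5)
})

test_that("known compositions are assigned with correct counts", {
  protein <- protein_species("P33", 33000, 11, 11)
  pope <- formula_mass("C39H76NO8P")
  cands <- lipid_species("POPE", mass = pope, lipid_class = "PE")
  mz_apo <- (33000 + 11 * 1.00728) / 11
  peaks <- tibble::tibble(
    mz = c(mz_apo, mz_apo + pope / 11),
    intensity = c(1, 0.5), area = c(1, 0.5)
  )
  asg <- assign_adducts(peaks, protein, cands, max_adducts = 3,
                        tolerance_da = 2.5)
  expect_true(all(asg$assigned))
  expect_equal(asg$n_adducts, c(0, 1))
  expect_equal(asg$adduct_counts[[1]][["POPE"]], 0L)
  expect_equal(asg$adduct_counts[[2]][["POPE"]], 1L)
  expect_equal(asg$charge, c(11L, 11L))
  # intensity shares within the charge state sum to one
  expect_equal(sum(asg$intensity_share), 1, tolerance = 1e-9)
})

test_that("a CDL vs 2xPE mass collision is flagged and tie-broken to fewer adducts", {
  protein <- protein_species("P33", 33000, 11, 11)
  # construct the near-collision: 2 x 729.2 = 1458.4 vs CDL at 1458.0
  cands <- dplyr::bind_rows(
    lipid_species("PEx", mass = 729.2, lipid_class = "PE"),
    lipid_species("CDL", mass = 1458.0, lipid_class = "CDL")
  )
  peak_mass <- 33000 + 1458.3
  peaks <- tibble::tibble(mz = (peak_mass + 11 * 1.00728) / 11,
                          intensity = 1, area = 1)
  asg <- assign_adducts(peaks, protein, cands, max_adducts = 2,
                        tolerance_da = 2.5)
  expect_true(asg$ambiguous)
  expect_equal(asg$adduct_counts[[1]][["CDL"]], 1L)
  expect_equal(asg$adduct_counts[[1]][["PEx"]], 0L)
})

test_that("bound fractions follow intensity shares and rescale invariantly", {
  protein <- protein_species("P33", 33000, 11, 11)
  pope <- formula_mass("C39H76NO8P")
  cands <- lipid_species("POPE", mass = pope, lipid_class = "PE")
  mz_apo <- (33000 + 11 * 1.00728) / 11
  peaks <- tibble::tibble(mz = c(mz_apo, mz_apo + pope / 11),
                          intensity = c(1, 1), area = c(2, 2))
  asg <- assign_adducts(peaks, protein, cands, 2, 2.5)
  q <- quantify_bound_fractions(asg)
  any_frac <- q$fraction[q$lipid_class == "any"]
  expect_equal(any_frac, c(0.5, 0.5))

  # uniform intensity rescaling leaves fractions unchanged
  asg7 <- asg
  asg7$area <- asg7$area * 7
  asg7$intensity <- asg7$intensity * 7
  expect_equal(quantify_bound_fractions(asg7)$fraction, q$fraction)

  # apo only
  asg_apo <- assign_adducts(peaks[1, ], protein, cands, 2, 2.5)
  q_apo <- quantify_bound_fractions(asg_apo)
  expect_equal(q_apo$fraction[q_apo$lipid_class == "any"], 1)

  bad <- asg
  bad$assigned <- FALSE
  expect_error(quantify_bound_fractions(bad), class = "lipidex_error_input")
})

test_that("average charge is the intensity-weighted mean of z", {
  asg <- tibble::tibble(
    charge = c(13L, 14L, 15L), area = c(0.2, 0.6, 0.2),
    assigned = TRUE
  )
  expect_equal(average_charge(asg), 14)
  one <- tibble::tibble(charge = 14L, area = 1, assigned = TRUE)
  expect_equal(average_charge(one), 14)
  none <- tibble::tibble(charge = integer(), area = double(),
                         assigned = logical())
  expect_error(average_charge(none), class = "lipidex_error_input")
})

test_that("spectrum -> peaks -> assignment recovers generator stoichiometry", {
  fx <- single_lipid_fixture(noise_sd = 0)
  s <- simulate_spectrum(fx, 0)
  pk <- pick_peaks(s, min_spacing_mz = 5)
  cands <- lipid_species("POPE", mass = fx$lipids$mass, lipid_class = "PE")
  asg <- assign_adducts(pk, fx$protein, cands, max_adducts = 3,
                        tolerance_da = 2.5)
  q <- quantify_bound_fractions(asg) |>
    dplyr::filter(lipid_class == "POPE")
  truth <- tibble::tibble(n_bound = 0:3, prob = dbinom(0:3, 3, 0.5))
  expect_lt(tv_distance(q, truth), 0.05)
})

test_that("assignment is invariant to candidate order away from ties", {
  fx <- fixture_spectrum(load_fixture("psh_titration"))
  s <- simulate_spectrum(fx, 0.2, seed = 21)
  pk <- pick_peaks(s, min_snr = 3, min_spacing_mz = 2)
  cands <- dplyr::bind_rows(
    lipid_species("PE", mass = formula_mass("C39H76NO8P"), lipid_class = "PE"),
    lipid_species("PG", mass = formula_mass("C40H77O10P"), lipid_class = "PG"),
    lipid_species("CDL", mass = formula_mass("C81H150O17P2"), lipid_class = "CDL")
  )
  a1 <- assign_adducts(pk, fx$protein, cands, 3, 2.5)
  a2 <- assign_adducts(pk, fx$protein, cands[3:1, ], 3, 2.5)
  unam <- which(a1$assigned & !a1$ambiguous & a2$assigned & !a2$ambiguous)
  expect_gt(length(unam), 0)
  for (i in unam) {
    c1 <- a1$adduct_counts[[i]]
    c2 <- a2$adduct_counts[[i]][names(c1)]
    expect_identical(unname(c1), unname(c2))
  }
})

test_that("stepwise detergent removes all lipid adducts from the protease fixture", {
  fx <- fixture_spectrum(load_fixture("psh_titration"))
  cands <- lipidex:::fixture_candidates(fx)

  # at the base detergent concentration the principal charge state shows the
  # apo peak plus at least three adduct peaks
  s_low <- simulate_spectrum(fx, 0.2, seed = 31)
  a_low <- assign_adducts(pick_peaks(s_low, min_spacing_mz = 2), fx$protein,
                          cands, 3, 2.5)
  main_z <- a_low |>
    dplyr::filter(assigned, charge == 11L)
  expect_gte(nrow(main_z), 4)
  expect_gte(max(main_z$n_adducts), 3)

  # at the top of the titration, bound lipid falls below detection
  s_high <- simulate_spectrum(fx, 0.5, seed = 32)
  a_high <- assign_adducts(pick_peaks(s_high, min_spacing_mz = 2), fx$protein,
                           cands, 3, 2.5)
  q <- quantify_bound_fractions(a_high)
  bound_any <- sum(q$fraction[q$lipid_class == "any" & q$n_bound >= 1])
  expect_lt(bound_any, 0.03)
})

test_that("detergent-shifted envelopes raise the average charge", {
  fx <- fixture_spectrum(load_fixture("murj_lipid2"))
  cands <- lipidex:::fixture_candidates(fx)
  z_of <- function(D, seed) {
    s <- simulate_spectrum(fx, D, seed = seed)
    average_charge(assign_adducts(pick_peaks(s, min_spacing_mz = 3),
                                  fx$protein, cands, 5, 2.5))
  }
  expect_gt(z_of(0.5, 41), z_of(0, 42))
})
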