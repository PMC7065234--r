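# Shared builders and independent oracles for the test suite.

# Closed-form exponential MLE (uncensored), independent of estimate_koff():
# k_off in inverse microseconds from durations in ns.
oracle_mle_koff <- function(durations_ns) 1000 / mean(durations_ns)

# Total-variation distance between two count distributions aligned on n_bound.
tv_distance <- function(obs, truth) {
  n <- sort(union(obs$n_bound, truth$n_bound))
  p <- obs$fraction[match(n, obs$n_bound)]
  q <- truth$prob[match(n, truth$n_bound)]
  p[is.na(p)] <- 0
  q[is.na(q)] <- 0
  0.5 * sum(abs(p - q))
}

# Step-function read-off of a survival curve (right-continuous, as survfit).
survival_at <- function(curve, t) {
  stats::approx(curve$time_ns, curve$survival, xout = t,
                method = "constant", f = 0, rule = 2)$y
}

# One-lipid test fixture: 33 kDa protein, three equivalent POPE sites at
# half occupancy when detergent-free.
single_lipid_fixture <- function(noise_sd = 0, n_sites = 3, K_D = 0.05,
                                 fwhm = 4) {
  spectrum_fixture(
    protein = protein_species("P33", 33000, 10, 12),
    lipids = tibble::tibble(
      name = "POPE", mass = formula_mass("C39H76NO8P"), lipid_class = "PE",
      conc = 50, n_sites = n_sites, K_L = 50, K_D = K_D, protected = FALSE
    ),
    detergent = detergent_species("NG", 306.4, cmc = 0.1),
    envelope = list(center = 11, width = 0.7),
    peak_fwhm_mz = fwhm, noise_sd = noise_sd,
    mz_min = 2700, mz_max = 3600, mz_step = 0.25, seed = 7L
  )
}
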