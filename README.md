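# lipidex

Membrane proteins sit in a shell of *annular* lipids — non-specific contacts
that exchange rapidly with bulk lipid or detergent — while a few *non-annular*
lipids bind defined sites (oligomer interfaces, active sites) where they
exchange slowly and do functional work. Telling the two apart is hard.
`lipidex` implements, as a reusable and tested R pipeline, the computational
side of a strategy that distinguishes them by exchange:

* **Detergent-competition titrations read out by native MS.** A
  detergent-solubilized protein with added lipids shows ladders of lipid
  adducts on each charge state, peaks at `(M + Σ m_lipid + z·1.00728)/z`.
  Stepping up the detergent concentration strips exchangeable lipids; the
  package picks peaks, assigns per-charge-state adduct stoichiometries against
  a candidate lipid list, quantifies bound fractions, and fits a competitive
  displacement model

  θ(L, D) = (L/K_L) / (1 + L/K_L + max(0, D − cmc)/K_D),

  classifying each lipid class and each adduct position as annular (retention
  index R = θ(D_max)/θ(D_min) ≤ 0.5) or non-annular (R > 0.5). Protected
  sites (θ flat in D) are flagged rather than letting K_D diverge.

* **Per-site residence times and k_off from binding/contact traces.**
  Distance traces are binarized with a dual-cutoff (hysteresis) scheme (bind
  below `d_on`, release only above `d_off`), dwells are extracted with small
  unbound gaps merged ("rattling" absorption), trace-end dwells are flagged
  censored, and k_off is estimated by the censoring-aware exponential MLE

  k̂_off = n_uncensored / Σ t_i  (all durations, censored included),

  reported in μs⁻¹ with percentile-bootstrap confidence intervals, plus a
  log-survival-slope cross-check, site ordering and pairwise fold ratios.

* **Per-state residue accessibility.** Single-cutoff contact frequencies
  between a substrate lipid and named residues, per conformational state.

* **Seeded synthetic-data generators** for adduct spectra, titrations, and
  two-state (telegraph) binding traces with controllable rattling, so every
  stage of the analysis is testable without instrument or simulation data.
  Three packaged fixtures (`psh_titration`, `leut_cdl_sites`, `murj_lipid2`)
  emulate the three study systems.

The package is tidyverse-native: functions take data frames first and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and result types
have `autoplot()` methods.

## Worked example

Estimate k_off for a slow, interfacial-like site from simulated dwells:

```r
library(lipidex)
dwells <- simulate_dwell_times(k_off = 8, n_events = 2000, seed = 1)
estimate_koff(dwells, n_boot = 200, seed = 2)
#> # A tibble: 1 × 8
#>   site_id k_off ci_low ci_high n_events n_censored mean_dwell_ns method
#>   <chr>   <dbl>  <dbl>   <dbl>    <int>      <int>         <dbl> <chr>
#> 1 site     7.94   7.64    8.28     2000          0          126. mle_censored
```

The true rate (8 μs⁻¹, mean dwell 125 ns) is recovered as 7.94 μs⁻¹ with a
95 % bootstrap interval [7.64, 8.28].

Run the full competition pipeline on the flippase fixture — a 57 kDa protein
carrying one detergent-protected substrate lipid (lipid-II) in its active
site plus exchangeable annular copies and POPE, titrated with octylglucoside:

```r
report <- run_analysis(list(fixture = "murj_lipid2", seed = 7))
report$tables$positions
#> # A tibble: 5 × 6
#>   lipid_class position theta_low_d theta_high_d retention_index retained
#>   <chr>          <int>       <dbl>        <dbl>           <dbl> <lgl>
#> 1 lipid-II           1       0.984      0.924           0.938   TRUE
#> 2 lipid-II           2       0.788      0.00625         0.00793 FALSE
#> 3 lipid-II           3       0.312      0.00275         0.00880 FALSE
#> 4 PE                 1       0.824      0.0129          0.0157  FALSE
#> 5 PE                 2       0.195      0.0102          0.0521  FALSE
```

Exactly one lipid-II position keeps its occupancy at the top of the titration
(retention 0.94 → retained, non-annular); the additional lipid-II copies and
all POPE positions are stripped (retention ≈ 0 → annular). `report$tables`
also holds the per-class competition fits, classifications, average charge
per concentration, and the generator's ground truth for comparison.

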