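---
title: "Distinguishing annular from non-annular lipid binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing annular from non-annular lipid binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipidex)
```

`lipidex` quantifies how bound lipids exchange with detergent around
solubilized membrane proteins, and how long individual lipids reside at
defined binding sites. This vignette is the package's own account of the
models it implements, the parameters that matter, the numerical choices made
where the underlying experimental protocols leave them open, and what the
synthetic data used for testing does and does not establish.

## The measurement model: adduct ladders in native mass spectra

A folded membrane protein released from its micelle carries `z` protons and
appears at `(M + z·1.00728)/z`; each bound lipid adds its mass, so lipid
adducts form a ladder of peaks per charge state spaced by `m_lipid/z`.
The package works with average (not monoisotopic) masses throughout: at
33–57 kDa, intact-protein native MS resolves average masses only. Charging
is modelled for positive-ion mode with the proton mass 1.00728 Da.

Peak analysis is targeted: the protein mass and the candidate lipid list are
known, so `assign_adducts()` deconvolves each picked peak at every charge in
the protein's range and searches all compositions with up to `max_adducts`
lipids for the smallest absolute mass error. This is deliberately not a
blind charge-deconvolution: the experimental design always knows the protein
and the lipids that were added.

Numerical choices, all config-overridable:

* **Peak shape.** Gaussian with configurable FWHM (default 8 m/z). The
  peak-shape default makes a three-adduct ladder resolvable but overlapping;
  fixtures override it where their lipid sets demand more or less resolution
  (2 m/z for the protease fixture, whose PE and PG adducts sit 2.8 m/z apart
  at z = 11).
* **Quantification by area, not apex height.** Adduct shoulders overlap in
  realistic spectra; areas integrate between flanking minima and are robust
  to that.
* **Apex refinement.** Apexes are refined by three-point parabolic
  interpolation so that the deconvolved-mass error is not dominated by the
  m/z grid step (a 0.25 m/z quantization error is already 3.5 Da at z = 14).
* **Mass tolerance.** Default 2.5 Da at the deconvolved-mass scale — enough
  to separate PE (718.0) from PG (749.0) trivially while deliberately
  exposing the near-collision between one cardiolipin and two PEs, which is
  flagged ambiguous and resolved by the documented tie-break (fewer total
  adducts, then candidate order). Fixtures whose compositions are farther
  apart may widen it (the flippase fixture uses 8 Da, its nearest distinct
  compositions being 440 Da apart).
* **Detection threshold.** "All lipid removed" is operationalized as a bound
  intensity fraction below 0.03; some threshold is unavoidable to turn a
  qualitative statement into a testable one.
* **Noise floor.** The median absolute deviation of the profile intensity;
  peaks must exceed `min_snr` (default 3) times it. Spurious noise peaks are
  simply never assigned and therefore drop out of quantification.

## The competition model

The underlying experiments sketch, but never write down, a binding model.
The package adopts the minimal single-site competitive-Langmuir form
consistent with lipids and detergent competing for the protein surface:

$$\theta(L, D) = \frac{L/K_L}{1 + L/K_L + \max(0, D - \mathrm{cmc})/K_D}$$

with the lipid concentration $L$ fixed and known, $K_L$ the lipid
half-occupancy constant, and $K_D$ the detergent half-displacement constant.
Two structural choices deserve emphasis:

* **Detergent competes only above its CMC.** Monomeric detergent below the
  critical micelle concentration does not form the micellar phase that
  dilutes and displaces bound lipid, so the effective competitor is
  $D_{\mathrm{eff}} = \max(0, D - \mathrm{cmc})$. When a detergent is added
  on top of a second detergent already above its own CMC, mixed micelles
  exist from the first addition; the flippase fixture therefore assigns the
  titrated detergent a low effective CMC (0.02 % w/v) rather than its
  pure-water value (~0.53 % w/v for octylglucoside).
* **Protected sites are a flag, not a parameter limit.** A site the
  detergent cannot reach has $\theta$ independent of $D$; fitting would send
  $K_D \to \infty$. `fit_competition()` detects a flat series (spread below
  0.05 while binding stays above the detection threshold) and sets
  `protected = TRUE`, still recovering $K_L$ from
  $\theta = (L/K_L)/(1 + L/K_L)$.

Classification uses the retention index
$R = \theta(D_{\max})/\theta(D_{\min})$: `annular` if $R \le 0.5$,
`non-annular` otherwise. The midpoint threshold is the least presumptive
split of a qualitative removed-versus-retained contrast; it is exposed as
`r_threshold`. The model assumes equilibrium endpoints — whether slow
removal kinetics masquerade as retention cannot be decided from endpoint
spectra, and the package does not try. Lipid classes are fitted
independently; no joint multi-lipid model is defined.

Counting *how many* lipids of one class resist detergent uses per-position
retention (`retention_by_position()`): position $j$ of a class is occupied
with probability $P(\mathrm{count} \ge j)$, and its retention index is that
probability's ratio across the titration ends. On the flippase fixture this
counts exactly one retained lipid-II position.

## Residence times and k_off

Contact traces are reduced to dwell times in three steps, each addressing a
specific artifact:

1. **Dual-cutoff binarization** (`binarize_contacts()`): bound begins when
   the distance drops below `d_on` (default 0.55 nm), and ends only when it
   exceeds `d_off` (default 1.0 nm). The hysteresis band absorbs fast
   "rattling" excursions that would otherwise fragment one binding event
   into many. The defaults are typical coarse-grained lipid-contact values
   and are config-overridable, since the source protocols state none.
2. **Gap merging** (`extract_dwells()`): interior unbound gaps no longer
   than `gap_tolerance_ns` (default 5 ns) flanked by bound runs are merged.
   With rattle gaps of mean 2 ns, ~92 % of gaps fall under a 5 ns tolerance.
3. **Censoring flags**: dwells touching either trace end are only known to
   be *at least* their observed length.

The estimator is the censored exponential MLE,
$\hat k_{\mathrm{off}} = n_{\mathrm{unc}} / \sum_i t_i$ over all durations
(censored included), converted to μs⁻¹ via
$k_{\mathrm{off}} = 1000/\tau[\mathrm{ns}]$. Discarding censored dwells
instead would bias $\hat k$ upward, and the test suite checks both that the
implemented estimator is unbiased within two standard errors on truncated
fixtures and that the naive estimator is not. Uncertainty is a percentile
bootstrap over dwell resampling. A single-exponential model is the default
and only fitted form: per-site single rates are what the analysis reports.
As an independent cross-check, the negative slope of a linear fit to the log
Kaplan–Meier survival curve (`koff_from_survival()`) agrees with the MLE
within 15 % on exponential data. Dimer protomers are treated as independent
replicates and pooled per site after dwell extraction.

A documented limitation: gap merging cannot distinguish a rattle from a
genuine unbind-and-rebind when rebinding is much faster than the gap
tolerance. At a site with mean unbound period ~10 ns, a 5 ns tolerance
merges ~39 % of genuine gaps and fuses consecutive visits, deflating the
trace-derived $\hat k_{\mathrm{off}}$ while preserving site ordering and
fold separations. Per-visit rates at such high-occupancy sites should be
read as lower bounds; dwell-resolved estimates (from the dwell generator or
from traces of lower-occupancy sites) are unaffected.

## What the synthetic generators emulate — and what they do not

`simulate_dwell_times()` draws i.i.d. exponential dwells; dwell durations
are in ns, rates in μs⁻¹. `simulate_contact_trace()` realizes a
continuous-time two-state (telegraph) process with exponential sojourns,
stationary initial state, frame discretization at `dt_ns`, and optional
rattling: a Poisson process (rate `rattle_rate`) of short exponential gaps
(mean `rattle_mean`) carved out of bound periods. Its long-run occupancy is
$k_{on}/(k_{on}+k_{off})$ when rattling is off. `simulate_spectrum()` sums
Gaussian peaks whose areas are charge-envelope weight times
occupancy-model probability — per lipid site group, adduct counts are
Binomial(`n_sites`, θ) — plus seeded additive Gaussian noise relative to the
tallest point, clipped at zero. Site groups of one lipid (e.g. a protected
active-site copy and annular copies) convolve into the class-level count
distribution.

All generators are deterministic given a seed, and restore the caller's RNG
state.

The fixtures encode the study conditions: a 33 kDa protease with 50 μM mixed
PE/PG/CDL in an NG titration from 0.2 to 0.5 % w/v (all classes at
half-occupancy detergent-free, fully stripped at the top); a dimeric
transporter with three cardiolipin sites at true rates 8, 32.5 and
75 μs⁻¹ and two protomer replicates of 100 μs traces at 0.5 ns frames; a
57 kDa flippase with one protected lipid-II (occupancy 0.8), two annular
lipid-II sites, two annular PE sites, an OG titration from 0 to 0.5 % w/v
and an envelope that shifts up by 2 charges per % OG. Where the underlying
reports give no number (lipid site counts, K values, k_on, trace lengths,
noise levels), values were chosen once as field-plausible and are stated in
the fixture YAMLs, not tuned.

Passing tests on these fixtures establishes that the pipeline recovers what
its own model assumes: exponential dwells, binomial site occupancy, Gaussian
peaks, additive noise. They do not establish robustness to what real data
adds — micelle-hump backgrounds, charge-dependent adduct stripping,
isotope structure, multi-exponential dwells from heterogeneous sites, free
versus micelle-partitioned lipid pools (configured occupancy parameters are
effective values). Those are explicit non-goals.

## Problem sizes and determinism

The test suite and the acceptance script are sized for a single CPU: dwell
recovery at n = 2000 events across four rates with 200 replicates, bootstrap
coverage at n = 500 with 300 resamples and 200 replicates, titrations of six
spectra at ~5000–8400 grid points, and kinetics traces of 30–100 μs at 0.5 ns
frames. Every randomized step takes an explicit seed; reports embed a config
hash, the seed, and the package version, and rerunning a config reproduces
`report.json` byte for byte. Parameters left at their defaults are logged as
such, so every paper-gap default is visible in the output of each run.
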