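# Synthetic emulation of the LeuT cardiolipin site kinetics: three CDL-binding
# sites per protomer, each named by a pair of flanking residues. The
# interfacial R88/K376 site unbinds slowest (< 10 per-microsecond), the
# R453/R446 site at an intermediate rate, and the low-specificity R11/I441
# site fastest (> 70 per-microsecond). Both protomers of the dimer are
# independent replicates. Traces carry rattling (brief spurious detachments)
# that the dual-cutoff / gap-merge extraction must absorb.
name: leut_cdl_sites
analysis: kinetics
sites:
  - {site_id: "R88/K376", k_on: 100, k_off: 8}    # dimer interface
  - {site_id: "R453/R446", k_on: 30, k_off: 32.5}
  - {site_id: "R11/I441", k_on: 25, k_off: 75}    # little specificity
kinetics:
  n_protomers: 2
  duration_ns: 100000
  dt_ns: 0.5
  output: distance
  rattle_rate: 20
  rattle_mean: 1
  d_on: 0.55
  d_off: 1.0
  gap_tolerance_ns: 5
  n_boot: 500
  seed: 303
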