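# Synthetic emulation of the MurJ substrate-binding experiment: the 57 kDa
# E. coli lipid-II flippase with its substrate lipid-II (one protected
# active-site copy plus exchangeable annular copies) and POPE, titrated with
# octylglucoside on an LDAO background. OG is added to pre-existing LDAO
# micelles, so the competing detergent carries a low effective (mixed-micelle)
# CMC. Raising OG also shifts the charge-state envelope upward.
name: murj_lipid2
analysis: titration
protein:
  name: MurJ
  average_mass: 57000
  charge_min: 12
  charge_max: 17
detergent:
  name: OG (mixed with LDAO)
  average_mass: 292.37
  cmc: 0.02
envelope:
  center: 14
  width: 0.8
  charge_shift_per_percent: 2
spectrum:
  peak_fwhm_mz: 4
  noise_sd: 0.01
  mz_min: 3300
  mz_max: 5400
  mz_step: 0.25
  seed: 202
lipids:
  - name: lipid-II-site1      # active-site copy, unreachable by detergent
    formula: C94H156N8O26P2
    lipid_class: lipid-II
    conc: 20                  # micromolar, 2-fold excess over protein
    n_sites: 1
    K_L: 5
    protected: true
  - name: lipid-II-annular
    formula: C94H156N8O26P2
    lipid_class: lipid-II
    conc: 20
    n_sites: 2
    K_L: 13.3
    K_D: 0.004
    protected: false
  - name: POPE
    formula: C39H76NO8P
    lipid_class: PE
    conc: 50
    n_sites: 2
    K_L: 50
    K_D: 0.004
    protected: false
titration:
  detergent_concs: [0, 0.1, 0.2, 0.3, 0.4, 0.5]
analysis_params:
  # at z ~ 14-15 the default 2.5 Da tolerance asks for < 0.2 m/z apex
  # precision; the nearest distinct compositions here are 440 Da apart, so a
  # wider deconvolved-mass window is safe and keeps minor peaks assigned
  tolerance_da: 8
accessibility:
  # Per-conformational-state accessibility of key MurJ residues to the lipid
  # substrate's acyl chains (two-state contact traces per cell; occupancy is
  # the stationary contact fraction the generator targets).
  d_contact: 0.7
  dt_ns: 1
  duration_ns: 20000
  k_off_base: 50
  seed: 404
  cells:
    - {state: inward-open,     residue: F256, occupancy: 0.50}
    - {state: inward-occluded, residue: F256, occupancy: 0.48}
    - {state: inward-closed,   residue: F256, occupancy: 0.52}
    - {state: outward,         residue: F256, occupancy: 0.50}
    - {state: inward-open,     residue: R18,  occupancy: 0.05}
    - {state: inward-occluded, residue: R18,  occupancy: 0.04}
    - {state: inward-closed,   residue: R18,  occupancy: 0.00}
    - {state: outward,         residue: R18,  occupancy: 0.30}
    - {state: inward-open,     residue: R24,  occupancy: 0.04}
    - {state: inward-occluded, residue: R24,  occupancy: 0.03}
    - {state: inward-closed,   residue: R24,  occupancy: 0.00}
    - {state: outward,         residue: R24,  occupancy: 0.35}
    - {state: inward-open,     residue: R255, occupancy: 0.05}
    - {state: inward-occluded, residue: R255, occupancy: 0.03}
    - {state: inward-closed,   residue: R255, occupancy: 0.00}
    - {state: outward,         residue: R255, occupancy: 0.40}
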