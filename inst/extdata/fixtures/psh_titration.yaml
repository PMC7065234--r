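# Synthetic emulation of the PSH detergent-competition experiment: the 33 kDa
# presenilin-homologue protease with the three main E. coli polar lipids (PE,
# PG, CDL) in nonylglucoside; stepping NG from 0.2 to 0.5 % w/v strips all
# lipid adducts (annular, exchangeable binding).
name: psh_titration
analysis: titration
protein:
  name: PSH
  average_mass: 33000
  charge_min: 10
  charge_max: 13
detergent:
  name: NG
  average_mass: 306.4
  cmc: 0.2
envelope:
  center: 11.3
  width: 0.8
  charge_shift_per_percent: 0
spectrum:
  peak_fwhm_mz: 2
  noise_sd: 0.01
  mz_min: 2450
  mz_max: 3700
  mz_step: 0.25
  seed: 101
lipids:
  - name: POPE
    formula: C39H76NO8P
    lipid_class: PE
    conc: 50        # micromolar, total added E. coli polar lipid split by class
    n_sites: 1
    K_L: 50
    K_D: 0.002
    protected: false
  - name: POPG
    formula: C40H77O10P
    lipid_class: PG
    conc: 50
    n_sites: 1
    K_L: 50
    K_D: 0.002
    protected: false
  - name: CDL
    formula: C81H150O17P2
    lipid_class: CDL
    conc: 50
    n_sites: 1
    K_L: 50
    K_D: 0.002
    protected: false
titration:
  detergent_concs: [0.2, 0.26, 0.32, 0.38, 0.44, 0.5]
analysis_params:
  # PE and PG adducts sit only ~2.8 m/z apart at z = 11; the apex spacing
  # filter must not swallow one of them
  min_spacing_mz: 2
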