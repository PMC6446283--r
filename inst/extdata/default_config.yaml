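# Default compartment constants and acquisition parameters for cerebral
# sodium (23Na) quantification at 3 T.
#
# Times in ms; region concentrations in mmol/kg wet weight; reference
# concentration in mmol/L; sd = between-subject SD used by the cohort
# simulator. The reference T1 (35 ms) is an assumed value typical of aqueous
# NaCl phantoms at 3 T, not a measured constant. The reference concentration
# is derived: 0.6 % NaCl = 6 g/L / 58.44 g/mol = 102.67 mmol/L.

acquisition:
  tr_ms: 120.0
  te_ms: 0.2
  voxel_mm: 3.6
  flip_deg: 87.0

reference:
  t1_ms: 35.0          # assumption (not a literature value)
  t2_fast_ms: 7.15
  t2_slow_ms: 33.7
  weight_fast: 0.6
  weight_slow: 0.4
  concentration: 102.67

regions:
  GM:
    t1_ms: 29.0
    t2_fast_ms: 4.0
    t2_slow_ms: 29.0
    weight_fast: 0.6
    weight_slow: 0.4
    concentration: 51.5
    sd: 4.5
  WM:
    t1_ms: 29.0
    t2_fast_ms: 4.0
    t2_slow_ms: 29.0
    weight_fast: 0.6
    weight_slow: 0.4
    concentration: 40.9
    sd: 3.8
  HCN:
    t1_ms: 29.0
    t2_fast_ms: 4.0
    t2_slow_ms: 29.0
    weight_fast: 0.6
    weight_slow: 0.4
    concentration: 60.9
    sd: 8.1
  pons:
    t1_ms: 29.0
    t2_fast_ms: 4.0
    t2_slow_ms: 29.0
    weight_fast: 0.6
    weight_slow: 0.4
    concentration: 39.8
    sd: 5.3
  cerebellum:
    t1_ms: 29.0
    t2_fast_ms: 4.0
    t2_slow_ms: 29.0
    weight_fast: 0.6
    weight_slow: 0.4
    concentration: 40.1
    sd: 4.9
  CSF:
    t1_ms: 58.1
    t2_fast_ms: 55.0     # monoexponential: fast weight is zero
    t2_slow_ms: 55.0
    weight_fast: 0.0
    weight_slow: 1.0
    concentration: 102.1
    sd: 21.6
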