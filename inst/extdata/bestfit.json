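{
  "comment": "Best-fit biochemical constants for the reference construct (P70a-deGFP) in the all-E. coli TXTL system; units nM and s. k_mat is a placeholder in the physiological range, not a published constant.",
  "kcat_m": 0.065,
  "KM_70": 1,
  "K70": 0.26,
  "S70_total": 30,
  "E_total": 400,
  "kd_m": 6.6,
  "KM_m": 8000,
  "kcat_p": 0.006,
  "KM_R": 10,
  "R_total": 1100,
  "k_mat": 0.0012,
  "Cm": 10,
  "Cp": 2.5,
  "Lm": 750,
  "P70": 1
}
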