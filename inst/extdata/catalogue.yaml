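# Measured specific loss powers of ferrite nanoparticles (equal radius,
# r = 15 nm) under an AC field of amplitude 37.3 kA/m at 500 kHz, as
# reported by calorimetry in the hyperthermia literature. SLP in W/g.
nanoparticles:
- name: MnFe2O4
  core: MnFe2O4
  shell: ~
  H0_kA_m: 37.3
  f_kHz: 500.0
  slp_w_g: 411.0
- name: MnFe2O4@CoFe2O4
  core: MnFe2O4
  shell: CoFe2O4
  H0_kA_m: 37.3
  f_kHz: 500.0
  slp_w_g: 3034.0
- name: CoFe2O4@MnFe2O4
  core: CoFe2O4
  shell: MnFe2O4
  H0_kA_m: 37.3
  f_kHz: 500.0
  slp_w_g: 2274.12
- name: Zn0.4Co0.6Fe2O4@Zn0.4Mn0.6Fe2O4
  core: Zn0.4Co0.6Fe2O4
  shell: Zn0.4Mn0.6Fe2O4
  H0_kA_m: 37.3
  f_kHz: 500.0
  slp_w_g: 3866.0
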