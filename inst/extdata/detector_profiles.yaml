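# Characterization of the three Gd2O2S:Tb scintillator / CMOS detectors:
# sigma_lsf from tilted-slit MTF measurements (pixels), alpha/beta from
# flat-field noise-level-function fits (Poisson gain, Gaussian sd in ADU).
detector1:
  scintillator_um: 84
  pixel_um: 48
  matrix_px: [512, 1024]
  adc_bits: 12
  sigma_lsf: 1.79
  alpha: 0.37
  beta: 9.12
detector2:
  scintillator_um: 96
  pixel_um: 48
  matrix_px: [512, 1024]
  adc_bits: 12
  sigma_lsf: 2.61
  alpha: 0.29
  beta: 7.10
detector3:
  scintillator_um: 140
  pixel_um: 48
  matrix_px: [512, 1024]
  adc_bits: 12
  sigma_lsf: 5.13
  alpha: 0.08
  beta: 3.31
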