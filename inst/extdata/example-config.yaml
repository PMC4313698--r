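# Example ppsnet configuration: overrides are merged over network_params()
# defaults; unknown keys are rejected.
auditory:
  rf_sigma: 6
ms:
  tau: 40
synapses:
  wa_center: 57
noise:
  intensity_frac: 0.2
hebb:
  gamma_pot: 4.0e-4
  gamma_forget: 1.0e-6
protocol:
  n_presentations: 30
  duration: 300
seed: 1
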