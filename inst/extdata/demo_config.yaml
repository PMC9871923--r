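# Demonstration run: both pipeline arms on small synthetic scenes.
seed: 20
out_dir: campariq_demo
pc:
  n_cells: 80
  n_frames: 2
  wavelengths: [1000.0]
  events:
    power_mW: [100.0, 100.0]
    n_pulses: [40, 40]
    pulse_s: [1.0, 1.0]
    spot_mm: [7.0, 7.0]
dynamic:
  n_cells: 15
  fraction_tuned: 0.2
  response_amplitude: 0.105
  noise_sd: 0.02
  bleach_half_life_s: 2000
  gray_s: 4
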