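# Default run configuration. Values here are overridden by a user YAML
# and then by CLI flags.
segment_length: 300        # seconds per analysis window
fs: 250                    # Hz
seed: 1
log_level: info
filter:
  highpass: 5              # Hz, QRS-emphasis passband lower edge
  lowpass: 15              # Hz, upper edge
  mwi_window: 0.150        # s, moving-window integrator
detector:
  refractory: 0.200        # s
  searchback_factor: 1.66  # gap multiple triggering search-back
delineator:
  p_prominence: 0.025      # mV, minimum P prominence
  p_lowpass: 4.5           # Hz, P-search lowpass cutoff
features:
  p_band: perbeat          # perbeat | whole
  wavelet_levels: 5
optimizer:
  particles: 20
  iterations: 30
  folds: 3
  lambda_max: 1.0
  lambda_min: 0.5
  log10_lower: -3          # search bounds, log10(C) and log10(gamma)
  log10_upper: 4
digitizer:
  gamma: 0.5
  px_per_mm: 4
  mm_per_s: 25
  mm_per_mv: 10
  fs_out: 250
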