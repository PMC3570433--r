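# Example run configuration for `maci fit` / run_maci_o2pls().
# Values shown are the package defaults, except `levels`, set here for
# small (64 px) frames; keep 3 for typical 256-512 px captures.
wavelet:
  family: sym8
  levels: 2
  boundary_mode: symmetric
features:
  variance_fraction: 0.95
  max_n: 10000
  exclude_approx: false
o2pls:
  max_k: 5
  max_l: 3
  max_m: 3
  folds: 7
  threshold: 0.01
  center: true
  block_scaling: false
phases:
  window: 5
  min_separation: 0.25
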