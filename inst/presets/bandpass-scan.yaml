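# Base configuration for cut-off-frequency scans (100 agents per grid cell);
# use with: bactaxis.R scan --config bandpass-scan.yaml --param omega1 \
#   --values 0.005,0.01,0.02,0.05,0.1
controller:
  kind: band_pass
  A: 16.0
  omega1: 0.02
  omega2: 5.0
simulation:
  n_bacteria: 100
  duration: 1000
  seed: 1
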