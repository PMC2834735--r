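# Step-wise attractant removal applied to the reference band-pass controller;
# use with: bactaxis.R step --config step-removal.yaml --step -0.1 \
#   --duration 200 --dt 0.005
controller:
  kind: band_pass
  A: 16.0
  omega1: 0.02
  omega2: 5.0
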