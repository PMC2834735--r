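# Non-adaptive low-pass controller with high amplification and fast cut-off,
# same field and start point as the band-pass population run.
controller:
  kind: low_pass
  A: 64.0
  omega0: 5.0
simulation:
  n_bacteria: 100
  duration: 1000
  seed: 1
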