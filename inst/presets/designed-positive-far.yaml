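# Designed positive pathway started farther from the concentration crest;
# records positions for distribution-pattern plots.
controller:
  kind: pathway
  variant: positive
simulation:
  n_bacteria: 2000
  duration: 1000
  init_position: [3.5, 0.0]
  record_positions: true
  seed: 1
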