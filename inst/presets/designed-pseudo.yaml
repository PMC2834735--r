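# Designed three-molecule pseudo chemotaxis pathway simulated on the original
# (nonlinear) differential equations.
controller:
  kind: pathway
  variant: pseudo
simulation:
  n_bacteria: 1000
  duration: 1000
  seed: 1
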