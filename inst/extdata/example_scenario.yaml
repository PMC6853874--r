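# Example simulation scenario: a reporter population with expression-
# dependent survival, a brighter comparison genotype, and a non-fluorescent
# control.  Intensities are in arbitrary units (A.U.); `n` is events per
# population.
seed: 1
default_n: 30000
populations:
  wt:
    signal: {shape: 1.0, scale: 50.0}
    noise: {family: gamma, mean: 100.0, variance: 225.0}
    survival: {p0: 0.2, beta: 0.01}
  bright:
    signal: {shape: 0.4, scale: 400.0}
    noise: {family: gamma, mean: 100.0, variance: 225.0}
  control:
    signal: {shape: 0.001, scale: 0.001}
    noise: {family: gamma, mean: 100.0, variance: 225.0}
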