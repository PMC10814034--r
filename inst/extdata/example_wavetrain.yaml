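# Four-wave increasing wavetrain on the canonical parameters: each wave is
# spliced at 1.5x its own peak time, while its spreader count still exceeds
# the count it started from.
"N": 10000000
I0: 1
segments:
  tau: [0.00825, 0.00825, 0.00825, 0.00825]
  rho: [0.00775, 0.00775, 0.00775, 0.00775]
  peak_fraction: [1.5, 1.5, 1.5, 1.5]
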