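# Quadratic news-wave scenario: one initial spreader in a population of
# ten million. Time is in abstract units; rates are per time unit.
name: example_basic
model: m2
"N": 10000000
S0: 9999999
tau: 0.00825
rho: 0.00775
t_end: 70000
n_points: 1001
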