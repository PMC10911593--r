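# SYNTHETIC placement-dependence scenario (geometry and capacities chosen
# by this package, not taken from a published table): a small habitat
# flanked by two large ones at 150 m gaps.  A release of 200 carriers into
# the small middle habitat fails everywhere; the same release into a large
# habitat fixes all three.
model: model1
note: "synthetic release-placement scenario: small habitat flanked by large ones"
params: {b_I: 0.45, b_U: 0.55, delta_I: 0.05, delta_U: 0.048}
habitats: {K: [400, 100, 400]}
migration:
  kernel: {family: exponential, xi: 75, t: 5, q: 0.8}
  positions: [0, 150, 300]
initial: {x0: [200, 0, 0], y0: [400, 100, 400]}
experiment: {driver: run, controls: {horizon: 10000}}
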