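# Two habitats initialised exactly on the critical non-carrier/carrier
# ratio 12.0435; the ratios stay constant and the trajectory rides the
# stable manifold of a four-way coexistence state.
model: model1
note: "two-habitat ratio-invariance demo (stable-manifold initial data)"
params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071}
habitats: {K: [400, 500]}
migration: {m: 0.001}
initial: {x0: [33.213, 41.516], y0: [400, 500]}
experiment: {driver: run, controls: {horizon: 200}}
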