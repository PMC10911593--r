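# Two-habitat basin mapping: baseline rates, capacities 400/600, m = 0.006.
# Minimal single-habitat releases: 51 (habitat A), 60 (habitat B).
model: model1
note: "two-habitat basin-of-attraction scenario"
params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071}
habitats: {K: [400, 600]}
migration: {m: 0.006}
initial: {x0: [0, 0], y0: [400, 600]}
experiment: {driver: basin, controls: {x_A_grid: [0, 10, 20, 30, 40, 50, 60], horizon: 4000}}
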