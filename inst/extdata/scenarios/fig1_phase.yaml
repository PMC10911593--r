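# Single-habitat phase-portrait parameter set; bistable with separatrix
# slope 4.392.
model: model1
note: "single-habitat two-compartment demo (phase portrait parameters)"
params: {b_I: 0.45, b_U: 0.55, delta_I: 0.05, delta_U: 0.048}
habitats: {d: [0.001]}
initial: {x0: [100], y0: [100]}
experiment: {driver: run, controls: {horizon: 2000}}
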