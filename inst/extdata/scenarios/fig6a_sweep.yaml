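# Migration sweep with directly specified unequal death rates: steady
# carrier populations of the two habitats coalesce as m grows.
model: model1
note: "migration sweep, coalescing steady states"
params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071}
habitats: {d: [0.001, 0.0015]}
initial: {x0: [100, 0], y0: [0, 100]}
experiment: {driver: sweep, controls: {m_grid: [0.001, 0.005, 0.01, 0.02, 0.05, 0.1], horizon: 6000}}
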