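# Migration sweep with equal death rates: an all-positive coexistence
# state exists for small m and disappears in a bifurcation near m = 0.0128,
# beyond which carriers fix in both habitats.
model: model1
note: "migration sweep, coexistence-loss bifurcation"
params: {b_I: 0.42, b_U: 0.57, delta_I: 0.05, delta_U: 0.048}
habitats: {d: [0.001, 0.001]}
initial: {x0: [100, 0], y0: [0, 100]}
experiment: {driver: sweep, controls: {m_grid: [0.005, 0.01, 0.015, 0.02], horizon: 6000}}
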