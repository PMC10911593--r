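# One-dimensional reaction-diffusion adaptation: a Gaussian carrier pulse
# of amplitude 40 over a non-carrier background of 200 elicits a traveling
# invasion wave; sufficiently reduced amplitude does not.
model: pde
note: "1-D traveling invasion wave (baseline rates, d = 0.001)"
params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071, d: 0.001}
grid: {extent: [-10, 30], nodes: 200, D: 0.01, bc: reflect}
experiment: {driver: run, controls: {x_amplitude: 40, y_level: 200, horizon: 2000, snapshots: 41}}
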