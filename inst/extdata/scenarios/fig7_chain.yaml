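# Three collinear equal habitats with gaps 200 and 400 m; migration from
# the exponential kernel (xi = 75 m, q = 0.8, t = 5 d).  A release of 150
# carriers in the leftmost habitat fixes habitats 1-2; habitat 3 is too far.
model: model1
note: "three-habitat chain: spread stalls at the distant habitat"
params: {b_I: 0.45, b_U: 0.55, delta_I: 0.05, delta_U: 0.048}
habitats: {K: [300, 300, 300]}
migration:
  kernel: {family: exponential, xi: 75, t: 5, q: 0.8}
  positions: [0, 200, 600]
initial: {x0: [150, 0, 0], y0: [300, 300, 300]}
experiment: {driver: run, controls: {horizon: 4000}}
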