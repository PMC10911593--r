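# Two-habitat nine-compartment model, baseline rates with reduced carrier
# fecundity (phi_w = 11): habitat B's steady carrier proportion jumps
# across 0.5 at a critical m slightly below 0.002.
model: model2
note: "nine-compartment migration sweep (habitat-B fixation threshold)"
params: {b_f: 0.5, b_m: 0.5, sigma: 1.0, phi_u: 13, phi_w: 11,
         v_u: 0.05, v_w: 0.95, psi: 0.114, mu_a: 0.02, mu_fu: 0.0571,
         mu_fw: 0.0633, mu_mu: 0.0952, mu_mw: 0.0952, K: 2.0e+5}
initial:
  A: [200, 300, 300, 500, 100, 100, 400, 0, 0]
  B: [200, 0, 800, 0, 100, 0, 400, 0, 0]
experiment: {driver: sweep, controls: {m_grid: [0.0005, 0.001, 0.0015, 0.002, 0.0025, 0.003], horizon: 2500}}
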