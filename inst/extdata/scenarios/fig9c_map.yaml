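# Outcome trichotomy over (release size, m) for a half-female, half-male
# carrier release into habitat A.
model: model2
note: "nine-compartment release-size x migration outcome map"
params: {b_f: 0.5, b_m: 0.5, sigma: 1.0, phi_u: 13, phi_w: 11,
         v_u: 0.05, v_w: 0.95, psi: 0.114, mu_a: 0.02, mu_fu: 0.0571,
         mu_fw: 0.0633, mu_mu: 0.0952, mu_mw: 0.0952, K: 2.0e+5}
initial:
  A: [200, 0, 10, 0, 10, 0, 20, 0, 0]
  B: [200, 0, 10, 0, 10, 0, 20, 0, 0]
experiment: {driver: release_map, controls: {release_grid: [10, 100, 1000, 10000], m_grid: [0.0005, 0.005], horizon: 2500}}
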