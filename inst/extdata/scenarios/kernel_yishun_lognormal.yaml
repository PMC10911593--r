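# Log-normal dispersal kernel, Yishun MRR estimates (xi = 45.2 m,
# sigma = 74.4 m over 7 days).
model: kernel
note: "Yishun log-normal kernel migration estimates"
kernel: {family: lognormal, xi: 45.2, sigma: 74.4, t: 7, q: 0.95}
experiment: {driver: migration, controls: {distances: [100, 150, 200, 250]}}
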