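# Exponential dispersal kernel fitted to Tampines (Singapore) MRR data:
# mean distance traveled 45.2 m over 7 days; habitat radius encloses 95%.
model: kernel
note: "Tampines exponential kernel migration estimates"
kernel: {family: exponential, xi: 45.2, t: 7, q: 0.95}
experiment: {driver: migration, controls: {distances: [100, 150, 200, 250]}}
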