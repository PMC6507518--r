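K: 200
nk_range: [1, 49]
beta: [12, 15]
sigma0: 8
sigma1: 8
rho: 0.3
sigma_eps: 35
r0: 0.4
r1: -0.4
p: 0.3
violation_frac: 0.80
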