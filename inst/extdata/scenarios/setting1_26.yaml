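K: 150
nk_range: [1, 19]
beta: [35, 40]
sigma0: 8
sigma1: 8
rho: 0.8
sigma_eps: 45
r0: 0.4
r1: 0.4
p: 0.3
violation_frac: 0.26
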