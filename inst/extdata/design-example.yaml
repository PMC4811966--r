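# One cell of the simulated-genotype study grid: 50 SNPs at MAF 5% in
# moderate LD, five causal SNPs sharing a total marginal variance of 0.30,
# 50% zero inflation, NB dispersion 1.
n: 500
k: 50
maf: 0.05
rho: 0.5
causal_idx: [1, 11, 21, 31, 41]
h_total: 0.30
zero_inflation: 0.5
theta: 1
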