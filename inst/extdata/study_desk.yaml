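# Desk-scale study grid for `mbmdr study`: both epistasis models at one
# MAF, two genetic variances, plus both null scenarios, with reduced
# breadth (20 SNPs, 25 replicates, B = 199).  The full-scale study uses
# the defaults (snps: 100, replicates: 500, perms: 999) over mafs
# [0.1, 0.25, 0.5] and g2s [0.01, 0.02, 0.03, 0.05, 0.1].
scenarios: [alternative, H01, H02]
models: [M27, M170]
mafs: [0.25]
g2s: [0.05, 0.1]
snps: 20
replicates: 25
perms: 199
seed: 1
adjust: on_the_fly
selector: pair_always
coding: codominant
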