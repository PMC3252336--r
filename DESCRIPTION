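Package: mbmdrq
Title: Model-Based Multifactor Dimensionality Reduction for
    Quantitative-Trait Epistasis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide two-locus epistasis screening for quantitative
    traits with Model-Based Multifactor Dimensionality Reduction (MB-MDR):
    cell-wise High/Low/No-evidence labelling of the nine two-locus genotype
    cells, pooled-construct association testing, and step-down maxT
    permutation control of the familywise error rate.  Implements
    lower-order (main) effect adjustment strategies -- residual-based
    screening (maxT-selected, alpha-selected, top-K, and stepwise-AIC
    regression) and on-the-fly Wald-test adjustment inside the MB-MDR
    steps -- under additive or codominant genotype coding.  Ships a
    two-locus quantitative-trait simulator (binary-mean epistasis models
    M27 and M170 with additive and over-dominant main-effect loci under
    Hardy-Weinberg and linkage equilibrium), the analytic
    additive/dominance/epistasis variance decomposition, and an evaluation
    layer for power, familywise error and false-positive rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
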