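---
title: "MB-MDR for quantitative traits: model, adjustment strategies, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MB-MDR for quantitative traits: model, adjustment strategies, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbmdrq)
```

## The statistical model

For a quantitative trait $Y$ measured on $n$ unrelated individuals and a
pair of bi-allelic SNPs with genotypes $g_a, g_b \in \{0,1,2\}$
(minor-allele counts), MB-MDR reduces the $3 \times 3$ genotype table to
a one-dimensional construct in three steps.

**Step 1 — cell association tests.** Each cell
$c = 3 g_a + g_b \in \{0, \dots, 8\}$ with at least `min_cell` members
(and at least `min_cell` members outside it) is compared with the pooled
remaining sample.  Without main-effect adjustment this is the classical
pooled-variance Student $t$-test with $n - 2$ degrees of freedom.  With
on-the-fly adjustment the comparison becomes the Wald $t$-test of the
cell indicator in the ordinary least-squares model
$$Y = \beta_0 + X_{\text{adj}}\gamma + \beta\,\mathbf{1}(c) + \varepsilon,$$
where $X_{\text{adj}}$ holds the coded genotype columns being adjusted
for; its degrees of freedom are $n - q - 2$ for a rank-$q$ adjustment.
Both tests are homoskedastic by construction, so the unadjusted test is
exactly the $q = 0$ special case — internal consistency that matters
when policies are compared.

**Step 2 — labels and the pair statistic.** Cells with two-sided
$p < \alpha_1$ are labelled `H` (positive statistic) or `L` (negative);
everything else — non-significant, undersized, or untestable because the
indicator is collinear with the adjustment columns — is `O`.  The pooled
`H` cells are then tested against all other samples, likewise the pooled
`L` cells, with the same test family, and the pair statistic is
$T = \max(T_H, T_L, 0)$, where a missing side contributes 0.  Only the
H/L/O sets enter $T$, so it is invariant under any relabelling of cell
indices that preserves them.

**Step 3 — step-down maxT.** The trait vector is permuted as a whole $B$
times; each permutation re-runs steps 1–2 for every pair (adjustment
designs are fixed functions of the genotypes and are re-resolved
identically).  Pairs are ranked by decreasing observed $T$ (ties broken
by pair order, for reproducibility); successive maxima are taken from the
bottom of the ranking upward; the adjusted p-value at rank $i$ is
$(1 + \#\{b : u_i^b \ge T_{(i)}\})/(B+1)$, with monotonicity enforced
down the ranking.  The smallest attainable value is $1/(B+1)$.  A pair is
reported significant when its adjusted p-value is at most $0.05$.

The single-locus variant (`mbmdr_1d()`) applies the identical machinery
to the 3 one-locus genotype cells of each SNP.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha1` | 0.1 | step-1 cell labelling level; looser than 0.05 so that moderately informative cells still enter the pooled construct |
| `min_cell` | 10 | smallest testable cell (dimensionless count). The threshold behind "insufficient sample size" is a package choice, exposed as a setting, since a universal value cannot be justified; 10 keeps the $t$ approximation serviceable at $n = 2000$ while discarding cells whose means are noise |
| `perms` (`B`) | 999 | maxT permutations; p-value resolution $1/(B+1)$. Desk-scale studies in the tests use 199, which still resolves the 0.05 threshold comfortably |
| `seed` | 1 | master seed; every permutation, replicate and screening step derives an independent sub-seed from (seed, purpose, index), so any component is reproducible in isolation |

## Main-effect adjustment

A SNP with a genuine main effect inflates the pair statistics of every
pair containing it (and, through chance correlations, pairs around it):
interaction findings may be a signal boost of lower-order effects rather
than epistasis.  Two families of corrections are provided.

**Residual-based** (`adjustment_policy("residual", ...)`): select SNPs by
single-SNP regression with step-down maxT (`sr_perm`), by raw $p < 0.05$
(`sr_alpha`), by the $K$ smallest raw p-values (`sr_topk`), or by
bidirectional stepwise AIC over SNP blocks (`mr_aic`); regress the trait
on the selected coded columns; scan the residuals as the new trait.  If
nothing is selected the original trait is scanned.

**On-the-fly** (`adjustment_policy("on_the_fly", ...)`): adjustment
columns enter the step-1/2 regressions directly.  `pair_always` adjusts
for both SNPs of the pair under investigation, whether or not they have
main effects; `one_d_significant` and `list_significant` adjust only for
pair members flagged by a prior single-locus MB-MDR or single-SNP
regression screen, so none, one, or both SNPs of a pair may be adjusted.

**Coding matters.**  Additive coding (one column, the allele count)
removes only the best linear-in-allele-count part of a main effect; an
over-dominant locus — heterozygote mean above both homozygote means —
keeps its dominance component, which then surfaces as spurious
"interactions" involving that locus.  Codominant coding (indicators for
heterozygote and minor homozygote) spans the full genotype factor and
removes the main effect entirely.  The package's evaluation layer
reproduces this contrast: under a null with an over-dominant locus,
on-the-fly additive adjustment leaves the (SNP3, SNP4) pair firing in
over half the replicates, codominant adjustment in essentially none.

## The simulator

`simulate_replicate()` emulates a specific two-locus study design:

* $m$ SNPs (default 100), independent draws from Hardy–Weinberg genotype
  frequencies — linkage equilibrium is implemented as independence.
* SNP1/SNP2: the functional pair at shared MAF $p$, with binary
  genotypic mean pattern M27 ($\mu_H$ iff $\ge 1$ minor allele at both
  loci) or M170 ($\mu_H$ iff exactly one locus heterozygous), scaled by
  $d = \sqrt{g^2 / \mathrm{Var}(\text{pattern})}$ so the two-locus
  genetic variance is exactly $g^2$; $\mu_L = 0$ without loss of
  generality.
* SNP3 (additive, $\beta_3 g_3$) and SNP4 (over-dominant,
  $\beta_4 \mathbf{1}(g_4 = 1)$) with variances
  $\sigma_3^2, \sigma_4^2 \sim U(0, 0.06)$; effect sizes are scaled so
  each locus contributes its drawn variance exactly given its MAF.
  Their MAFs are drawn per replicate from $U(0.05, 0.5)$, the same law
  as the noise SNPs, since the design does not pin them down; both are
  exposed as configuration fields.  $\sigma_3^2$ and $\sigma_4^2$ are
  drawn independently; the environmental variance
  $\sigma_e^2 = 1 - g^2 - \sigma_3^2 - \sigma_4^2$ then fixes the total
  phenotypic variance at 1.
* Null scenarios: `H01` keeps only the SNP3/SNP4 main effects
  ($d = 0$); `H02` has no genetic contribution at all
  ($\sigma_e^2 = 1$).

Per-replicate sub-seeds make every replicate reproducible in isolation;
noise-SNP MAFs are redrawn per replicate (a fixed-per-setting draw is the
other defensible reading; redrawing averages over marker-frequency
configurations and was chosen once).

What the generator does *not* emulate: linkage disequilibrium between
markers, genotyping error, missingness, population structure, covariates.
Passing tests therefore demonstrate calibration and power under idealised
marker independence, not robustness to the correlation structure of real
genotype panels.

`variance_components()` decomposes any such model analytically: with HWE
cell probabilities $f_i f_j$, the total genetic variance is the variance
of the cell means; each locus's main-effect variance is the variance of
its marginal conditional means; the additive part is the squared
frequency-weighted covariance of the marginal means with allele count
divided by the allele-count variance (the frequency-weighted
least-squares line); dominance is the remainder, epistasis the residual
of the two-locus variance.  For M170 at $p = 0.5$ the marginal means are
constant, so the main-effects variance is exactly zero and the
additive/dominance shares of it are undefined; the function returns `NaN`
for those two ratios with `degenerate` diagnostics rather than a
conventional value.

```{r}
variance_components("M170", 0.25)
```

## Numerical choices and degenerate inputs

* All step-1/2 tests are computed from sufficient statistics (cell
  counts, cell trait sums, global sums; for adjusted tests, cell
  indicators residualised against each pair's fixed design and their
  Gram matrix).  This makes a full scan one matrix product per permuted
  trait and is exactly — to $10^{-10}$, enforced by tests — the per-pair
  computation.
* Zero residual variance in a split (e.g. a two-point trait split
  perfectly by a cell) yields statistic $\pm\infty$ and $p = 0$ by
  convention, with a warning in the scalar API; if additionally the two
  group means coincide the statistic is 0 and $p = 1$ (no evidence).
* An indicator collinear with the adjustment design (squared residual
  norm below $10^{-10}$) is untestable: the cell is labelled `O`; a
  pooled H/L group whose indicator is collinear contributes 0.
* Rank-deficient residualisation designs are handled by pivoting with a
  warning; monomorphic SNPs are excluded from stepwise AIC scope and
  carry $F = 0$, $p = 1$ in single-SNP scans.
* maxT ties in the observed ranking are broken by pair order (stable
  sort); permutation-vs-observed comparisons use `>=`, making the
  estimator valid with the $+1/(B+1)$ convention.

## Design decisions taken where the design was open

* **Step-down rather than single-step maxT** for the pair scan, matching
  the free step-down form used for the single-locus scan.  The two agree
  on the top-ranked pair, which drives familywise error; step-down is
  uniformly more powerful further down the ranking.
* **Pooled-variance (classical) Student tests, not Welch**: the Wald
  analogue under OLS is homoskedastic, and adjusted and unadjusted
  policies should differ only by the adjustment columns.
* **Stepwise AIC steps whole SNP blocks** (a codominant SNP enters or
  leaves with both columns, as a factor term) starting from the
  intercept-only model with moves in both directions; the start model is
  exposed as an option (`start = "full"`).  Column-wise stepping would
  allow half-adjusted SNPs, which no coding scheme contemplates.
* **Selection screens use the same coding as the adjustment** under
  evaluation, so each policy is internally coherent.
* **The `sr_perm` screen permutes the single-SNP $F$ statistics** through
  the same maxT machinery; permutation calibrates the null, so mixing
  1-df and 2-df statistics across SNPs is legitimate.
* **Significant sets for `one_d_significant`/`list_significant` are
  computed once per dataset** on the observed trait and held fixed
  across maxT permutations, keeping per-pair adjustment designs fixed
  functions of the genotypes.  The per-pair null hypotheses then differ
  across pairs — the known conceptual weakness of these two policies,
  reproduced rather than repaired.
* **Missing genotypes are rejected, not imputed**: simulated data are
  complete and silent imputation would contaminate the test statistics.

## Desk-scale study sizes

The bundled studies (tests and `scripts/acceptance.R`) run the full
pipeline at reduced breadth: 20–50 SNPs, 50–300 replicates, $B = 199$,
always at the design's $n = 2000$.  Breadth scales the number of pairs
and hence the maxT threshold, not the per-pair sampling distribution, so
calibration (familywise error within Bradley's liberal interval
$(0.025, 0.075)$), severe inflation without adjustment under `H01`, the
additive/codominant contrast of `pair_always` adjustment, and
near-complete power for $g^2 = 0.1$ all reproduce at this scale.
Full-breadth runs (100 SNPs, 500 replicates, $B = 999$ per setting, 36
settings) use the identical code path via `mbmdr study --config` and are
a cluster-scale undertaking.

## Known limitations

* Interactions of order three and higher are out of scope, as are
  dichotomous traits, family designs, and gene–environment interaction.
* The 2-parameter $(-1, 0, 1)/(-\tfrac12, \tfrac12, -\tfrac12)$ genotype
  coding, attractive because it is invariant to allele-label choice, is
  not implemented.
* No covariates other than SNP main effects can be adjusted for.
* maxT assumes a common null across hypotheses; for the
  `one_d_significant` and `list_significant` policies this assumption is
  structurally violated (see above), and their error control is
  correspondingly poor — a property of the methods, faithfully
  reproduced.
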