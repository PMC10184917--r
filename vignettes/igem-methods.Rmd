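---
title: "Geneset-embedded joint NMF: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geneset-embedded joint NMF: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igem)
```

## The model

Two omic views are measured on the same subjects: a strictly positive
expression matrix `X1` (subjects × genes) and a methylation beta-value
matrix `X2` (subjects × CpGs), both preprocessed to non-negative,
mean-normalized form. The factorization shares one subject loading matrix
`W` (subjects × K) across views,

$$X_1 \approx W H_1, \qquad X_2 \approx W H_2, \qquad H_1 = \alpha\rho,$$

and constrains the gene basis through a *fixed* geneset design $\rho$
(genesets × genes, each row normalized to unit mass over its member genes).
The free parameters are $W$, the topic–geneset score matrix $\alpha$
(topics × genesets) and the CpG basis $H_2$; $H_1$ is always the product
$\alpha\rho$ and never free. Each latent *topic* is therefore a
non-negative combination of genesets, which is what makes the topics
directly interpretable: a topic's content is read off the largest entries
of $\alpha$ and of $H_1$, not recovered post hoc by enrichment.

The objective is

$$L = \lVert X_1 - W\alpha\rho\rVert_F^2 + \lVert X_2 - W H_2\rVert_F^2
  + \lambda_{net}\sum_{g,c} B_{gc}\sum_k (H_{1,kg}-H_{2,kc})^2
  + \lambda_W \Sigma W + \lambda_\alpha \Sigma\alpha + \lambda_H \Sigma H_2$$

with all factors elementwise non-negative. The graph term couples the two
bases through the interaction graph `B` (genes × CpGs): an edge says the
gene's expression and the CpG's methylation were correlated in cis, and the
penalty pulls their per-topic basis scores together. We use the symmetric
squared-difference form because it is bounded below, standard in
graph-regularized NMF, and decomposes as
$\sum_k H_1 D_g H_1^\top + H_2 D_c H_2^\top - 2 H_1 B H_2^\top$ with the
degree matrices $D_g = \mathrm{diag}(B\mathbf{1})$,
$D_c = \mathrm{diag}(B^\top\mathbf{1})$, which yields clean multiplicative
updates. The L1 terms (plain entry sums, since everything is non-negative)
encourage sparse loadings.

## Optimization

`igem()` runs blockwise multiplicative updates in the order
`W → α → H2`, recomputing `H1 = αρ` immediately after the `α` step so every
block always sees the freshest coupled state. Each update multiplies the
current block by the ratio of the negative to the positive part of its
gradient; the L1 weights enter the denominators as $\lambda/2$, which is
exactly the gradient of $\lambda\,\Sigma$ under the factor-2 convention of
the squared-error terms (verified against central finite differences to
better than 1e-8 relative in the test suite). Numerical choices:

* **ε guard** `1e-12` added to every denominator; division never produces
  non-finite values on valid input, and any NaN/Inf in a block aborts with
  a message naming the block.
* **Convergence** on relative objective change, default `rel_tol = 1e-6`,
  `max_iter = 2000`.
* **Restarts**: `n_restarts` random initializations; the restart with the
  lowest final objective is returned. Restart seeds derive from the master
  seed, so a fit is bit-reproducible.
* **Initialization**: entries uniform on (0.1, 1.1), rescaled by
  $\sqrt{\bar X / K}$ (and, for $\alpha$, divided by the mean column mass
  of $\rho$) so the initial reconstruction is on the data's scale; an
  SVD-based (`"nndsvd"`) deterministic option exists.
* **Monotonicity** is a property of these updates in practice rather than
  a theorem we rely on: the suite verifies non-increase within 1e-9
  relative over thousands of iterations across penalty settings,
  including all-zero penalties where the updates reduce exactly to the
  two-view Lee–Seung rules.

`K` (default 10) is a modeling choice; `igem_rank_scan()` reports, per
candidate K, the best objective, per-view reconstruction errors and the
restart dispersion to support an elbow choice. No automatic selection is
performed — with nested models the objective is non-increasing in K, so a
minimum would be meaningless.

The λ weights default to 1 (and are worth lowering, e.g. to 0.1–0.5, on
mean-normalized desk-scale data where the squared-error terms are small);
they are not calibrated to any external dataset.

## The preprocessing pipeline

The model-ready matrices are produced by five documented steps, each with
its threshold exposed in the run configuration (defaults in parentheses):

1. **Differential expression** (p ≤ 0.05): Welch t-test per gene between
   responders and non-responders on log expression. This is a deliberate,
   documented stand-in for a count-model fit: the package ingests
   already-normalized matrices, only the pass/fail gate feeds downstream,
   and precomputed p-values can be supplied instead. A gene must also
   belong to at least one geneset — genes outside the geneset universe
   cannot enter the geneset-embedded factorization.
2. **Differential methylation** (|Δβ| ≥ 0.025, window 500 kb): group mean
   beta difference at or above threshold *and* proximity to a selected
   gene. We read the threshold as inclusive (≥); a p-value gate exists but
   is off by default, since the beta-difference criterion is the operative
   filter.
3. **Geneset merging** (≥ 80 % of the smaller and ≥ 50 % of the larger set
   overlapping): pairs meeting the rule are replaced by their union until a
   fixed point. The published wording of the two fractions is ambiguous —
   read literally, a 50 % condition on the smaller set is vacuous whenever
   the 80 % condition on the larger holds — so the package defaults to the
   only non-degenerate reading (strong condition on the smaller set) and
   exposes both fractions as arguments. Pairs are scanned in lexicographic
   id order and the surviving set keeps the smaller id, making the result
   deterministic and idempotent.
4. **ρ construction**: membership restricted to selected genes, rows
   renormalized to sum to one; emptied genesets are dropped and logged.
5. **Interaction graph** (top 10 pairs, p < 0.05, window 500 kb): per gene,
   Pearson correlation against every proximal CpG; at most the ten
   smallest-p significant pairs become edges. Edges are binary by default —
   the source analyses treat qualifying pairs as valid interactions without
   weighting — with `|r|` weights behind a flag.

Normalization then residualizes each feature on age and sex (keeping the
feature mean), clips at zero — the factorization takes only non-negative
input, and clipping is the least-surprising repair for the rare negative
residuals — divides each feature by its mean, and balances the views:
with $n_1$ genes and $n_2$ CpGs, `X1` is scaled by $n_2/(n_1+n_2)$ and
`X2` by $n_1/(n_1+n_2)$, so a view cannot dominate the joint loss merely
by having more features.

## Association and genetics analyses

* Responder status: MADRS total change ratio $(w_0 - w_8)/w_0 \ge 0.5$,
  positive = improvement; items with zero baseline are undefined and
  reported NA.
* Topic–response: Spearman per topic, BH across the K topics, FDR < 0.05.
  Topic–MADRS and top-gene–MADRS: Pearson per pair, BH across all tested
  pairs within the analysis (the correction family is the analysis, the
  finest family the source procedure specifies), reported at FDR < 0.05
  and additionally < 0.1 for the gene-level table.
* Genotype QC: minor-allele orientation, then missingness ≤ 0.01,
  MAF ≥ 0.05, HWE exact p ≥ 0.001, attributed to the first failing
  criterion in that order. The HWE test is the exact conditional test
  computed by the stable recurrence over heterozygote counts; the suite
  checks it against a direct log-factorial enumeration for every table
  with n ≤ 30.
* Response SNP scan: OLS of the label on dosage + age + sex, Wald p on the
  dosage term, top set at p < 1e-4, deliberately without global
  multiple-testing correction (the scan is exploratory; its hits feed the
  SNP–topic regressions). SNP–topic regressions run under the additive
  (0/1/2) and the major-allele-presence (minor homozygote vs rest) coding;
  the two codings probe dosage-linear and recessive-like effects and
  coincide when no heterozygotes are present.
* cis-QTL: per feature, all SNPs within 500 kb, BH within the feature's
  cis set, FDR < 0.1. Topic scores and MADRS ratios have no genomic
  position, so their scans run genome-wide (flag-controlled).
* Patient clustering: per-column min–max to [0, 1] (constant columns map
  to 0), Euclidean distance, average linkage (no method is prescribed by
  the source analyses; average linkage is a conservative default),
  exported as newick.

## The synthetic cohort generator

`generate_cohort()` draws everything downstream stages assume, plus the
ground truth recovery tests join against:

* **Factors**: `W`, `α`, `H2` from Gamma(2, 2); expression is
  $\exp(W\alpha\rho + \text{effects} + \text{noise})$ (log-normal, hence
  strictly positive; with noise, covariate effects and planted effects
  disabled the identity is exact), methylation is the logistic squash of a
  per-CpG baseline plus a scaled, centered topic signal.
* **Labels** are Bernoulli with logit linear in the standardized scores of
  one designated topic; the responder fraction is monotone in the slope.
  MADRS totals at week 0 are drawn from 22–40, the week-8 total is
  constructed to respect the ≥ 50 % reduction rule for the drawn label
  (floor/ceiling keeps the integer arithmetic on the right side of the
  threshold), and totals are spread over ten 0–6 items by a multinomial
  draw with deterministic overflow reallocation.
* **Planted differential features** add label-linked offsets: genes on the
  log scale; CpGs at a beta ≈ 0.5 anchor with damped topic load and an
  offset sized (via the logistic slope at 0) so the realized group
  difference clears the configured `beta_effect`. Planted CpGs are drawn
  from gene-proximal sites because the differential-methylation filter is
  cis by definition; a planted effect 600 kb from every gene would be
  unmeasurable by construction.
* **Genotypes** are Binomial(2, MAF) per SNP under Hardy–Weinberg
  equilibrium, except a configurable number of violating SNPs drawn with
  inbreeding coefficient F (excess homozygosity); missing calls are
  uniform at the configured rate. Planted QTLs add a per-allele effect of
  a strictly cis SNP to the target feature's signal; targets with no SNP
  inside the window are skipped rather than planted non-cis.
* **Streams**: each modality draws from its own RNG stream derived from
  the master seed, so enlarging one panel never perturbs another
  modality's draws; the same config and seed reproduce the files
  byte-for-byte.

Defaults are 111 subjects and 10 topics — the scale of the motivating
cohort — with desk-scale feature panels (150 genes, 200 CpGs, 500 SNPs, 20
genesets), log-scale noise SD 0.3, Δβ target 0.05, MAF in [0.1, 0.5].
The generator emulates the *statistical structure* the pipeline assumes:
low-rank non-negative signal, cis-correlated gene–CpG pairs, HWE
genotypes, a topic-linked response. It does not emulate read-level
sequencing artifacts, array probe chemistry, batch effects, population
structure, or realistic MADRS item distributions (only the total-score
rule is constrained). Passing recovery tests therefore demonstrates
correctness of the machinery under the stated generative assumptions, not
performance on real cohort data.

## Harness problem sizes

The test suite and `scripts/acceptance.R` use: 5-subject instances for
finite-difference gradient checks; 20 instances × 200 iterations for
monotonicity; a 60 × 120 × 150 noiseless planted instance (10 genesets,
K = 3, best of 5 restarts) for exact recovery; 20 seeds at signal-to-noise
ratio 5 for planted-loading recovery (matched by exhaustive permutation,
exact for K ≤ 6); 100 null and 50 planted cohorts for calibration and
detection of the association scans; and the bundled seed-7 configuration
(90 subjects, 90 genes, 120 CpGs, 200 SNPs) for the fixed filter counts
and the byte-identity rerun. These sizes were chosen so the whole suite
exercises every claim in minutes on a single core while keeping each
statistical check comfortably powered.

## Known limitations

* Two views only; the interfaces reserve the extension point but the
  update algebra is written for the expression + methylation pair.
* Multiplicative updates stagnate near zero entries; exact zeros are
  absorbing. Restarts mitigate, and the ε guard prevents division blowups,
  but strongly sparse solutions should be read qualitatively.
* The Welch-based differential gate is a stand-in: on raw counts a proper
  count model should supply the p-values (they can be passed in).
* BH control within a cis set is per feature; nothing corrects across
  features in the QTL tables, matching the source procedure.
* Monotonicity of the coupled updates is verified empirically, not proved,
  for the graph-coupled objective.
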