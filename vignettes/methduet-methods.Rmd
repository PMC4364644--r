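---
title: "Dual-model differential methylation discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-model differential methylation discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methduet)
```

## The scientific problem

Epigenome-wide association studies (EWAS) on Infinium-style arrays ask
whether DNA methylation at individual CpG sites, measured in an accessible
tissue such as whole blood, correlates with a phenotype. methduet
implements one complete discovery recipe for a pediatric-obesity setting:
two covariate-adjusted linear models are fitted at every interrogated
location — one with the child's dichotomized weight category as the
variable of interest, one adding and contrasting the additive dose of an
obesity-associated SNP (rs4929949, near *STK33*) — and a gene is nominated
as a candidate when both models place one of its CpG locations among their
top-ranked hits. The package also ships a cohort simulator so that every
stage, and the pipeline's operating characteristics, can be exercised and
tested without access to the original cohort.

## Measurement scales

Arrays report a beta-value per probe and sample, the fraction of
methylated signal, in $[0,1]$. Beta-values are strongly heteroscedastic
near the boundaries, so all modelling happens on the M-value scale,

$$ M = \log_2 \frac{\beta}{1-\beta}, $$

the logit2 of beta. `beta_to_m()` clamps beta into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ first, which
keeps fully (un)methylated probes finite without materially moving
interior values; `m_to_beta()` is the exact inverse away from the clamp.

## Quality control

`qc_filter()` applies a seven-rule cascade plus sex-chromosome removal.
Probes are dropped when they have any missing beta-value, an aggregated
detection p-value above 0.05, fewer than 75% of samples with detection
p below $10^{-5}$, a SNP under the probe, or a cross-reactivity flag.
Samples are dropped when they have any missing beta-value, an aggregated
detection p above $10^{-5}$, or fewer than 75% of sites below $10^{-5}$.
Sex-chromosome probes are removed last and counted separately, since they
reflect study design (a mixed-sex cohort) rather than data quality.

Two genuinely open choices are exposed as switches rather than hard-coded:

* **Aggregation.** How a probe's (or sample's) detection p-values collapse
  to the single number compared against 0.05 / $10^{-5}$ is not uniquely
  defined by the rule names. The default is the mean over the other axis
  (`aggregation = "mean"`), with `"max"`/`"any"` available. Note that the
  mean rule at the sample threshold of $10^{-5}$ is very strict: on a
  matrix of thousands of probes, a single clearly failing cell pushes a
  sample's mean above the threshold, so it effectively demands
  failure-free samples.
* **Order.** Sample rules run before probe rules by default
  (`order = "samples_first"`), so a globally bad sample cannot drag
  otherwise fine probes below the detection thresholds; the reverse order
  is available, and for entities that each violate exactly one rule the
  retained set is identical either way (a property the test suite checks
  against a set-subtraction oracle).

Every removal is attributed to the first rule that catches it, so per-rule
ID lists are disjoint, counts are additive, and the identity
`probes_retained = probes_in - probes_removed_qc - probes_removed_sex`
holds by construction — the test suite asserts it on random cohorts, and
on a 27578-probe manifest with 8157 QC-failing and 1082 sex-chromosome
probes the cascade retains exactly 18339.

## Normalization and island collapsing

`quantile_normalize()` performs classic across-sample quantile
normalization of the M-value matrix (each sample's values replaced by the
mean of the row-sorted columns at the matching rank, ties sharing their
rank span's mean), delegating to `limma::normalizeQuantiles(ties = TRUE)`,
which implements exactly this convention; the test suite verifies it
against a hand-written implementation of the definition.

Probes sharing a CpG-island name (strings like
`"chr19_IC:17905037-17906698"`: chromosome, density class, inclusive
1-based span) are then averaged per sample into a single island location
by `collapse_islands()`; free-standing probes pass through. Normalization
runs at probe level *before* collapsing, so island averages are means of
already-comparable values. For $S$ sites of which $m$ belong to $I$
distinct islands the result has $S - m + I$ locations (18339 sites with
7782 members in 3678 islands give 14235). An island's gene annotation is
inherited from the member probe closest to a transcription start site,
with ties broken to the smallest probe ID — the manifest does not define
a per-island gene, so this deterministic, auditable rule is the package's
own choice.

## The per-location model

At each location $k$ the model is

$$ M_k = a_k + b_{kG} G + b_{kT} T + b_{kW} W + b_{kB} B \,(+\, b_{kS} S) + \varepsilon_k $$

with $G$ sex (female = 0, male = 1), $T$ Tanner stage (1–5), $W$ weight
category (normal-weight = 0, obese = 1), $B$ white-blood-cell count
(adjusting for the granulocyte/lymphocyte composition shifts that
dominate whole-blood methylation), and, in the second model, $S$ the
additive risk-allele dose (TT = 0, TC = 1, CC = 2). Model 1's contrast is
$b_{kW}$; model 2's is $b_{kS}$.

Fitting is robust by default: Huber M-estimation via iteratively
reweighted least squares with tuning constant $c = 1.345$ (95% Gaussian
efficiency), scale re-estimated each iteration as the rescaled MAD of the
residuals, convergence when no coefficient moves by more than $10^{-8}$,
and a cap of 10000 iterations (non-convergence sets a flag rather than
erroring). The residual variance is the Huber-weighted residual sum of
squares over $n - p$, divided by the Gaussian consistency factor
$E[\min(1, c/|z|)\,z^2] = 2\Phi(c) - 1 \approx 0.821$: without this
correction the robust variance is biased low by ~18% on clean Gaussian
data and every downstream p-value would be anticonservative. The residual
degrees of freedom are taken as $n - p$ with no effective-df correction —
a simplification shared with ordinary practice and a documented
limitation. With `robust = FALSE` the fit is exact (vectorized) OLS.

## Empirical-Bayes moderation and ranking

`ebayes_moderate()` shrinks each location's variance toward a global
prior. The prior $(d_0, s_0^2)$ is estimated by matching moments of
$\log s_k^2$ under the scaled-F sampling model: the excess of the
empirical variance of $\log s_k^2$ over its $\chi^2$ sampling component
$\psi'(d_k/2)$ identifies $\psi'(d_0/2)$ (inverted by Newton iteration),
and the mean identifies $s_0^2$. When the observed spread does not exceed
the sampling floor, $d_0 = \infty$: variances are exchangeable, every
moderated variance equals the plain average of the $s_k^2$, and the
reference distribution is normal. Otherwise

$$ \tilde s_k^2 = \frac{d_0 s_0^2 + d_k s_k^2}{d_0 + d_k}, \qquad
   t_k = \frac{b_k}{u_k \tilde s_k}, $$

with $u_k$ the contrast's unscaled standard-error factor from the
(weighted) design cross-product, and two-sided p-values on $d_0 + d_k$
degrees of freedom. On OLS fits this reproduces the reference limma
`lmFit`/`eBayes` chain to machine precision (a cross-check in the test
suite, not the implementation). Benjamini–Hochberg adjustment
(`bh_adjust()`, delegating to `stats::p.adjust`) controls the FDR across
locations.

`rank_top()` orders locations by ascending raw p-value — the ordering the
result tables use — with ties broken by location ID, and keeps the top
$k = 15$ by default. The adjusted p-values are reported alongside; note
that a weight-category model of this size can easily have no location
passing adjusted $p < 0.05$ while still producing a meaningful ranked
list, which is why discovery here rests on the intersection step rather
than on single-model significance.

## Dual-contrast discovery

`cross_model_intersect()` nominates genes hit by a top-$k$ location in
*both* models. Matching is at the gene level only — two distinct CpG
sites of one gene count, coordinate overlap is never used — and is
token-based by default: a symbol's tokens are itself plus its
`-`-separated components, so the readthrough form `CORO7-PAM16` in one
table matches `CORO7` in the other (`match = "exact"` disables this).
Each shared gene is reported with both matching rows and a
`direction_consistent` flag, true when the two contrast coefficients
share a sign. On the bundled published tables this yields exactly one
gene, *CORO7*, with coefficients $-0.137$ (weight model) and $-0.144$
(genotype model): both hypomethylated as obesity risk rises.

## The cohort simulator

`simulate_cohort()` draws cohorts with the structure the analysis
assumes, and its defaults are the package's reference study conditions:

* 69 children (35 obese / 34 normal-weight, 22 boys / 47 girls), Tanner
  stage drawn from a latent normal correlated at 0.3 with the
  weight-category latent (mild confounding, so covariate adjustment does
  real work), white-blood-cell counts lognormal
  ($\log\mu = \log 6.5$, $\sigma = 0.25$, in $10^9$ cells/L), genotype
  dose binomial with risk-allele frequency 0.48 under Hardy–Weinberg.
* Baseline probe methylation from a promoter-biased three-component Beta
  mixture (weights 0.60/0.15/0.25 on unmethylated Beta(1.5, 15),
  hemimethylated Beta(5, 5), methylated Beta(15, 1.5)), floored to
  $[0.01, 0.99]$ — reported beta-values on real arrays stay away from the
  exact boundaries after background correction, and without the floor
  quantile normalization pins the most extreme probes to identical values
  across samples, collapsing their residual variance to zero.
* Differential effects injected additively on the M scale (where the
  model lives) with magnitude 1.5 M-units and random sign, then mapped
  back to beta for storage; within-group noise SD 0.5 M-units. Neither
  the within-group variance nor the true effect sizes of the motivating
  cohort are published, so these are conventions chosen to be realistic
  for whole-blood arrays, flagged as such.
* Spiked probes are placed on clean, free-standing autosomal probes so
  that ground truth survives QC and island averaging; `n_shared_genes`
  optionally spikes one gene with a weight effect on one probe and a
  genotype effect on another (both negative, the pattern the discovery
  step is designed to catch).
* Detection p-values are drawn from $U(0, 10^{-6})$ for passing cells and
  $U(0.05, 1)$ for failing cells, unambiguously on either side of both QC
  thresholds. The default cell failure rate is 0 — processed
  series-matrix-style deposits are detection-clean, and under the default
  mean aggregation any failing cell would remove its sample — so the
  detection rules are exercised in tests through explicit nonzero rates
  and hand-built fixtures.

What the simulator does *not* emulate, and what passing tests therefore
do not certify about real data: probe-type chemistry differences, spatial
or batch effects, correlated probes beyond shared island membership,
cell-composition heterogeneity beyond a single WBC covariate, and
genotype–methylation cis effects. Conclusions from the simulator concern
the pipeline's statistical behavior, not array chemistry.

## Operating characteristics checked by the tests

The suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) verifies on simulated cohorts at the reference
size (n = 69, 5000 free-standing locations, 10 replicates):

* the pooled fraction of raw $p < 0.05$ under a pure null lies in
  $[0.04, 0.06]$ for the weight contrast;
* the empirical FDR among adjusted-$p < 0.05$ calls under 2% spiked
  alternatives at 1.5 M-units stays at or below 0.075;
* the mean sign-aligned fitted weight coefficient over truly affected
  probes recovers 1.5 within three Monte-Carlo standard errors;
* count identities (probe accounting, $S - m + I$) hold exactly;
* quantile normalization, BH, robust-vs-OLS and the prior moment
  recovery agree with independent brute-force oracles.

Problem sizes in the tests (hundreds to a few thousand probes per case,
five to ten replicates) are the package's chosen desk-scale defaults;
all of them scale up by changing `sim_config()` fields.

## Numerical notes and limitations

* IRLS convergence is measured on the maximum coefficient change; a
  perfect fit (residual scale below $10^{-10}$) short-circuits with unit
  weights and zero variance. Zero variances are excluded from prior
  moment estimation and simply shrink to $s_0^2$.
* The trigamma inversion uses Newton iteration on a monotone function and
  is accurate to $10^{-10}$ relative.
* Ties in ranking break on location IDs; ties in quantile normalization
  share their rank span's mean reference value. Both choices are
  deterministic, so identical inputs and seeds give byte-identical
  outputs end to end.
* Decimal commas seen in some published tables are a rendering locale;
  all internal numbers and all files written use decimal points.
* The robust-fit residual df of $n - p$ ignores the mild df loss from
  weight estimation; with 60+ samples the effect on p-values is
  negligible relative to the moderation step.
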