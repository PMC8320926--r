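---
title: "Aggregated knockoff filtering for untargeted metabolomics: model, assumptions and design choices"
author: "MetaboKnockoffs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated knockoff filtering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboKnockoffs)
```

## The problem

Untargeted LC-MS metabolomics yields wide feature tables — hundreds of
named metabolites over a few hundred samples — with strong inter-metabolite
correlation and substantial missingness. Selecting the metabolites that
genuinely differ between sample classes (say CD, UC and non-IBD subjects)
with univariate tests ignores the correlation structure; multivariate
learners such as random forests rank features well but provide no valid
error control on the resulting list. Model-X knockoffs close that gap: a
synthetic negative-control copy of the feature matrix calibrates any
importance score, and a selection rule on the calibrated scores controls
the false discovery rate (FDR).

`MetaboKnockoffs` implements the aggregated variant of this idea as a
reusable pipeline, together with a ground-truth simulator so the pipeline's
empirical FDR and power can be measured end to end.

## The pipeline

For a table $X \in \mathbb{R}^{n\times p}$ (samples by metabolites) with
class labels $y_i \in \{0, \dots, K-1\}$:

1. **t% rule** (`tPercentFilter`). A metabolite is kept only if it has an
   observed, nonzero intensity in at least $t\%$ of samples, i.e. in at
   least $\lceil tn/100 \rceil$ samples. $t = 0$ disables filtering;
   $t = 100$ keeps exactly the complete columns. The kept set is monotone
   decreasing in $t$.
2. **KNN imputation** (`knnImpute`). Each missing entry $(i, j)$ becomes
   the mean of metabolite $j$ over the $k = 10$ nearest neighbour samples,
   with the root-mean-square distance computed over co-observed
   metabolites only. Neighbours lacking $j$ are skipped; with no eligible
   donor the observed column mean is used. At $t = 100$ the step is a
   no-op by construction.
3. **Standardization** (`standardizeIntensities`). Each column to mean 0,
   SD 1 (denominator $n-1$, matching the covariance estimate below).
4. **Knockoff model** (`fitKnockoffModel`). Assume $X \sim N(\mu, \Sigma)$.
   $\mu$ is the column mean; $\Sigma$ the Ledoit–Wolf shrinkage covariance
   (automatic intensity, target = scaled identity), which keeps
   $\Sigma^{-1}$ well defined even with $p$ close to $n$. The
   equi-correlated rule sets $s_j = \min(2\lambda_{\min}(\Sigma^{corr}), 1)$
   on the correlation scale; knockoffs are drawn from the conditional
   normal
   $\tilde X \mid X \sim N\!\big(X - (X - \mathbf{1}\mu')\Sigma^{-1}D_s,\;
   2D_s - D_s\Sigma^{-1}D_s\big)$, $D_s = \mathrm{diag}(s)$, without ever
   seeing $y$. This matches first and second moments of the exchangeable
   joint distribution: $\mathrm{cov}([X, \tilde X])$ converges to
   $[[\Sigma, \Sigma - D_s], [\Sigma - D_s, \Sigma]]$ (verified by test).
5. **Importance** (`rfImportance`). For each of $B = 15$ independent
   knockoff draws, a random forest (1000 trees by default,
   $\mathrm{mtry} = \sqrt{2p}$) is fitted to the augmented matrix
   $[X\; \tilde X^{(b)}]$ and every column scored by out-of-bag
   permutation importance — the per-tree drop in OOB accuracy when the
   column is permuted, averaged over trees; the score kept is
   $Z = |\text{mean decrease}|$.
6. **Knockoff-adjusted score** (`knockoffStat`).
   $W_j = |Z_{\text{orig},j}| - |Z_{\text{ko},j}|$. For null metabolites
   $W_j$ is symmetric about 0; a large positive $W_j$ is evidence of true
   association.
7. **Intermediate p-values** (`intermediatePValues`).
   $\pi_j = (1 + \#\{k: W_k \le -W_j\})/p$ for $W_j > 0$, and 1 otherwise:
   the negative part of the $W$ distribution serves as an empirical null.
8. **Aggregation** (`quantileAggregate`).
   $\bar\pi_j = \min(1, q_\gamma(\{\pi_j^{(b)}\})/\gamma)$ with
   $\gamma = 0.5$: twice the median over draws, capped at 1. Aggregation
   removes the run-to-run variability of a single knockoff draw.
9. **Selection** (`bhSelect`). Benjamini–Hochberg step-up on $\bar\pi$ at
   $\alpha = 0.05$, with $m$ = the post-filter metabolite count (the set
   actually tested).

`runKnockoffPipeline` chains the stages; `sweepThresholds` repeats the run
over $t \in \{0, 60, 70, 80, 100\}$ and reports the union, intersection
and pairwise overlaps of the selections (each $t$ re-imputes and
re-standardizes its own surviving set, and by default receives an
independent randomization so overlaps are not artifacts of shared noise);
`evaluateFdrPower` wraps simulation replicates into mean FDP/power with
Monte-Carlo standard errors.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `t` | 0–100 (%) | minimum fraction of observed, nonzero intensities per metabolite |
| `knnK` | 10 | neighbour samples for imputation |
| `B` | 15 | independent knockoff draws aggregated |
| `gamma` | 0.5 | quantile level of p-value aggregation |
| `alpha` | 0.05 | nominal FDR of the BH step-up |
| `nTrees` | 1000 | trees per forest (200 is plenty for tables of this size and ~5x faster; the default keeps the reference setting) |
| `mtry` | $\sqrt{2p}$ | candidate features per split |
| `shrinkage` | automatic | Ledoit–Wolf intensity; fix to 0 for the raw empirical covariance |

## What the simulator emulates — and what it does not

`simulateMetaboSet` draws a latent class-conditional Gaussian with unit
variances and a configurable correlation (independent, AR(1), or
equicorrelated blocks), shifts a seeded random subset of `nSignal`
metabolites by `effectSize` SD between consecutive classes, exponentiates
to obtain positive, lognormal-like intensities, and masks entries either
completely at random or with a logistic left-censoring probability
calibrated so each metabolite's expected missing fraction equals
`missingRate`. Defaults mirror a cohort-scale untargeted study: 546
samples, three roughly equal classes, 100 metabolites, AR(1) correlation
0.5, 20% missingness, and a sparse signal set (10 metabolites).

The simulator does **not** reproduce chromatography-specific artifacts
(retention-time drift, adducts, isotopes), heavy-tailed technical noise,
batch effects, or non-Gaussian dependence. Passing FDR/power tests on
simulated data therefore certify the *procedure* under its own Gaussian
working assumptions — the same assumptions the second-order knockoff
construction makes — not robustness to every failure mode of real LC-MS
data. On real tables the Gaussianity of standardized log-scale intensities
is an approximation, and knockoff quality degrades exactly where that
approximation does.

## Numerical choices

* **Covariance.** Ledoit–Wolf shrinkage toward a scaled identity with the
  analytic intensity; a fixed intensity is accepted. A covariance whose
  correlation matrix is numerically singular even after shrinkage is an
  error rather than a silent pseudo-inverse.
* **PSD repair.** $V = 2D_s - D_s\Sigma^{-1}D_s$ is symmetrized and its
  eigenvalues floored at 0; a warning fires if the floored mass exceeds
  $10^{-8}$ of the trace. Sampling uses the symmetric eigendecomposition
  square root $V^{1/2}$, which (unlike a Cholesky factor) exists for
  merely positive semidefinite $V$.
* **Seeding.** Knockoff copy $b$ uses seed $\mathrm{xor}(\text{seed}, b)$;
  per-draw forest and swap seeds are derived deterministically from the
  master seed; threshold sweeps mix $t$ into the stream. Same seed, same
  platform ⇒ bit-identical results; the RNG state of the caller is never
  disturbed.
* **Ties and degenerate cases.** $W_j = 0$ maps to $\pi_j = 1$ (zero
  evidence is never a discovery); BH ties at the threshold are all
  selected; constant columns are dropped before standardization with a
  warning; all-missing columns are dropped before imputation with a
  warning; a filter that removes every metabolite is an error.
* **Quantile convention.** The lower empirical quantile (order statistic
  at $\lceil \gamma B\rceil$) — deterministic and conservative; at
  $\gamma = 0.5$, $B = 15$ it is the 8th order statistic.

## Design decisions on genuinely open points

* **Zero-as-missing.** The t% rule speaks of *nonzero* values, implying
  zeros encode absent peaks; `readFeatureTable(zeroIsMissing = TRUE)` is
  the default, with the flag restoring zeros as measurements. Both
  conventions occur in repository exports.
* **Neighbour axis for imputation.** Neighbours are *samples*, not
  metabolites: with $n \gg p$ per chromatography mode and class structure
  across rows, sample space is better populated. (The cited KNN-imputation
  lineage contains both readings.)
* **Importance sign.** "Absolute mean decrease" is read as
  $|\text{mean}(\text{decrease})|$. The per-tree absolute variant
  ($\text{mean}|\text{decrease}|$) would require per-tree importance
  values the forest engine does not expose, and is not offered.
* **Pair-position swapping.** Before each forest fit, each
  original/knockoff pair's column positions are swapped with probability
  1/2 (seeded, recorded, undone when scores are paired into $W$), so any
  positional bias of tree construction cannot systematically favour
  originals. `swap = FALSE` restores fixed-order concatenation.
* **Multiclass handling.** One multiclass forest with overall OOB accuracy
  as the metric; one-vs-rest contrasts are expressed by subsetting samples
  before the pipeline.

## A structural limitation worth knowing

The intermediate p-values have resolution $1/p$: their smallest possible
value is $1/p$, hence $\bar\pi_j \ge 1/(\gamma p)$ after aggregation.
Feeding such p-values to the BH step-up at level $\alpha$, a selection of
$k$ metabolites requires $\bar\pi_{(k)} \le k\alpha/m$ with $m = p$, so
**any** non-empty selection needs at least
$\lceil 1/(\gamma\alpha) \rceil$ discoveries — 40 at the defaults
$\gamma = 0.5$, $\alpha = 0.05$. Consequently:

* with sparse truth (e.g. 10 associated metabolites out of 100) the
  selection is structurally empty: the empirical FDR is trivially
  controlled, but power is zero regardless of effect size;
* the procedure only has power when the number of class-associated
  metabolites (strictly, of metabolites reaching the p-value floor)
  exceeds that threshold. The dense-signal test in the suite (50 signals
  of 100, effect 1.5 SD, $n = 200$) shows essentially full recovery at
  controlled FDP in that regime.

This is an inherent property of quantile-aggregated empirical knockoff
p-values combined with BH, not an implementation artifact; raising
$\gamma$ lowers the floor only to $\lceil 1/\alpha \rceil$. Published
selection counts obtained with this family of methods that fall below the
floor indicate a selection rule other than a literal BH step-up (for
instance thresholding $\bar\pi_j \le \alpha$ directly). The package
implements the literal step-up.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while keeping the Monte-Carlo error small: FDR control is measured
over 30 replicates of $n = 200$, $p = 100$, 10 signals at 1.0 SD, AR(1)
$\rho = 0.5$, with $B = 15$ and 200-tree forests; signal recovery over 20
replicates at $n = 300$, effect 1.5 SD; knockoff moment validity at
$n = 5000$, $p = 20$; the selection operations against brute-force
enumeration on 1000 random small instances.

## Known limitations

* Second-order (Gaussian) knockoffs only; no deep generative knockoffs.
* A single importance engine (random-forest OOB permutation importance);
  no lasso-path or SHAP statistics.
* No enrichment analysis, clustermaps or other downstream interpretation
  of real selections.
* FDR control is exact for the single-draw knockoff filter under
  exchangeability; for the aggregated variant it is inherited
  approximately (and empirically verified here), as in the aggregation
  literature.
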