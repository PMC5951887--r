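---
title: "Hybrid ordinal-regression/IRT DIF analysis: models, decisions, limits"
author: "hybridDIF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ordinal-regression/IRT DIF analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-item Likert scales are routinely summed and compared across groups
— cohorts from different countries, men and women, ethnic groups. Such
comparisons presume *measurement invariance*: respondents with the same
level of the underlying trait should answer each item the same way
regardless of group membership. When that fails for an item, the item
shows *differential item functioning* (DIF), and group comparisons on
the raw scores mix true trait differences with item-level artefacts.

hybridDIF implements the hybrid ordinal-logistic-regression/IRT approach
to DIF detection for ordinal items, with empirical Monte-Carlo detection
thresholds, iterative purification, and an individual-level impact
analysis. It was built around the design of a multi-cohort analysis of
the 32-item HIV Stigma Scale (three cohorts of 250, 188 and 598
respondents; four subscales of 11, 8, 6 and 7 four-category items, two
of them reverse-scored), and ships a synthetic-data generator that
emulates that design; all machinery is generic over any
respondent-by-item matrix of ordinal codes.

## The model chain

**Trait estimation.** Items are calibrated under Samejima's graded
response model: the probability that a response reaches category $k$ or
higher is $P(u_{ij} \ge k \mid \theta_i) = \sigma\!\big(a_j(\theta_i -
b_{jk})\big)$ with logistic $\sigma$, discrimination $a_j > 0$ and
ordered thresholds $b_{j2} < \dots < b_{jK}$. Estimation is marginal
maximum likelihood with the trait integrated out over a fixed
quadrature grid under a standard-normal prior; the prior fixes the
latent metric (mean 0, SD 1), which is the identification the rest of
the pipeline relies on. Respondents are scored by EAP (posterior mean
on the same grid). EAP was chosen over ML scoring because it is defined
for every response pattern, including perfect ones, and matches the
methodology of the ordinal-regression DIF literature this package
follows.

**DIF testing.** For each item, three nested cumulative-logit
(proportional-odds) models are fitted to $P(u \ge k)$:

* Model 1: $\alpha_k + \beta_1\theta$ (no DIF)
* Model 2: Model 1 $+ \beta_2\,\mathrm{group}$ (uniform DIF)
* Model 3: Model 2 $+ \beta_3\,\theta\times\mathrm{group}$ (non-uniform DIF)

With $G$ groups, "group" is $G-1$ indicator columns (reference group:
first level in sorted label order) and the interaction adds another
$G-1$ columns, so the two-group case reduces exactly to the printed
single-coefficient form. The test statistic is the change in
Nagelkerke's pseudo-$R^2$ (Cox–Snell rescaled by its maximum) between
Model 1 and 2 (uniform) and Model 2 and 3 (non-uniform). The changes
telescope: $\Delta_{13} = \Delta_{12} + \Delta_{23}$ exactly. The $n$
in the pseudo-$R^2$ formula is the number of rows in that item's fit,
after listwise deletion.

**Empirical thresholds.** Fixed pseudo-$R^2$ cutoffs from the
literature (0.13/0.26, 0.035/0.070, 0.02) vary widely; instead the
detection threshold is simulated: DIF-free data are generated from the
fitted item parameters (all groups share them), with trait values
resampled with replacement from the observed per-group EAP
distributions — so *true* group trait differences are preserved while
*item* behaviour is exchangeable. Each replication is scored and tested
in a single pass, and the threshold is the smallest multiple of the
grid step (default 0.01) strictly above the largest statistic observed
anywhere. One analysis-level threshold is applied to both statistics,
matching how such thresholds are reported (a single value per
analysis). Replications are scored with the generating item parameters
rather than refit: the simulated data are DIF-free by construction, the
generating parameters are the MML estimates of that design, and
refitting 100 times would add Monte-Carlo noise to the null statistics
without changing what they measure.

**Purification.** Items flagged at iteration 0 contaminate the trait
estimate used as the matching criterion, producing both false positives
and false negatives. The loop therefore recalibrates the model on the
non-flagged (anchor) items only, re-scores, recomputes the statistics
for *all* items, and re-flags, until two successive rounds agree.
Thresholds are computed once from the iteration-0 calibration and held
fixed — the threshold step precedes the iterative step in the workflow
this package follows, and re-simulating per iteration would let the
cutoff drift with the flag set. If the flag set oscillates
(A → B → A), the run stops at the iteration cap and is explicitly
marked non-converged rather than silently accepting either set. An
empty flag set at iteration 0 terminates immediately: the anchor set is
the full item set and nothing would change.

**Impact.** Flagging is a statistical statement; whether DIF *matters*
is a score-level question. The package compares each person's initial
EAP score (DIF ignored) with a purified score from an augmented
calibration in which every flagged item is split into $G$ group-specific
virtual items (responses present only for that group) while anchors
stay shared. Both calibrations use the identical quadrature and prior,
so the difference reflects the DIF handling only. The sign convention
is fixed as *difference = initial − purified*; the absolute difference
is compared with a salience cutoff of 0.20, read as a small effect size
on the trait (SD-unit) scale. (The source study's prose and its figure
axis disagree on the subtraction order; the figure's initial − purified
is used, and salience depends only on the absolute value.)

**Dimensionality.** The DIF models assume the subscale measures one
trait. As an exploratory check the package estimates polychoric
correlations (two-step ML: thresholds from the margins, correlation by
one-dimensional likelihood maximisation; nearest-PSD repair by clipping
negative eigenvalues) and applies two retention rules to the spectrum:
permutation-based parallel analysis and the Empirical Kaiser Criterion
$\,l_j > \max\!\big(\tfrac{p - \sum_{i<j} l_i}{p - j + 1}(1 +
\sqrt{p/n})^2,\, 1\big)$. Permutation (rather than independent-normal
simulation) respects the ordinal margins; the polychoric matrix is
recomputed for every permuted copy. Both rules are applied to the same
polychoric spectrum, consistent with the ordinal data; whether the
original analyses used polychoric or Pearson input is not stated in the
source, so this is the package's own choice.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `K` | 4 | response categories; all items share one K per analysis |
| `minCell` | 5 | minimum group-by-category count before collapsing; merges run from the extremes inward, identically in all groups |
| quadrature | 101 points on [−6, 6] | EAP/MML grid; fine enough that scores agree with a 10×-finer grid to ~1e−7 |
| EM stop | max param change < 1e−4, or likelihood flat to 1e−8 for 3 cycles; ≤ 2000 cycles | calibration tolerance; the plateau rule covers weakly identified anchor refits |
| `nMcReplications` | 100 | null replications behind the threshold |
| `thresholdGrid` | 0.01 | threshold granularity; yields analysis thresholds of 0.01–0.03 at these designs |
| `flagRule` | "either" | uniform or non-uniform exceedance flags the item |
| `maxIterations` | 10 | purification cap; oscillation ⇒ non-converged |
| salience cutoff | 0.20 | small effect size on the θ (SD) scale |
| PA quantile | 0.95 | reference quantile for parallel analysis |

Reverse-scored items are recoded (`code → K + 1 − code`) immediately
after loading, before any analysis, with a scale definition flag to
disable; standard scoring practice recodes before modelling, and the
fits assume positive discrimination.

## The synthetic generator

`generateStudy()` emulates the multi-cohort design: three cohorts of
250/188/598 respondents, group trait means 0.25/−0.25/0 (SD 1) — a
modest, realistic between-cohort trait difference so the
impact-versus-DIF distinction is exercised — 32 four-category items in
subscales of 11/8/6/7, discriminations uniform on [1.2, 2.5],
thresholds as sorted standard-normal draws with a minimum gap of 0.3
(redrawn otherwise, keeping every category populated at these sample
sizes so the min-cell rule passes, as it did in the motivating study),
a gender column with female proportions 0.50/0.43/0.34, one person with
a missing gender label (emulating a recoded single-respondent
category), and 2% MCAR cell missingness. Injected DIF is uniform (all
thresholds of an item shifted for one group) or non-uniform (the
item's discrimination multiplied for one group).

What it does **not** emulate: real item wording effects, local
dependence between items, non-MCAR missingness, multidimensionality
within a subscale, and the actual (unpublished) item parameters of the
motivating cohorts. Passing tests therefore demonstrate that the
machinery detects and quantifies DIF under the stated generating model,
not that any particular real dataset is DIF-free.

## Numerical choices

* Proportional-odds fits use Newton–Raphson with analytic gradient and
  Hessian and step-halving; the cumulative-logit log-likelihood is
  concave, so the fit is deterministic. Convergence: largest update
  < 1e−8. Rank-deficient designs (constant or collinear columns) are
  rejected up front; separation surfaces as a non-convergence error
  with the likelihood trace.
* The GRM M-step optimises each item on an unconstrained scale
  (log discrimination, first threshold, log threshold gaps), which
  enforces ordering by construction; a few damped Newton steps per EM
  cycle are taken, accepting only objective decreases, so the marginal
  likelihood is non-decreasing across cycles (generalised EM).
* Intercept-only cumulative models are solved in closed form
  (empirical cumulative logits).
* The bivariate normal CDF inside the polychoric likelihood is
  evaluated by 48-node Gauss–Legendre quadrature of the
  correlation-integral representation, vectorised over cell boundaries
  (agrees with a reference implementation to ~1e−9); the correlation
  search is bounded to [−0.995, 0.995] and falls back to Pearson with a
  warning when the likelihood is boundary-bound.
* Persons with no observed responses score at the prior mean (θ = 0,
  SE = 1) by convention.
* Per-cell seeds in `runAnalysis()` derive from the master seed and the
  contrast/subscale name by a small polynomial hash, so cells are
  reproducible independently and removing one subscale leaves the
  others byte-identical.

## Problem sizes used in the shipped checks

The package's own test suite and the `scripts/acceptance.R` summary use
simulation sizes chosen to estimate each property stably: parameter
recovery at n = 2000; operating characteristics on an 8-item, two-group
design (300–400 per group) with thresholds simulated once per design
from 100 null replications and the detection pipeline replicated 50–100
times; impact recovery at 500 per group; dimensionality at n =
1000–4000. The end-to-end run uses the full three-cohort design with
uniform DIF of 1.2 planted on three of the eight disclosure-concerns
items for the smallest cohort — sized so the per-item pseudo-$R^2$
changes fall in the 0.02–0.05 class that real between-cohort findings
on this subscale show — mirroring the kind of finding the method is
meant to surface (the motivating study reported salient disclosure-concerns
DIF between its Swedish and Indian cohorts, with group effects in
opposite directions and a near-zero overall mean difference — the same
qualitative pattern the planted run reproduces).

## Known limitations

* Only the graded response model is offered (appropriate when all
  items share K; a partial-credit alternative is out of scope).
* One threshold per analysis, shared by the uniform and non-uniform
  statistics; per-statistic grids are computed and returned but not
  used for flagging.
* The Monte-Carlo null resamples EAP scores, which are shrunken
  relative to true traits; thresholds are therefore mildly
  conservative, which the type-I checks reflect.
* Items with fewer effective categories after collapsing are modelled
  with their own contiguous code range; mixing wildly different K
  within an analysis is not supported beyond that.
* The dimensionality module is exploratory; confirmatory factor
  analysis with ordinal-appropriate estimators is deliberately not
  reimplemented here.
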