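---
title: "Change scores, allostasis ratios and the dyadic vulnerability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change scores, allostasis ratios and the dyadic vulnerability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(allostat)
```

## The scientific problem

Chronic stressors do not always move a group's mean physiology. In socially
housed primate mothers exposed to prolonged foraging uncertainty, central
stress signalling (CSF corticotropin-releasing factor, CRF) rises clearly at
the group level, while peripheral HPA-axis output (plasma cortisol) shows
essentially no group-mean change — yet individual mothers change their
cortisol by around 20% of baseline, in both directions. The hypothesis this
package operationalises is *social allostasis*: individual HPA responses
redistribute bidirectionally, patterned by each mother-infant dyad's relative
vulnerability, so that the group mean stays within a narrow band.

`allostat` implements the analysis chain needed to interrogate a cohort of
mother-infant dyads measured before and after such a stressor:

1. **Change scores** and the closed-form **change-score identity**.
2. The **allostasis ratio**: group-mean versus mean individual percent change,
   with a permutation contrast between two biomarkers.
3. **Baseline-split inversion analysis** with Newman-Keuls post hoc testing,
   and **regression-to-the-mean diagnostics**.
4. **Variable clustering** and the composite **dyadic vulnerability index**.
5. A **synthetic cohort generator** with a latent vulnerability factor, used
   to validate every stage by parameter recovery and calibration.

## The change-score identity

For paired measurements with summary statistics $(s_{pre}, s_{post}, r)$,
where $r = \mathrm{corr}(pre, post)$ and $\Delta = post - pre$:

$$sd(\Delta) = \sqrt{s_{pre}^2 + s_{post}^2 - 2 r\, s_{pre} s_{post}},\qquad
r(pre, \Delta) = \frac{r\, s_{post} - s_{pre}}{sd(\Delta)},\qquad
r(\Delta, post) = \frac{s_{post} - r\, s_{pre}}{sd(\Delta)}.$$

These relations are algebraically exact for any sample fed its own moments
(`change_identity()` is tested against both this identity and a large
bivariate-normal Monte-Carlo oracle). They matter scientifically because a
*strong negative* baseline-delta correlation is already implied by weakly
correlated pre/post values with comparable SDs — a point that must be kept in
mind when interpreting "high-baseline dyads decreased, low-baseline dyads
increased". With cortisol's printed summaries (SDs 7.09 and 5.61 ug/dl,
$r = -0.24$) the identity gives $r(pre, \Delta) = -0.84$:

```{r}
change_identity(summary_stats(44.12, 7.09, 44.36, 5.61, -0.24, 22))
```

That is why the package pairs the inversion analyses with two diagnostics
that distinguish structured inversion from regression to the mean
(`rtm_diagnostics()`): the Pitman-Morgan test of correlated variances (a
regression-to-the-mean artefact shrinks the follow-up variance) and a
symmetric-inversion check comparing absolute deviations from the respective
means (null when individuals cross the mean to an equal and opposite degree).

## Sign conventions

The change score is always `post - pre`. Paired t statistics are reported on
`pre - post`, so a mean increase yields negative t; this mirrors the
convention of the motivating report, which prints a mean CRF change of
+82.30 pg/ml alongside a paired t of -2.52. That report also prints the mean
group cortisol change as -0.24 ug/dl although its own pre/post means imply
+0.24; the package documents and keeps the `post - pre` convention (+0.24)
and does not attempt to resolve the source's internal inconsistency.

## The allostasis ratio and its inference

For each biomarker, `ratio_determination()` computes

* `group_pct` — the *ratio of means*: $100\,(\bar{y}_{post} -
  \bar{y}_{pre})/\bar{y}_{pre}$; the ratio-of-means reading reproduces the
  CRF group change of 24.2% exactly from the printed means; and
* `individual_pct` — the *mean of per-dyad ratios*:
  $100\,\mathrm{mean}(|\Delta_i|/pre_i)$, the only reading consistent with
  an individual cortisol change near 20% exceeding
  $\mathrm{mean}|\Delta|/\mathrm{mean}(pre)$.

Their quotient is small when large individual changes cancel at the group
level. The original analysis entered the four percentages into a 2x2 Fisher
exact test; treating percentages as counts is not a defined procedure, so
the package's primary inference is `contrast_measures_permutation()`: per
dyad, the (pre, post) pair labels are swapped between the two measures after
each measure is standardized to unit baseline mean (making the swap
scale-free), and the two-sided tail probability of the ratio difference is
computed with add-one smoothing. The literal mode (`fisher_2x2_literal()`)
is retained for reproduction only and is flagged as statistically
ill-defined in its output.

## The synthetic cohort generator

`synthetic_config()` encodes the study conditions: 22 dyads in four pens,
cortisol 44.12 (7.09) to 44.36 (5.61) ug/dl with pre/post correlation
-0.24, CRF 339.83 (117.40) to 422.13 (134.08) pg/ml with correlation 0.26,
and the covariate marginals of the printed cohort table. One latent
vulnerability factor $v \sim N(0,1)$ per dyad loads on maternal weight
(-0.75), within-pen rank order (0.75 toward subordinate), infant weight
(-0.70), dyadic closeness (0.70, i.e. -0.70 on the 1-5 distance score) and
baseline cortisol (+0.80). The loading magnitudes were fixed once from the
printed predictor-correlation table (for example, they imply
$\mathrm{corr}(\text{weight}, \Delta\text{cortisol}) \approx 0.84 \times
0.75 \times 0.80 \approx 0.50$, near the printed 0.58).

Two modelling choices deserve emphasis:

* **No separate delta equation.** Each post value is drawn jointly with its
  pre value to achieve the configured marginals and pre/post correlation;
  the baseline-delta coupling of -0.84 then *emerges* from the change-score
  identity rather than being imposed. Group-level homeostasis (mean cortisol
  change +0.24 ug/dl, far below the delta SD of ~10) and the CRF group rise
  (+82.30 pg/ml) emerge the same way.
* **Measurement floors.** Gaussian draws are censored at assay detection
  limits (CRF at 20 pg/ml, the assay's stated sensitivity; cortisol at
  1 ug/dl; weights at 0.01 kg). Percent-change statistics are meaningful
  only for detectable baselines; without the floors a rare near-zero
  baseline draw can dominate `individual_pct`. Tail mass below the floors
  is under 0.5%, so configured marginals are unaffected to within
  Monte-Carlo error.

The infant-sex effect on the CRF change (default 0.85 SD higher for mothers
of female infants, matching the printed point-biserial magnitude of ~0.43)
is folded into the joint CRF draw through a centred unit-variance sex
contrast, so the CRF marginals remain exact. Rank is the within-pen order of
$v$ plus noise with rank 1 (most dominant) at the lowest $v$; the late
exposure cohort's infants are older at onset by 79 days, with the overall
onset marginal preserved. Dyadic distance has no printed distribution beyond
its 1-5 scale; the generator treats the aggregated score as continuous with
mean 3.0 and SD 0.8, truncated to the scale.

What the generator deliberately does *not* emulate: within-stressor temporal
dynamics (no samples were taken during the exposure), assay error structure
beyond the detection floor, discreteness of the observational distance
score, and any dependence between pens. Tests passing on these cohorts
therefore demonstrate the *methods* are correct and calibrated under the
stated generative assumptions, not that real data satisfy them.

## Clustering and the vulnerability index

`cluster_variables()` clusters *variables* by the Euclidean distance between
their (by default z-scored) observation columns. Heights are reported in
per-observation linkage units — raw distance divided by $\sqrt{n-1}$ — so
that the height between two standardized variables is $\sqrt{2(1-\rho)}$
independent of cohort size. The source figure's "50 Euclidean Linkage Units"
cutoff is tied to an unstated scaling and cannot be reproduced exactly; the
package's default cutoff of 1.2 (variables correlated above ~0.28 with the
core) was chosen a priori on this normalized scale and validated, not tuned,
on synthetic cohorts. Complete linkage is the default; single and average
are available (the source names no linkage).

`select_core()` cuts the tree and returns the flat cluster containing the
standardized cortisol-change anchor, minus the anchor and all other
HPA-axis/outcome variables — so the index can never leak outcome
information. `build_index()` then sums oriented z-scores; default
orientations make *lighter mothers, lighter infants, closer dyads and more
subordinate mothers* more vulnerable. The ambiguous "proximity (inverted)"
phrasing of the source is resolved as: vulnerability increases with
closeness, so the 1-5 *distance* score enters with orientation -1 (negated
once). Orientations are declared, never learned from the data.

On synthetic cohorts of 500 dyads the index correlates at least 0.8 with the
hidden vulnerability factor across seeds (the acceptance suite verifies
this over 20 seeds), and at 200 dyads the default pipeline recovers exactly
the four-variable core {maternal weight, dominance, infant weight, dyadic
distance} in ~98% of seeds.

## Numerical and design choices

* Sample (n-1) SDs everywhere; they reproduce the printed worked numbers.
* Two-sided p throughout; the pipeline's primary threshold is p <= 0.05
  without multiplicity correction, mirroring the exploratory source
  analysis, but the consolidated report appends a clearly-labelled
  supplementary Benjamini-Hochberg column over all collected p-values.
* The baseline split is at the *mean* (not median) of the baseline.
* Newman-Keuls post hoc testing uses the four group-by-time cell means with
  the pooled within-cell variance — a documented approximation to the
  mixed-design error the source does not specify.
* For the two-group pre/post design the interaction F is computed as the
  squared two-sample t on the change scores (an algebraic identity, tested);
  with a covariate it is the F of the group term in the least-squares model
  of the change score on group plus covariate, df (1, n-3).
* Exact-zero variance cases (constant deltas, perfectly proportional
  measures) return F = 0, p = 1 rather than 0/0, guarded by relative
  floating-point tolerances; genuinely undefined z-scores raise errors.
* Rank enters predictor contrasts as a dominance score (pen size + 1 -
  rank) by default so reported directions match the narrative text; the raw
  coding is available (`rank_coding = "raw"`). The source's printed rank
  correlation sign is consistent only under an unstated recoding, and its
  printed infant-sex correlation sign conflicts with its own text; both are
  surfaced, neither is silently "fixed".

## Problem sizes used in the validation suite

The packaged tests validate oracle equivalence with a $10^6$-draw
Monte-Carlo sample; permutation inference against exhaustive enumeration at
12 dyads ($2^{12}$ swap patterns); null calibration of the permutation and
Pitman-Morgan tests with 1000 replicate cohorts of 22 dyads; parameter
recovery at 500 dyads over 20 seeds; structure recovery at 200 dyads (30
seeds) and at the study size of 22 dyads (200 seeds); and generator moment
matching at $10^5$ dyads within 1%. These sizes give Monte-Carlo error
comfortably below each asserted margin.

## Known limitations

* The permutation contrast conditions on the observed dyads; with very few
  dyads its p-values are discrete (the add-one smoothing keeps them
  conservative).
* The Newman-Keuls error term ignores the pre/post correlation within
  dyads, like the classical mixed-design approximation it mirrors.
* The cross-sectional exposure analysis assumes linear weight effects and
  shares the small per-group sizes of the staggered design.
* The paper-literal Fisher mode is reported only as a historical
  reproduction; its p-value has no sampling interpretation.

## A complete run

```{r, eval = FALSE}
report <- run_pipeline(run_config(input = synthetic_config(), seed = 1,
                                  out_dir = "allostat-run"))
str(report$changes$cortisol)
report$index$core_variables
```
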