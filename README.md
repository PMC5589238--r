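# allostat

Change-score analytics and dyadic vulnerability indexing for pre/post
biomarker studies of **social allostasis** — the hypothesis that, under a
chronic group-level stressor, individual HPA-axis responses redistribute
bidirectionally so that the *group* mean stays constant while *individual*
changes are large.

The motivating setting is a cohort of socially housed primate mother-infant
dyads measured before and after prolonged foraging uncertainty: plasma
cortisol (µg/dl) shows ~20% mean individual change with near-zero group
change, while CSF corticotropin-releasing factor (CRF, pg/ml) rises ~24% at
the group level. The package asks, and equips others to ask: is the
cortisol pattern structured inversion — vulnerable dyads down, advantaged
dyads up — or a regression-to-the-mean artefact?

## What it computes

* **Change scores** (`compute_changes`) — per-dyad `post − pre`, percent
  changes, standardized deltas.
* **Change-score identity** (`change_identity`) — closed forms for
  `sd(Δ)`, `r(pre, Δ)` and `r(Δ, post)` from printed summary statistics
  `(s_pre, s_post, r)`:

  `sd(Δ) = √(s_pre² + s_post² − 2 r s_pre s_post)`,
  `r(pre, Δ) = (r s_post − s_pre)/sd(Δ)`,
  `r(Δ, post) = (s_post − r s_pre)/sd(Δ)`.

* **Allostasis ratio** (`ratio_determination`) — group-mean vs mean
  individual percent change per biomarker; permutation contrast between
  biomarkers (`contrast_measures_permutation`) plus a paper-literal Fisher
  mode (`fisher_2x2_literal`, reproduction only).
* **Baseline-split inversion** (`baseline_split_interaction`) with
  Newman-Keuls post hoc testing; **regression-to-the-mean diagnostics**
  (`rtm_diagnostics`, Pitman-Morgan plus a symmetric-inversion check).
* **Predictor contrasts** (`predictor_contrast`) of any covariate against
  the two standardized change scores; **cross-sectional exposure analysis**
  (`cross_sectional_analysis`) for staggered designs.
* **Variable clustering and the dyadic vulnerability index**
  (`cluster_variables`, `select_core`, `build_index`) — the oriented
  z-score sum over the core vulnerability variables (maternal weight
  inverted, rank toward subordinate, infant weight inverted, dyadic
  distance inverted).
* **Synthetic cohorts** (`synthetic_config`, `generate_cohort`) — a
  latent-vulnerability-factor generator calibrated to the printed cohort
  marginals, returning hidden truth for parameter-recovery validation.
* **One-shot pipeline** (`run_pipeline`) and a thin CLI
  (`inst/cli/allostat.R` with subcommands
  `simulate|changes|ratio|contrasts|index|run`).

## Worked example

The identity applied to the printed cortisol summaries (SDs 7.09 and 5.61,
pre/post correlation −0.24, n = 22):

```r
library(allostat)
change_identity(summary_stats(44.12, 7.09, 44.36, 5.61, -0.24, 22))
#> $sd_delta      10.04
#> $r_pre_delta   -0.84
#> $r_delta_post   0.73
```

So a −0.84 baseline-delta correlation is already implied by the printed
summary statistics — structured inversion must be argued with additional
diagnostics, which the package provides.

A synthetic cohort of 200 dyads run through the main stages:

```r
sim <- generate_cohort(synthetic_config(n_dyads = 200), seed = 1)
ch  <- compute_changes(sim$cohort)
ratio_determination(ch$cortisol_pre, ch$cortisol_post, "cortisol")
#> cortisol: group -1.1%  individual 19.6%  ratio 0.055
ratio_determination(ch$crf_pre, ch$crf_post, "crf")
#> crf:      group +23.6%  individual 69.7%  ratio 0.338
contrast_measures_permutation(ch, 9999, seed = 2)$p
#> 0.0031

core <- select_core(cluster_variables(sim$cohort))
#> "maternal_weight" "dominance" "infant_weight" "dyadic_distance_hfd"
res <- build_index(sim$cohort, core)
#> index vs delta-cortisol: r = -0.53, F(1,197) = 78.5, p = 5e-16
truth_recovery_report(sim$cohort, sim$truth, res$index)
#> 0.85
```

Cortisol's individual change (19.6%) dwarfs its group change (−1.1%) while
CRF moves at the group level too; the permutation contrast separates the
two regimes (p ≈ 0.003). Clustering recovers the four-variable vulnerable
core, the resulting index inversely predicts the cortisol change, and it
correlates 0.85 with the generator's hidden vulnerability factor.

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites (fixtures are generated in code).
* `vignettes/social-allostasis.Rmd` — the model, its assumptions, parameter
  defaults, numerical choices and limitations.
* `inst/cli/allostat.R` — command-line wrapper.
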