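---
title: "Thermogram deconvolution and diagnostic scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermogram deconvolution and diagnostic scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlbscore)
```

## The measurement and the model

Differential scanning calorimetry (DSC) of diluted blood serum records the
excess heat capacity $C_P(T)$ as the sample is heated through the thermal
denaturation range of the major serum proteins, roughly 45–90 °C. The
resulting curve — the serum *thermogram* — superposes the unfolding
transitions of albumin, the immunoglobulin classes and the other abundant
proteins. Disease states alter the serum proteome (relative abundances,
ligand binding, post-translational modification), and those alterations
reshape the thermogram even when no single tumor marker is measured. The
package implements a complete analysis chain that turns a cohort of such
traces into a per-subject probability score (PS) for having an unaltered,
healthy-like thermogram.

`tlbscore` is tidyverse-native: every user-facing function takes a data
frame first and returns a tibble, fitted objects have `tidy()`, `glance()`
and `autoplot()` methods, and the long thermogram table
(`subject_id`, `temperature`, `cp`) is the interchange format between
pipeline stages.

### Six-transition deconvolution

Each thermogram is modeled as a sum of six logistic (Hubbert) peaks plus an
offset,

$$C_P(T) = C_{P,0} + \sum_{i=1}^{6} \frac{4 A_i\, e^{-x_i}}{(1+e^{-x_i})^2},
  \qquad x_i = \frac{T - T_{c,i}}{w_i},$$

where $A_i$ is the apex height of transition $i$, $T_{c,i}$ its center and
$w_i$ its width. The factor 4 normalizes the bell so that the curve equals
$A_i$ exactly at $T_{c,i}$; it then equals $0.786\,A_i$ at $T_{c,i} \pm w_i$
and $0.420\,A_i$ at $T_{c,i} \pm 2 w_i$, which is the practical meaning of
the width parameter. All 19 parameters are fit per subject by bounded
Levenberg–Marquardt least squares (`minpack.lm`), with $A_i \ge 0$ and
$w_i \in [0.3, 15]$ °C.

**Peak identity.** Features downstream refer to "peak $i$", so the six
transitions must mean the same thing for every subject. Two mechanisms
enforce this. First, initial centers sit at six fixed anchor temperatures
spread evenly across the analysis window (`default_anchors()`). Second, each
fitted center is confined to a box around its anchor (default half-width:
half the anchor spacing). Without the boxes, a fit of six strongly
overlapping bells under realistic noise is ridge-degenerate — many parameter
sets reproduce the curve within noise, and centers wander by several degrees
between equally good local optima. The boxes select the optimum in the
basin of the anchored assignment, and the peaks are re-sorted by center
before return so indices are always in temperature order. Setting
`center_halfwidth = Inf` recovers the unconstrained fit.

**Numerical settings.** The optimizer runs with relative tolerance
$10^{-10}$ and is restarted from its last estimate until 2000 cumulative
iterations; non-convergence is reported as a flag, never an error, so batch
runs continue. Near-zero heights are retained (the result always has six
peaks); features that normalize by a height refuse to divide by anything
below $10^{-8}$ of the largest height and raise an error instead.

### The canonical grid

The moment and area features below are plain sums over grid points, so they
are only comparable across subjects when every trace sits on one shared
grid. The canonical window is 45–90 °C at 0.1 °C steps (configurable);
`resample_thermogram()` puts any trace there by linear interpolation.
Absolute magnitudes of the summed features scale with grid density — that is
documented behavior, irrelevant to classification because the grid is
shared cohort-wide. Baseline correction (`subtract_baseline()`) fits a
straight line through the mean points of two flat anchor windows and
subtracts it; negative heat capacity afterwards is kept, not clipped,
because clipping would bias the weighted moments (a warning fires when more
than 5 % of points go negative).

### The 14-parameter feature set

With $C_P(T_j)$ the resampled trace and $A_i$ the fitted heights:

* **Average temperature** $T_{av} = \sum_j C_P(T_j) T_j / \sum_j C_P(T_j)$ —
  the first moment of the thermogram read as a density.
* **Skewness** $G_1 = m_3 / m_2^{3/2}$ with weighted central moments
  $m_k = \sum_j C_P(T_j)(T_j - T_{av})^k / \sum_j C_P(T_j)$.
* **Normalized areas** $AUC_{ni} = \sum_j C_P(T_j) / A_i$ for $i = 2..5$.
* **Height-polygon areas**: the six heights on radar axes 60° apart bound a
  hexagon of area $(\sqrt3/4)\sum_{s=1}^{6} A_s A_{s+1}$ (cyclic,
  $A_7 \equiv A_1$); dividing by $A_i^2$ gives the scale-free $AP_{ni}$.
* **Distances** $Dv_i$: the Euclidean norm of the relative deviations of
  $(T_{av}, AUC_{ni}, AP_{ni})$ from the healthy-cohort medians
  (`compute_reference()`).

$T_{av}$ and $G_1$ are computed from the measured trace, not the fitted
model. All 14 features are invariant under a global positive rescaling of
$C_P$ — the analysis is deliberately independent of protein concentration
and instrument gain, so no unit normalization is attempted anywhere.

Two conventions in the polygon feature were genuinely open: the hexagon is
closed cyclically ($A_7 = A_1$, required for the six-term sum to be a
polygon area), and the constant is $\sqrt3/4$ (the area of a unit-side
equilateral triangle). Any fixed constant only rescales the feature
cohort-wide and cannot change the sign or significance of downstream
statistics.

### The probability score

Healthy is coded 1, so a binomial logit model gives the probability of an
*unaltered* thermogram:

$$PS = \frac{e^{\mu}}{1+e^{\mu}}, \qquad
  \mu = a_0 + \sum_k a_k p_k,$$

fitted by iteratively reweighted least squares (`stats::glm`, relative
deviance tolerance $10^{-10}$, at most 100 iterations). Three variants
differ only in the parameter set $\{p_k\}$: variant 1 uses the ten direct
parameters, variant 2 the four distances, variant 3 all 14. Features enter
raw (unstandardized), so coefficients are per-unit-of-feature; an affine
rescaling of a feature rescales its coefficient inversely and leaves every
PS unchanged. For a Bernoulli response the residual deviance is
$-2\log L$, hence AIC $=$ deviance $+\,2k$ and BIC $=$ deviance
$+\,k\log n$ with $k$ coefficients including the intercept; nested variants
are compared by referring deviance differences to a $\chi^2$ with the
difference in $k$ as degrees of freedom (`compare_models()`).

A subject with $PS$ above the threshold (default 0.5) is classified
*negative* (unaltered, healthy-like), below it *positive* (altered). A score
exactly at the threshold is classified positive — the conservative choice
toward clinical follow-up; the strict inequalities leave the tie undefined
otherwise. Because the distance features are nonlinear functions of the
direct ones, the full model can approach quasi-separation on well-separated
cohorts; this is detected and flagged, and an optional ridge penalty
(`lambda > 0`, via glmnet) is available. The default remains plain maximum
likelihood.

**Evaluation.** Positives are the diseased. `confusion_metrics()` reports
accuracy, sensitivity, specificity and the diagnostic odds ratio
$DOR = (tp \cdot tn)/(fn \cdot fp)$, applying a Haldane–Anscombe $+0.5$
correction only when a zero cell occurs (and flagging it). Confidence
intervals are Clopper–Pearson exact for the three proportions and Woolf
log-normal for the DOR; the methods behind published intervals of this kind
are rarely stated, and the Woolf upper endpoint can differ from a printed
value by one unit in the last digit.

**Leave-one-out.** `loo_cv()` refits the model $n$ times, excluding one
subject per fold. By default the healthy reference medians behind the
$Dv_i$ features are recomputed from the HC members of each training fold,
so no information about the held-out subject leaks into its own features.
This is the stricter protocol; `reference_policy = "fixed"` reproduces the
simpler one (reference computed once from all HC subjects), which published
analyses may implicitly have used — the difference is small on cohorts of
this size but systematic.

### Univariate statistics

Per-parameter screening uses quartiles (`stats::quantile` type 7, linear
interpolation — the convention is configurable nowhere, but stated
everywhere it matters), an adapted Cohen $d$ (median difference over the
size-weighted pooled IQR; pooling weights are the group sizes), ROC analysis
with the Youden cut-off, the Kruskal–Wallis rank test and Fisher's exact
test. The Youden search scans midpoints between consecutive sorted unique
values in both orientations and maximizes $J = $ sensitivity $+$
specificity $- 1$, breaking ties toward higher specificity, then lower
threshold; it is tested against an exhaustive brute-force search and against
pROC.

## The synthetic cohort generator

No clinical thermograms ship with the package, so `generate_cohort()`
creates labeled cohorts for end-to-end validation. Its defaults *are* the
study conditions of the package's tests and acceptance script:

* **Cohort sizes** 85 healthy controls and 114 lung-cancer patients.
* **Canonical profile**: six transitions at 50, 57, 64, 70.5, 77 and 84 °C
  with heights 0.30, 0.70, 1.00, 0.60, 0.45, 0.20 and widths 1.5–2.0 °C —
  a stylized healthy serum profile with the dominant transition in the low
  60s. The separations are wider than in real serum, where the transitions
  overlap strongly; they are chosen so that the 19-parameter deconvolution
  is well-posed at the simulated noise level and ground-truth recovery is
  testable. This is a stated limitation: passing recovery tests here does
  not show that a real, heavily overlapped serum trace yields equally
  stable per-peak parameters.
* **Healthy variability**: heights lognormal around the canonical values
  (CV 8 %, mean-preserving), centers jittered with SD 0.25 °C, widths with
  SD 0.10 °C, plus Gaussian measurement noise with SD 0.5 % of the
  subject's maximum height — a homogeneous group.
* **Disease effect**: every patient receives a common perturbation —
  second and fourth transitions gain height, the dominant third and the
  fifth lose, the hottest sixth gains most, and all centers drift slightly
  upward — plus one of three modes (`transfer`, `shift`, `hightail`,
  weights 0.5/0.25/0.25), all scaled by the effect size `delta` and
  subject-specific lognormal magnitudes. Patient dispersions are inflated
  by $1 + 0.6\,\delta$ — a heterogeneous group. The direction of the common
  component was chosen from a sensitivity analysis of $(T_{av}, G_1)$ with
  respect to each peak parameter so that the group medians of
  $T_{av}, G_1, AUC_{n3}, AP_{n3}$ move up and $AUC_{n4}, AP_{n4}$ move
  down, the directional pattern reported for clinical cohorts.
* **Effect size**: `delta = 0.5`, calibrated once by seeded simulation so
  that the full model's held-out accuracy lands in the high-80s percent
  range with visible class overlap (resubstitution ≈ 91 %, leave-one-out
  ≈ 87 % at the default seed) — a realism target for the simulation, not a
  claim of reproducing any patient data. `delta = 0` makes the two groups
  exchangeable.

All randomness flows from a single integer seed; cohorts are bit-identical
across runs given the same seed.

## Worked example

```{r pipeline, eval = FALSE}
library(tlbscore)

cohort <- generate_cohort(generator_config(), seed = 1)
fs <- featurize_cohort(cohort$thermograms, cohort$metadata)

model <- fit_score_model(fs$features, variant = 3)
ps <- predict_ps(model, fs$features)
confusion_metrics(fs$features$group, classify_ps(ps))

loo <- loo_cv(fs$features, variant = 3)
glance(loo)
plot_ps_distribution(tidy(loo))
```

The problem sizes used by the test suite and the acceptance script — one
199-subject cohort at the default conditions, two reduced-effect cohorts
for the monotonicity check, 20 noisy deconvolution replicates and 50
logit-recovery cohorts of 500 subjects — were chosen so the whole validation
runs in a few minutes on a single core while keeping every Monte-Carlo
assertion comfortably away from its threshold.

## Known limitations

* The two-anchor linear baseline is a simple stand-in for instrument-side
  baseline handling; laboratory pipelines often use proprietary corrections
  whose details are unpublished.
* The generator's transitions are more separated than in real serum, and
  its disease modes are phenomenological, not biophysical; conclusions
  about classifier architecture transfer, conclusions about absolute
  clinical performance do not.
* Quartile, Cohen-d pooling and confidence-interval conventions follow the
  common defaults stated above; published tables computed under other
  conventions can differ in the last printed digit.
* The number of transitions is fixed at six; the package deliberately does
  not perform model selection over peak counts, nor thermodynamic
  (two-state) interpretation of the fitted transitions.
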