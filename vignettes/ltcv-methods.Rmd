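---
title: "Methods: psychometric analysis of the looming contrast assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometric analysis of the looming contrast assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcv)
```

This vignette is the package's own account of its methods: the stimulus
model, the statistical pipeline, the synthetic-data generator used to
validate it, and the design decisions taken where the procedure admitted
more than one defensible reading.

## The stimulus

A looming presentation is a deterministic sequence of phases: the dark disk
expands from radius 0 to `r_max` over 0.5 s, holds at `r_max` for 0.5 s,
disappears, and after a 0.5 s gap the cycle repeats, three times in total.
There is no gap after the final hold, which is what makes the arithmetic
close: 3 × (0.5 + 0.5) + 2 × 0.5 = 4 s per presentation. `build_timeline()`
lays the phases out and `disk_radius()` evaluates the radius anywhere on the
timeline.

Two conventions here were genuinely open and are package decisions, not
assay facts:

- **Expansion profile.** Only the endpoints of the expansion are specified
  (0 to `r_max` in 0.5 s). We default to *linear radius growth* and expose
  the profile as an injectable function
  (`stimulus_config(expansion_profile = )`), so a constant-angular-speed or
  accelerating profile can be substituted without touching anything else.
- **`r_max` as on-screen radius.** `r_max` (20 cm rat, 15 cm mouse) is
  treated as a physical radius on the ceiling monitor, not a projected
  visual angle; no viewing-distance conversion is applied anywhere.

Contrast is quantified by the Michelson index
`MI(%) = (Id − Ib)·100/(Id + Ib)` from the irradiance of the fully expanded
disk (`Id`) and of the background alone (`Ib`), measured at the arena
center in the same instrument units — MI is unit-invariant, so no unit
layer is needed. Dark disks give negative MI; all modeling uses the
**magnitude** `|MI|` as the covariate, because the assay's dark-disk ranges
are naturally ordered by |MI| while the sign merely records polarity. Weber
contrast is reported alongside as `(Id − Ib)/Ib`; that formula is this
package's declared convention (the measure is named in the assay literature
without a printed formula), and outputs label it as such.

Session schedules are uniform seeded permutations of the R×C trial list
(each of C levels exactly R times) — plain Fisher–Yates randomization with
no anti-repetition constraint, since unconstrained randomization is the
reference behavior; a `no_immediate_repeat` flag exists but is off by
default. The emitted plan carries *earliest-allowed* onset times spaced by
the presentation duration plus the 30 s minimum inter-stimulus interval:
in the live assay stimuli are triggered manually when the animal is near
the arena center, so real onsets can only be later than planned, never
closer together.

## Scoring

Each presentation is scored by three masked observers. The aggregation
rule is a package decision: per-stimulus **majority vote** on the response
label, with two tie rules — (1) if the top label is tied but more
observers saw *some* response than saw none, the trial is positive and the
label tie is broken deterministically (lexicographically first among the
tied response labels, configurable); (2) a response/none tie without a
response majority stays negative. Any stereotyped response counts as
positive, with no severity weighting — the assay reads detection, not
response intensity. Species-invalid labels (head bobbing in a mouse sheet,
running in a rat sheet) indicate scoring errors and are rejected in strict
mode (default) or dropped with a warning in lenient mode; strict mode also
requires exactly the designed number of observers per trial.

The unit of analysis is the per-animal per-contrast response frequency:
positives over the fixed number of stimuli applied at that contrast.

## The psychometric model

The response frequency is modeled as grouped-binomial with a logit link:

$$y_{ij} \sim \mathrm{Binomial}(n_j, p_{ij}), \qquad
\operatorname{logit}(p_{ij}) = \beta_0 + \beta_1 x_j + \gamma^\top z_i$$

with \(x_j\) the contrast magnitude in percent (0–100, uncentered — so the
C50 lands directly on the contrast axis) and \(z_i\) optional factors (sex,
age, time-of-day window, treatment, genotype, animal identity).

`fit_logit_glm()` maximizes the likelihood by iteratively reweighted least
squares, written out rather than delegated: working response
\(z = \eta + (y/n - \mu)/(\mu(1-\mu))\), weights \(n\mu(1-\mu)\), weighted
least squares per iteration. Numerical choices, all configurable through
`irls_control()`:

- convergence when the relative change of the coefficient vector drops
  below 1e−8 (default), max 100 iterations; non-convergence is reported in
  the fit object, never silently;
- fitted probabilities are clamped to `[1e−10, 1 − 1e−10]`; any fitted
  value pinned at the clamp at convergence raises the `separation_flag`
  (a covariate perfectly predicting the response makes coefficients, and
  hence C50, undefined);
- starting values come from the empirical proportions shrunk away from
  0/1; the coefficient covariance is the inverse Fisher information at the
  final weights; the log-likelihood includes the binomial constant so AIC
  agrees with the standard definition for grouped data.

Model construction is bottom-up: starting from the magnitude-only base
model, `stepwise_aic()` greedily adds the candidate term that lowers AIC
most, keeping it only on a *strict* decrease, and stops otherwise. The
"ANOVA between models" is realized as the likelihood-ratio chi-square
between nested fits (`lr_test()`) — the standard deviance-ANOVA reading
for GLMs. Collinear candidates are rejected through the singular-design
check rather than entering with aliased coefficients.

Pairwise factor contrasts (`tukey_contrasts()`) are Wald contrasts on the
logit scale with the **single-step multivariate-normal adjustment**: each
adjusted p is the tail probability of the maximum absolute component of a
multivariate normal with the contrasts' correlation matrix (the Tukey-type
adjustment for non-orthogonal GLM contrasts), with Bonferroni available as
a fallback. Odds ratios `exp(estimate)` carry family-wise intervals from
the equicoordinate normal quantile. For a family of size one this reduces
exactly to the unadjusted two-sided Wald test. The adjustment is checked
in the test suite against an independent multiple-comparison
implementation to quasi-Monte-Carlo accuracy.

### C50

For a logit-linear model the 50% point is where the linear predictor
vanishes: \(C_{50} = -(\beta_0 + \gamma^\top z)/\beta_1\), computed
profile-wise so magnitude-by-factor interactions are handled (the slope is
the predictor difference between magnitude 1 and 0 at that profile).
Uncertainty is by the delta method on the coefficient covariance by
default; a parametric bootstrap (binomial resamples of the fitted
probabilities, refit, percentile interval) is available and seeded. A C50
is only reported when the fit converged, is not separated, and the slope
is positive; otherwise `valid = FALSE` with a machine-readable reason —
never a numeric threshold. This is what a never-responding cohort (e.g. a
genotype lacking all photoreceptor classes) produces.

**Per-animal route.** Sessions are thin (5 levels × 3 reps for rats,
6 × 4 for mice) — too thin for stable per-animal slopes. The default
`per_animal_c50()` therefore fits one cohort model with a **shared
magnitude slope and per-animal intercepts** and inverts each animal's
curve; fully independent per-animal fits are exposed via
`method = "independent"` for well-powered designs. Animals with all-zero
or all-one response vectors are flagged invalid up front and excluded from
the shared fit so they cannot destabilize it.

**Group comparison.** `compare_c50_groups()` runs Bartlett's
homoscedasticity test first and, when equal variances are not rejected at
the configured α, the pooled-variance two-sample t-test. The
heteroscedastic branch is not part of the reference procedure, which is
silent on it; we substitute Welch's test but flag it explicitly
(`welch_fallback = TRUE`) rather than silently.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable with
known ground truth. It emulates the assay's design exactly: the rat
session is 5 contrast levels × 3 repetitions (15 stimuli), the mouse
session 6 × 4 (24 stimuli), randomized per animal. Since the calibrated
per-level contrast values live in supplementary material rather than the
main text, the generator's default magnitudes are a package choice made
once: 20/40/60/80/100% for rats and 15/30/45/60/75/90% for mice — evenly
spanning "low enough that controls never respond" to "high enough that
they always do", which is how the assay's range is constructed.

Ground truth per group: response probability
\(\mathrm{logit}^{-1}(s\,(x - c_i))\) with slope \(s\) (default 0.1 per
percent) and animal thresholds \(c_i \sim N(C_{50}, \sigma_a)\). Default
\(C_{50} = 50\%\) (mid-range) and \(\sigma_a = 5\%\): at the assay's
group sizes (5–7 animals) this yields the between-animal scatter and
group separations qualitatively seen in real cohorts. Between-animal
variability is placed on the *C50 scale*, not the logit-intercept scale,
because "this animal's threshold is 5 points higher" is the interpretable
statement; the two differ only by the slope factor. A `non_responder`
profile forces probability 0 everywhere (the triple-knockout pattern).
Response *types* are drawn from a contrast-dependent categorical whose
weights shift from head-bobbing/rearing at low contrast toward
freezing/running at high contrast — qualitatively emulating the observed
mixes, with no quantitative claim. Observer noise is an optional symmetric
label-flip per observer (default 0) to exercise the consensus step.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: habituation and sequential dependence across
trials, manual-triggering selection effects, inter-observer bias that is
correlated rather than independent, overdispersion beyond the
animal-threshold mixture, and any lapse/guess-rate asymptote (the model's
upper asymptote is 1, matching the assay's reported full-response plateau
in controls).

## Validation and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch at run
time: the design constants (4 s presentation; 15/24-trial sessions; 20/15
cm expansion endpoints; ≥ 30 s onset spacing; the hand value
MI(13, 39) = −50); agreement of the IRLS optimum with an independent
iterative-zoom grid search of the likelihood (within 1e−6) and with the
reference GLM fitter (coefficients within 1e−6) on 50 random small
instances; group-C50 recovery bias below 5% over 200 simulated mouse
cohorts (7 animals, true C50 50, slope 0.1); the type-I error of the group
comparison on identical simulated cohorts over 2000 seed pairs (full
pipeline: simulate → frequencies → per-animal C50 → Bartlett + t), which
should sit in [0.03, 0.07] at α = 0.05; the invalid-flagging of
never-responding cohorts; and bit-identical demo reruns under a fixed
seed. These sizes (200 and 2000 replicates) were chosen so the Monte-Carlo
standard error is small against the acceptance bands while the whole suite
stays comfortably runnable on a laptop core.

## Known limitations

- Fixed-effects only: animal identity enters as a fixed intercept, not a
  random effect; no GLMM machinery (Laplace/AGQ) is included, and no
  simulated-quantile residual diagnostics.
- The single-step adjustment is our implementation of the Tukey-type
  contrast correction; equivalence with any specific external
  implementation is verified empirically in tests, not claimed
  analytically.
- The delta-method C50 interval is symmetric and can be poor near
  separation; the bootstrap option is the remedy.
- `render_frames()` is an offline visualization (normalized gray values,
  background 0.5, disk `0.5(1 + MI/100)`); it makes no claim about monitor
  gamma or absolute luminance, and there is no real-time display or rig
  I/O.
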