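---
title: "Movement-level process modeling of bimanual suturing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-level process modeling of bimanual suturing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturespm)
library(dplyr)
```

## The model

`suturespm` analyses microsurgical suturing at *movement level*. Each hand's
behaviour over time is annotated as a sequence of elementary activities: an
`<action;target>` tuple with one of four actions (`move`, `transport`,
`hold_still`, `grasp`) applied to one of four targets of interest (`needle`,
`incision`, `thread`, `tool`), plus two special labels — `idle` for
nonproductive movement with no definable target (typically one hand waiting
while the other works) and `not_visible` when the tool leaves the field of
view. That yields an 18-symbol alphabet (4 × 4 + 2). A suture is divided
top-down into five ordered segments — needle transport, piercing, and three
knots — and each segment carries one interval sequence per hand, tiling the
segment's span with no gaps: unannotated time inside a segment is not
permitted, the annotator must label it `idle` or `not_visible`, so the
nonproductive-time quantity below is unambiguous. The target is a *target of
interest*, not a direction of motion: extracting the thread away from the
incision is still `<transport;incision>`.

Time is continuous seconds rather than video frames: annotation tools work
frame-by-frame, but durations are what the model consumes, and seconds are
frame-rate-agnostic.

### Preprocessing: merging very short activities

Annotations at movement granularity produce spurious sub-second fragments
(a brief pause mid-transport, a flicker of relabeling).
`merge_short_activities()` absorbs every interval shorter than 0.5 s into the
previous activity; a short *leading* interval, which has no predecessor, is
absorbed by its successor. After absorption, adjacent intervals with equal
labels are coalesced, and the rule is iterated to a fixed point, so no
sub-threshold interval survives unless a whole sequence collapses to a single
interval. Total annotated time is conserved exactly (durations are summed,
then boundaries recomputed). Coalescing makes interval counts canonical —
without it, the same timeline could be represented by different row counts.

### Activity vectors

For each analysis unit (a suture, or one segment of a suture) and each hand,
the durations spent on each label are accumulated into a nonnegative vector
over the vocabulary and normalized to unit Euclidean length. A suture-level
vector pools the raw durations of the suture's segments *before*
normalization (the alternative — averaging normalized segment vectors — would
weight a 5-second segment equally with a 50-second one). Normalization makes
vectors describe movement *composition*, invariant to how long the task
took; `build_vectors()` is therefore exactly invariant under uniform time
rescaling.

Three vocabulary variants are supported for the robustness re-analysis:
`full18` (all labels), `actions_special6` (targets collapsed onto actions,
idle and not-visible kept), and `actions_only4` (only the four actions; idle
and not-visible durations are *dropped before normalization*, the minimal
reading of "actions only" — a unit that is entirely idle then has no
in-vocabulary time and is skipped, with skips counted and reported).

### Similarity scoring

The similarity of two units of the same hand, level and vocabulary is the
cosine of the angle between their vectors — for unit-length nonnegative
vectors, the dot product, in [0, 1]. Each unit is scored by its mean
similarity to all expert units and to all novice units in the dataset,
always excluding the unit's own participant (the only leakage control; the
scoring is deliberately in-sample otherwise). The skill score is the
difference, expert minus novice mean similarity: positive values are
expert-like. Two design points deserve emphasis:

* segment-level pools contain only *same-type* segments (knot 1 against
  knot 1, and so on) — comparing a piercing to a knot would conflate task
  phase with skill;
* group means are unweighted over eligible units, not per-participant means
  of means, so participants contributing more sutures weigh more in the
  pool. Missing trailing knots of incomplete sutures simply contribute no
  vector.

### Efficiency

For one hand over a unit of total annotated duration $T$, with $t_w$ the
time labelled `idle` or `not_visible`, suturing efficiency is
$S_{eff} = (T - t_w)/T$. Bimanual efficiency is $B_{eff} = t_B/T$ where
$t_B$ is the length of the exact intersection of the two hands' productive
interval sets — time when *both* hands simultaneously carry one of the 16
`<action;target>` labels. `hold_still` with a target is productive (holding
an incision open is work); `not_visible` counts in $T$ and in $t_w$, on the
assumption that nothing productive happens off camera. The intersection is
computed by an event-boundary sweep, never by sampling; a 1 ms
timeline-sampling implementation exists only as an independent oracle in the
test suite. These definitions force $0 \le B_{eff} \le
\min(S_{eff,L}, S_{eff,R}) \le 1$ and additivity of $T$ and $t_w$ from
segments to sutures, both asserted as invariants.

### Group statistics

Suture-level outcomes (similarity difference, $S_{eff}$ per hand,
$B_{eff}$) are compared between skill groups with a linear mixed model,
`outcome ~ group + (1 | participant)`, fitted by REML; repeated sutures by
the same participant motivate the random intercept. The novice-vs-expert
contrast is tested with a t test using Satterthwaite degrees of freedom
(`lmerTest`), and the 95% interval is t-based with those df. Outcomes are
analysed untransformed although they live on bounded scales; values within
0.01 of a bound trigger a warning rather than an automatic transform, and a
Brown–Forsythe check (`variance_homogeneity_check()`, absolute deviations
from group medians) is provided as the accompanying spread diagnostic.

Segment-level outcomes are modelled as `outcome ~ group * segment` with the
participant random intercept, *residual variances allowed to differ by
segment-by-skill cell* (an `nlme::varIdent` structure — at segment level the
spread of bounded outcomes varies visibly across cells), sum-to-zero
contrasts, and marginal (type III) F tests for skill, segment and their
interaction. "Segment- and skill-dependent variances" admits more than one
reading; cell-wise residual variance is the common remedy for exactly this
diagnostic and is what is implemented. If the heteroscedastic fit fails to
converge, the model falls back to a common residual variance and the result
is flagged (`heteroscedastic` attribute), never silently.

The suite calibrates both models by simulation: interval coverage of the
suture-level contrast is checked at a generative geometry of a −0.20
contrast, 0.11 participant SD and 0.05 residual SD over 5 + 5 participants ×
5 sutures (200 replicates, coverage required in 93–97%), and the type III
interaction test is required to hold its 5% size within ±2 points under a
null generative model (500 replicates).

### Target-label noise

Of the two halves of a tuple, the *target* is the interpretable one — whether
a tool is moving or grasping is nearly unambiguous on video, but which
structure the action concerns can be debatable. `inject_target_noise()`
therefore corrupts only targets: each targeted interval independently, with
probability `p`, has its target resampled uniformly from the three *other*
targets, so `p = 1` means every targeted label has changed. Actions, `idle`
and `not_visible` are untouched.

Two consequences are worth stating plainly:

* **Efficiency is exactly invariant** under this corruption at any `p`,
  because $t_w$ and $t_B$ depend only on whether a label is special, which
  switching never alters. A study that observes efficiency degrading under
  target noise has implicitly also moved labels into or out of the no-target
  class; `inject_target_noise(..., mode = "idle")` emulates that (relabeling
  hit intervals as `idle`), and is off by default.
* **Switching among the other three targets does not fully erase target
  information.** It maps a group's target share $q$ to $(1-q)/3$, an affine
  map, so about a ninth of the squared between-group target separation
  survives even at `p = 1`. On synthetic cohorts whose groups differ only in
  targets, the similarity separation collapses to near — but provably not
  exactly — zero; on cohorts whose groups differ in action mixtures it
  persists essentially undiminished. Both behaviours are asserted in the
  suite.

`noise_sweep()` re-runs selected analyses over a probability grid (default
0–1 in steps of 0.1, 20 replicates per point; single-threshold reports
without replication hide Monte-Carlo error) and summarises, per contrast,
the largest grid `p` such that every grid point up to it is significant at
α = 0.05 in a majority of replicates.

## The synthetic generator

No annotation corpus ships with the package; `generate_dataset()` produces
cohorts with the statistical structure the analysis assumes, and its
defaults *are* the study conditions: 5 experts and 5 novices, 5 sutures
each, 5 segments per suture, two hands tiling identical spans.

Per (group, hand, segment) the generator holds a mixture over the 18 labels,
built from marginal action and target probabilities tilted toward the
segment's natural target (needle during needle transport, incision during
piercing, thread during knots). Interval durations are log-normal
(`meanlog = log 2`, `sdlog = 0.6` — positive, right-skewed, a few seconds
typical, as movement times are), and segment spans are log-normal around
15 s (needle transport), 25 s (piercing) and 20 s (knots). A per-participant
random effect shifts the logit of the nonproductive share — keeping
efficiencies inside (0, 1) and inducing the within-participant correlation
the random-intercept models assume — with the baseline logit chosen
numerically so the *marginal* nonproductive fraction equals the profile's
target despite the nonlinear transform. Its default SD of 0.5 on the logit
scale corresponds to roughly 0.11 SD on the efficiency scale at a novice
operating point.

Calibration of the default profiles: novice left-hand (microforceps)
nonproductive share 0.32 against 0.121 for experts, and right-hand
(needleholder) 0.17 against 0.066 — relative efficiency gaps of about 29%
and 13%. Hands are coupled through `bimanual_overlap`, a [0, 1] propensity
with 0.5 meaning independence: the left hand's nonproductive probability at
a moment is shifted by $\rho\,(I_R - p_R)$ with $\rho = 2(\text{overlap} -
0.5)$, which preserves the marginal share while correlating the hands.
Experts default to 0.60 (mild coordination), novices to 0.45 (mild hand
alternation — one hand idling while the other works, the characteristic
novice pattern), which places the relative bimanual efficiency gap near
45–48% at scale. Expert and novice action and target mixtures also differ,
so the similarity signal lives in both halves of the tuple;
`default_profiles("targets_only")` and `default_profiles("actions_only")`
isolate one half each, with equal nonproductive shares and neutral coupling,
for the noise study. Incomplete sutures (missing third knot) are generated
with configurable probability, default 0.

What the generator deliberately does **not** emulate: annotator hesitation
and boundary jitter (activities switch instantaneously), serial dependence
of consecutive activities (labels are drawn independently given the
mixture), grammar-like ordering of activities within a segment, learning or
fatigue across sutures, and any kinematic content. Passing tests on this
synthetic therefore show that the pipeline's *statistical machinery* behaves
as designed under the assumed structure — not that real annotated cohorts
satisfy that structure.

```{r demo}
d <- generate_dataset(synthetic_config(seed = 1))
eff <- efficiency_table(d, level = "suture")
eff |> group_by(group) |>
  summarise(across(c(s_eff_left, s_eff_right, b_eff), mean))
suppressWarnings(suture_level_lmm(eff, "s_eff_left"))[
  , c("estimate", "ci_low", "ci_high", "p_value", "random_intercept_sd")]
```

## Numerical choices and degenerate inputs

* Interval arithmetic uses a 1 μs tolerance for gap/overlap/span checks;
  merging conserves total time to better than 1 ns by summing durations and
  recomputing boundaries.
* `unit_normalize()` refuses all-zero vectors with an explicit
  "no in-vocabulary activity time" error; `build_vectors()` converts such
  per-item errors into counted skips rather than failures, and
  `reduced_vocabulary_analysis()` aborts if more than half the items skip.
* `group_similarity()` errors, naming the group, when self-exclusion empties
  a pool (e.g. the only expert scoring themselves) rather than returning
  `NaN`.
* Mixed-model edge cases: singular fits are flagged (`singular` column), not
  hidden; fewer than two participants per group is an error, since the skill
  contrast would be confounded with a participant.
* All stochastic entry points (`generate_dataset()`,
  `inject_target_noise()`, `noise_sweep()`) take mandatory seeds, use an
  isolated RNG scope, and are bit-for-bit reproducible; sweep cell seeds are
  derived from the master seed.

## Problem sizes used by the shipped checks

The package's own verification uses cohorts of 5 + 5 participants × 5
sutures for parameter recovery (50 replicates), 200 and 500 replicates for
the two statistical-calibration simulations, ~1,200 sutures for the
generator's nonproductive-share calibration check, and 100 + 100
participants × 5 sutures in `scripts/acceptance.R` for stable estimates of
the generative efficiency gaps. These sizes were chosen to keep Monte-Carlo
error comfortably below the assertion margins.

## Known limitations

* The similarity score is in-sample: pools are drawn from the same dataset
  being scored. With own-participant exclusion this is the intended design,
  but scores are not out-of-sample classifier outputs, and no ROC-style
  machinery is provided.
* Movement-level composition cannot see precision: two performances with
  identical label durations but very different needle placement are
  indistinguishable.
* The heteroscedastic segment-level model reads "segment- and
  skill-dependent variances" as cell-wise residual variance; other variance
  structures (e.g. segment-dependent random-effect variances) are plausible
  and not implemented.
* `actions_only4` drops out-of-vocabulary time before normalization; an
  alternative (renormalizing over a 5th "other" bin) would change reduced-
  vocabulary similarities.
* Handedness is recorded but never modelled; the analysis treats the left
  hand as microforceps and the right as needleholder regardless.
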