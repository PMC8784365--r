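# suturespm

Movement-level surgical process modeling of bimanual microsurgical suturing,
for surgical data scientists and educators who want objective, reproducible
skill measures from timed tool-activity annotations.

## What it computes

The package models each hand's behaviour during a suture as a timeline of
elementary activities — `<action;target>` tuples over four actions (*move*,
*transport*, *hold still*, *grasp*) and four targets of interest (*needle*,
*incision*, *thread*, *tool*), plus *idle* (nonproductive movement) and
*not visible* — 18 labels in all. A suture is split into five ordered
segments (needle transport, piercing, three knots), each tiled by both
hands' interval sequences. On top of that representation it provides:

* **Activity vectors** — per suture or segment and per hand, durations are
  accumulated over the vocabulary and normalized to unit Euclidean length,
  so vectors encode movement composition independent of pace.
* **Similarity skill scores** — the similarity of two units is the cosine
  `cos θ = sv_i · sv_j` of their unit vectors; each unit gets its mean
  similarity to expert and to novice units (own participant excluded) and
  the difference, positive = expert-like.
* **Efficiency** — per hand, `S_eff = (T − t_w)/T` with `t_w` the
  idle/not-visible time; bimanually, `B_eff = t_B/T` with `t_B` the exact
  interval-intersection time during which both hands are simultaneously
  productive.
* **Group statistics** — suture-level linear mixed models
  `outcome ~ skill + (1 | participant)` with Satterthwaite t tests;
  segment-level `skill × segment` models with cell-wise residual variances
  and type III F tests; Brown–Forsythe spread diagnostics.
* **Robustness analyses** — target-label corruption over a probability grid
  (actions are considered reliable, targets interpretable) and re-analysis
  under reduced vocabularies (actions + specials, or actions only).
* **A calibrated synthetic generator** — study-shaped cohorts (5 + 5
  participants × 5 sutures × 5 segments, two hands) with group-dependent
  activity mixtures, nonproductive shares, participant random effects and
  bimanual coupling, so the whole pipeline runs and is testable without any
  recorded data.

The annotation format is plain delimited text (comma or tab), one interval
per row, with header
`participant_id,group,handedness,suture,segment,hand,start_s,end_s,action,target`.

## Worked example

```r
library(suturespm)
library(dplyr)

d <- generate_dataset(synthetic_config(seed = 1))  # 10 participants, 50 sutures
d <- merge_short_activities(d)                     # absorb < 0.5 s fragments

eff <- efficiency_table(d, level = "suture")
eff |> group_by(group) |> summarise(across(c(s_eff_left, s_eff_right, b_eff), mean))
#>   group  s_eff_left s_eff_right b_eff
#> 1 expert      0.867       0.927 0.819
#> 2 novice      0.675       0.841 0.560

suture_level_lmm(eff, "s_eff_left")
#>   estimate ci_low ci_high p_value random_intercept_sd
#> 1   -0.192 -0.298  -0.086 0.00309              0.0673

similarity_table(d, level = "suture", hand = "left") |>
  group_by(group) |> summarise(mean_difference = mean(difference))
#>   group  mean_difference
#> 1 expert           0.139
#> 2 novice          -0.258
```

Reading the numbers: novices in this cohort spend about a third of their
left-hand (microforceps) time nonproductively versus ~13% for experts; the
mixed model estimates the novice deficit in left-hand efficiency at −0.19
(95% CI −0.30 to −0.09, participant SD 0.07), and the cosine skill score
separates the groups by sign — experts' sutures are closer to other experts
(+0.14), novices' to other novices (−0.26).

Segment-level comparisons and the noise study follow the same pattern:

```r
segment_level_anova(efficiency_table(d, "segment"), "s_eff_left")
#>            term       F num_df den_df  p_value
#> 1         skill 16.4166      1      8 0.003675
#> 2       segment  0.5157      4    232 0.724233
#> 3 skill:segment  0.2671      4    232 0.898916

sw <- noise_sweep(d, p_grid = seq(0, 1, 0.2), replicates = 10, seed = 1)
attr(sw, "survival")   # largest corruption p at which each contrast survives
```

The single-command pipeline writes a full report bundle (similarity and
efficiency tables, model results, manifest with checksums):

```r
run_full_analysis(run_config(
  synthetic = synthetic_config(seed = 1),
  output_dir = "out", seed = 1))
```

or, from a shell, via the thin CLI:

```sh
Rscript inst/cli/suturespm.R analyze --output-dir out --seed 1
```

## Going further

The methods vignette
(`vignettes/movement-level-process-model.Rmd`) documents the model and its
assumptions, the statistical choices (variance structures, untransformed
bounded outcomes, Satterthwaite tests), what the synthetic generator does
and does not emulate, and known limitations.
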