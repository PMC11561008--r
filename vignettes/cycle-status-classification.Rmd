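---
title: "Menstrual cycle status classification: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Menstrual cycle status classification: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclehealth)
```

`cyclehealth` is a rule engine, not a statistical model: its value lies in
being exactly and auditably the published decision logic. This vignette
records the model, the conventions chosen where the published material
leaves room, and what the test evidence does and does not show. Nothing
here is a diagnosis; every concerning classification carries only a
"medical review required" flag.

## The decision model

Classification is a walk through a binary tree whose adjacency is shipped
as data (`inst/extdata/decision_tree.yaml`). The root resolves menarche
status, hormonal contraception, and amenorrhea; the natural-cycle subtree
then classifies each closed cycle on five kinds of evidence:

| Evidence | Tier | Criterion (default) |
|---|---|---|
| cycle length | 0 | regular 21–35 d inclusive; > 35 prolonged; < 21 short |
| bleed onsets / year | 0 | > 9 naturally menstruating; ≤ 9 oligomenorrheic |
| urinary LH tests | 2 | any positive → ovulation *probable*; all negative → anovulatory |
| luteal length | 2 | next bleed < 14 d after the positive test → short luteal phase |
| mid-luteal serum P4 | 3 | > 16 nmol/L eumenorrheic; measurable ≤ 16 luteal phase defect; any measurable P4 *confirms* ovulation |

Two non-obvious commitments follow from the published criteria:

* **Probable never promotes to confirmed.** A regular cycle with a positive
  LH test but no blood draw stays at `B1_PROBABLE_OV`. The confirmatory
  mid-luteal draw is the only path to `C1`/`D1`.
* **Exact boundary semantics** are: length 35 is regular and 36 prolonged;
  21 regular and 20 short; P4 16.0 is a defect and 16.5 eumenorrheic
  (strict `> 16`); luteal 13 is short and 14 is not (strict `< 14`); loss
  80 ml is not heavy bleeding and 81 is (strict `> 80`). The acceptance
  sweeps in `tests/testthat/test-acceptance.R` verify every switch point by
  exhaustive integer (or half-unit) sweeps against an independent flat
  re-implementation of the leaf predicates.

## Monitoring tiers as a privacy contract

Each event kind carries a tier (`event_tiers()`): 0 bleed-level data
(including contraception records and per-menses loss), 1 symptoms/BBT/
mucus, 2 urinary LH, 3 serum P4. `classify(log, cap = t)` deletes all
events above tier `t` before anything else runs, so a capped classification
is *identical* to one computed on a log that never contained the deeper
data. This is tested by byte-comparison of serialized results across all
phenotypes and caps. The practical reading: an organisation that chooses to
stop at a conservative node genuinely cannot be influenced by data above
that node.

Raising the cap is monotone in specificity on noise-free data: the leaf
either stays or moves from the unconfirmed leaves (`B1`,
`B1_PROBABLE_OV`) to a terminal one (`C1`, `D1`, `D2`, `E`).

## Conventions chosen where the source material is open

* **Cycle-day numbering** is 1-based with day 1 = first bleed day; a bleed
  onset is a bleed day with no bleed the previous calendar day (multi-day
  menses merge; spotting is not distinguished).
* **Luteal length** counts the LH-positive day through the day before the
  next onset (`length − lh_day + 1`), making the "< 14 days after a
  positive test" criterion testable with a single convention.
* **Amenorrhea gap**: "3 months" is 90 days (3 × 30), inclusive — a gap of
  exactly 90 days classifies as secondary amenorrhea.
* **Individual-level aggregation**: the individual's leaf is that of the
  most recent closed cycle — status is established per cycle, the aggregate
  is a reporting convention. Oligomenorrhea is the exception: it is an
  annual-frequency condition, so on a fully observed 365-day window the
  window count alone decides (≤ 9 onsets → `F`, > 9 → not `F`, even when a
  borderline recent cycle exceeded 35 days — that cycle still shows as `F`
  in the per-cycle table). On partially observed logs the annualised count
  is flagged `EXTRAPOLATED_COUNT` and never triggers `F` by itself; the
  most recent cycle's length decides, conservatively.
* **Question order** within the subtree (prolonged before short, short
  before ovulation evidence) is the one consistent with every leaf's
  predicate; because the adjacency is data, alternative orders are
  testable without code changes.
* **BBT shift detection** uses the field-standard three-over-six rule: the
  first day whose temperature and the next two recorded temperatures all
  strictly exceed the maximum of the previous six recorded temperatures,
  with the third at least 0.2 °C above it (standard fourth-day exception
  when the third clears the maximum but not the margin). The published
  material states the direction of the temperature effect but no
  algorithm, so the rule, window and margin are package choices exposed as
  arguments. BBT is advisory evidence only; it never substitutes for LH or
  P4 in the tree.
* **Contraception regimens**: biphasic pills are modelled as a 10 + 11 day
  progestin split (the source states only "second half"); dose levels are
  ordinal labels (`constant`, `step-up`) since no concentrations are
  published; the progestin-only pill is 28 active days with an optional
  7-day pill-free variant; device lifetimes default to 5 years (copper IUD
  configurable 3/5/10). Withdrawal-bleed days are annotations inside
  hormone-free windows and are never counted as menstrual bleeds.
* **Planner frequencies**: "quarterly" = every 91 days, "monthly" = every
  30 days from plan start; LH testing runs from cycle day 8 for at most 12
  days, truncated a week before the expected next onset; the blood draw
  targets the earliest window day (+7 of +7…+9) to stay mid-luteal even
  for short luteal phases.

## The simulator: what it emulates and what it does not

`simulate_individual()` renders each phenotype's latent hormone curves
(arbitrary-unit piecewise shapes for E1G, PdG, LH, FSH; only the ordinal
relations and the serum-P4 nmol/L scale are contractual) and then observes
them through the same monitoring schedule the planner prescribes: LH tests
from day 8 until the first positive, the serum draw 7 days later, daily
BBT, bleed events with per-menses loss. Defaults are the study conditions:
28 ± 2 day cycles (support 26–32), luteal phases of 14–16 days (12–13 for
the short-luteal phenotype), serum-P4 plateaus of 20 / 10 / 18 / 0 nmol/L
for the eumenorrheic / low-P4 / short-luteal / anovulatory phenotypes,
BBT shift +0.35 °C with σ = 0.05 °C noise, 5-day menses with 40 ± 10 ml
loss, oligomenorrheic cycle lengths 36–60 d (mean 45). Adherence is a
single per-observation miss probability.

Because observations follow the stop-at-first-positive testing rule, a
missed surge-day test leaves *recorded negative* tests: under increasing
miss rates, recovery of the specific leaves degrades toward `E` and
`B1_PROBABLE_OV` (and only with fully missed test blocks toward `B1`).
The property suite asserts exactly that monotone degradation.

What the simulator does **not** emulate — and therefore what passing
recovery tests cannot show about real data: cycle-to-cycle autocorrelation
and stress responses, gradual transitions between phenotypes, reporting
biases (retrospective symptom inflation), test-strip reading ambiguity,
withdrawal-bleed irregularity on extended pill use, and any
pharmacokinetics of the synthetic hormones. Recovery results are evidence
that the engine decodes its own evidence model correctly, not a clinical
validation.

## Numerical and degenerate-input choices

* Duplicate `(date, kind)` measurements are a hard parse error
  (auditability over convenience); every fatal error names its row.
* A log with no bleeds is not a segmentation error — amenorrhea is a
  classification outcome (`NO_BLEEDS` flag on the empty cycle table).
* Open (final) cycles are never length-classified; with no closed cycle
  the engine stops at `B1` rather than guessing from an open cycle.
* Age is required when menarche has not occurred (`MISSING_AGE`), since
  both pre-menarche leaves are age-defined.
* The BBT detector requires ≥ 9 recorded temperatures
  (`INSUFFICIENT_DATA`) and is translation-invariant.
* All randomness flows from one integer seed; per-individual streams are
  derived as `(seed · 48271 + index · 9973 + 1) mod (2³¹ − 2)`, keeping
  every derived seed a valid 32-bit integer.

## Problem sizes used by the test and acceptance suites

Boundary sweeps are exhaustive over their stated ranges (46 lengths, 25
progesterone values, 13 luteal lengths, 10 onset counts, 9 ages, 6 gap
months, 41 loss values). The recovery experiment uses 50 individuals × 7
natural phenotypes × 8 cycles at zero noise; the two-oracle agreement check
uses 10,000 random evidence vectors; the shift-detection study uses 200
replicates. These sizes make every check exact or tightly estimated while
keeping the full suite under a minute on one core.

## Known limitations

The engine classifies only premenopausal, non-pregnant states; pregnancy,
postpartum, peri-menopause and menopause are enumerated stubs
(`life_stage_profile()`). Cervical mucus and BBT are carried as evidence
but never drive the tree. Cycle-day conventions assume daily-resolution
dates; time-of-day is deliberately not modelled. The contraception module
describes regimens and monitoring compatibility; it never advises on
contraception use.
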