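# cyclehealth

Deterministic, auditable classification of menstrual cycle status from
longitudinal self-monitoring logs, with privacy-tiered evidence access,
hormonal-contraception regimen models, dated monitoring plans, and a seeded
synthetic-data simulator.

## The problem

Athletes, coaches and support staff increasingly track menstrual health, but
the raw signals — bleed dates, urinary luteinizing-hormone (LH) ovulation
tests, basal body temperature (BBT), mid-luteal serum progesterone (P4),
cervical mucus, symptoms — are easy to misread, and collecting more of them
than needed raises real privacy and cultural-safety concerns. `cyclehealth`
implements the published decision trees for menstrual cycle status as a rule
engine: every classification is a root-to-leaf walk through yes/no questions,
the full path is returned as an evidence trail, and a **monitoring-tier cap**
guarantees that data deeper than the chosen privacy level is never read.
It is an educational/monitoring aid, **not a diagnostic tool**: every
concerning leaf carries a "medical review required" flag and nothing more.

## The classification model

A cycle is the interval between bleed onsets (day 1 = first bleed day). For
each closed cycle the engine evaluates, in order:

- **Prolonged / infrequent**: cycle length > 35 d, or ≤ 9 bleed onsets in a
  fully observed 365-day window → oligomenorrheic (`F`).
- **Short cycle**: length < 21 d → potential luteal phase defect (`D2`).
- **Ovulation evidence** (tier ≥ 2): no LH tests → naturally menstruating,
  unconfirmed (`B1`); all tests negative → anovulatory (`E`).
- **Luteal phase**: next bleed < 14 d after the positive LH test → short
  luteal phase (`D2`); a positive LH test alone makes ovulation *probable*
  (`B1_PROBABLE_OV`) — only a mid-luteal serum draw (tier 3), 7–9 days after
  the surge, can *confirm* it: P4 > 16 nmol/L → eumenorrheic (`C1`);
  measurable but ≤ 16 nmol/L → luteal phase defect (`D1`).

Before the natural-cycle subtree, the basic tree resolves pre-menarche
(`A1`), primary amenorrhea (`A2`: no menarche by 15, or by 14 without
secondary sex characteristics), secondary amenorrhea (`FHA`: no bleed for
≥ 3 months after established menarche), and hormonal contraception (`HC`,
handed to the contraception taxonomy `O1.1`–`H4`; a copper IUD routes back
to the natural tree). Per-menses blood loss > 80 ml raises the heavy
menstrual bleeding flag, escalating after more than 7 heavy cycles.

The tree adjacency ships as data (`inst/extdata/decision_tree.yaml`) and
every threshold is a named, overridable config key with the published
default (`?thresholds`).

## Worked example

Simulate six cycles of a low-progesterone luteal-phase-defect phenotype and
classify at full monitoring depth (tier 3):

```r
library(cyclehealth)
sim <- simulate_individual("LPD_LOW_P4", n_cycles = 6, seed = 42,
                           noise = noise_spec(bbt_sd = 0))
segment_cycles(sim$log)[1:3, c("index", "onset", "length_days",
                               "lh_positive_day", "luteal_length_days",
                               "midluteal_p4_nmol_l")]
#>   index      onset length_days lh_positive_day luteal_length_days midluteal_p4_nmol_l
#> 1     1 2024-01-01          31              18                 14                  10
#> 2     2 2024-02-01          27              14                 14                  10
#> 3     3 2024-02-28          29              16                 14                  10

classify(sim$log, cap = 3)
#> <cycle_classification> sim-lpd_low_p4-42 as of 2024-06-21 (tier 3)
#>   leaf: D1 - Luteal phase defect (low progesterone)
#>   ovulation: CONFIRMED
#>   flags: EXTRAPOLATED_COUNT, LOW_P4, MEDICAL_REVIEW
#>   per-cycle leaves: D1 D1 D1 D1 D1
```

The cycles are regular (27–31 days) with a normal-length luteal phase, so
nothing looks wrong from bleed dates alone — but the mid-luteal serum
progesterone of 10 nmol/L is measurable (ovulation **CONFIRMED**) yet below
the 16 nmol/L criterion, so each cycle classifies as `D1` with a
medical-review flag. At cap 2 the same log returns `B1_PROBABLE_OV` and at
cap 0 plain `B1`: deeper data is simply never read. A small recovery run
shows the engine recovering every simulated phenotype at full monitoring:

```r
recovery_experiment(5, noise_spec(bbt_sd = 0), cap = 3, seed = 1)$confusion
#>         assigned
#> intended A2 C1 D1 D2 E F FHA
#>      A2   5  0  0  0 0 0   0
#>      C1   0  5  0  0 0 0   0
#>      D1   0  0  5  0 0 0   0
#>      D2   0  0  0  5 0 0   0
#>      E    0  0  0  0 5 0   0
#>      F    0  0  0  0 0 5   0
#>      FHA  0  0  0  0 0 0   5
```

A thin command-line wrapper is included at `inst/cli/mhm.R`
(`validate`, `cycles`, `classify --explain`, `contraception`, `plan`,
`simulate` subcommands).

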