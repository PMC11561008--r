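test_that("pre-menarche and primary amenorrhea split on age", {
  m13 <- individual_meta("a", age_years = 13, menarche_reached = FALSE,
                         secondary_sex_characteristics_present = TRUE)
  r13 <- classify(symptom_only_log(meta = m13), cap = 1)
  expect_equal(r13$leaf, "A1")
  expect_false("MEDICAL_REVIEW" %in% r13$review_flags)

  m16 <- individual_meta("a", age_years = 16, menarche_reached = FALSE,
                         secondary_sex_characteristics_present = TRUE)
  r16 <- classify(symptom_only_log(meta = m16), cap = 1)
  expect_equal(r16$leaf, "A2")
  expect_true("MEDICAL_REVIEW" %in% r16$review_flags)

  # alternate criterion: 14 with no secondary sex characteristics
  m14 <- individual_meta("a", age_years = 14, menarche_reached = FALSE,
                         secondary_sex_characteristics_present = FALSE)
  expect_equal(classify(symptom_only_log(meta = m14), cap = 1)$leaf, "A2")
  m14b <- individual_meta("a", age_years = 14, menarche_reached = FALSE,
                          secondary_sex_characteristics_present = TRUE)
  expect_equal(classify(symptom_only_log(meta = m14b), cap = 1)$leaf, "A1")

  # age is required when menarche has not occurred
  mna <- individual_meta("a", menarche_reached = FALSE)
  expect_error(classify(symptom_only_log(meta = mna), cap = 1),
               class = "cyclehealth_error_MISSING_AGE")
})

test_that("a 3-month bleed gap after menarche is secondary amenorrhea", {
  start <- as.Date("2024-06-01")
  log <- bleed_log(start + 28 * (0:3))
  last <- start + 28 * 3
  r <- classify(log, cap = 0, as_of = last + 120)
  expect_equal(r$leaf, "FHA")
  expect_true(all(c("AMENORRHEA", "MEDICAL_REVIEW") %in% r$review_flags))
  # within the window: still on the natural path
  expect_equal(classify(log, cap = 0, as_of = last + 60)$leaf, "B1")
})

test_that("hormonal contraception routes to HC; copper IUD stays natural", {
  start <- as.Date("2024-01-01")
  hc_row <- make_rows(start, "CONTRACEPTION",
                      '{"category": "OCP_COMBINED_MONO"}')
  log <- bleed_log(start + 28 * (0:2), extra_rows = hc_row)
  r <- classify(log, cap = 0)
  expect_equal(r$leaf, "HC")
  expect_equal(r$contraception_leaf, "O1.1")

  cu_row <- make_rows(start, "CONTRACEPTION", '{"category": "IUD_COPPER"}')
  log2 <- bleed_log(start + 28 * (0:2), extra_rows = cu_row)
  r2 <- classify(log2, cap = 0)
  expect_equal(r2$leaf, "B1")
})

test_that("the natural-cycle subtree reproduces the leaf criteria", {
  ann <- regular_annual()
  # confirmed ovulation with adequate mid-luteal progesterone
  r <- classify_natural_cycle(cycle_fixture(28, 14, midluteal_p4 = 20), ann)
  expect_equal(r$leaf, "C1")
  expect_equal(r$ovulation_status, "CONFIRMED")
  # measurable but low progesterone still confirms ovulation
  r <- classify_natural_cycle(cycle_fixture(28, 14, midluteal_p4 = 12), ann)
  expect_equal(r$leaf, "D1")
  expect_equal(r$ovulation_status, "CONFIRMED")
  # all tests negative: anovulatory
  r <- classify_natural_cycle(cycle_fixture(28, NA, lh_tests_done = 10), ann)
  expect_equal(r$leaf, "E")
  expect_equal(r$ovulation_status, "ABSENT")
  # prolonged cycle regardless of tier
  for (cap in 0:3)
    expect_equal(classify_natural_cycle(cycle_fixture(40), ann,
                                        cap = cap)$leaf, "F")
  # positive LH but no blood test: probable ovulation only, never C1/D1
  r <- classify_natural_cycle(cycle_fixture(28, 14), ann, cap = 2)
  expect_equal(r$leaf, "B1_PROBABLE_OV")
  expect_equal(r$ovulation_status, "PROBABLE")
  # short luteal phase: 28 - 16 + 1 = 13 < 14
  r <- classify_natural_cycle(cycle_fixture(28, 16, midluteal_p4 = 18), ann)
  expect_equal(r$leaf, "D2")
  expect_equal(r$ovulation_status, "CONFIRMED")
  r <- classify_natural_cycle(cycle_fixture(28, 16), ann, cap = 2)
  expect_equal(r$ovulation_status, "PROBABLE")
  # short cycle goes to the defect branch before any LH logic
  r <- classify_natural_cycle(cycle_fixture(19), ann, cap = 0)
  expect_equal(r$leaf, "D2")
  expect_equal(r$ovulation_status, "UNKNOWN")
})

test_that("leaf switches occur exactly at the published thresholds", {
  ann <- regular_annual()
  leaf_len <- vapply(15:60, function(L)
    classify_natural_cycle(cycle_fixture(L), ann, cap = 0)$leaf,
    character(1))
  expect_equal(max((15:60)[leaf_len != "F"]), 35)
  expect_equal(min((15:60)[leaf_len != "D2"]), 21)

  p4_grid <- seq(10, 22, by = 0.5)
  leaf_p4 <- vapply(p4_grid, function(p)
    classify_natural_cycle(cycle_fixture(28, 14, midluteal_p4 = p),
                           ann)$leaf, character(1))
  expect_equal(max(p4_grid[leaf_p4 == "D1"]), 16)
  expect_equal(min(p4_grid[leaf_p4 == "C1"]), 16.5)

  luteal_leaf <- vapply(8:20, function(lut)
    classify_natural_cycle(cycle_fixture(28, 29 - lut, midluteal_p4 = 20),
                           ann)$leaf, character(1))
  expect_equal(min((8:20)[luteal_leaf != "D2"]), 14)
})

test_that("oligomenorrhea at the individual level follows the annual window", {
  # fully observed year: 9 evenly spaced onsets -> F, 10 -> not F
  eoy <- as.Date("2024-01-01") + 364
  expect_equal(classify(year_log(9), cap = 0, as_of = eoy)$leaf, "F")
  r10 <- classify(year_log(10), cap = 0, as_of = eoy)
  expect_equal(r10$leaf, "B1")
  # ...even though individual 36-37 day cycles are flagged per cycle
  expect_true(all(r10$per_cycle$leaf == "F"))
  expect_true("OLIGO" %in% r10$review_flags)
  # partial observation: a prolonged most-recent cycle still triggers F,
  # the annualised count alone never does
  log_long <- bleed_log(as.Date("2025-01-01") + c(0, 40, 80))
  r <- classify(log_long, cap = 0)
  expect_equal(r$leaf, "F")
  expect_true("EXTRAPOLATED_COUNT" %in% r$review_flags)
  log_norm <- bleed_log(as.Date("2025-01-01") + c(0, 28, 56))
  r2 <- classify(log_norm, cap = 0)
  expect_equal(r2$leaf, "B1")
  expect_true("EXTRAPOLATED_COUNT" %in% r2$review_flags)
})

test_that("heavy menstrual bleeding flags follow the loss criteria", {
  start <- as.Date("2025-01-01")
  mk <- function(losses) {
    onsets <- start + 28 * (seq_along(losses) - 1)
    extra <- make_rows(onsets, "BLOOD_LOSS_ESTIMATE", as.character(losses))
    bleed_log(onsets, extra_rows = extra)
  }
  r95 <- classify(mk(95), cap = 0, as_of = start + 40)
  expect_true("HMB" %in% r95$review_flags)
  expect_true("MEDICAL_REVIEW" %in% r95$review_flags)
  # strictly more than 80 ml: 80 exactly does not flag
  r80 <- classify(mk(80), cap = 0, as_of = start + 40)
  expect_false("HMB" %in% r80$review_flags)
  # more than 7 heavy cycles escalates
  r8 <- classify(mk(rep(90, 8)), cap = 0)
  expect_true(all(c("HMB", "HMB_PERSISTENT") %in% r8$review_flags))
  r7 <- classify(mk(rep(90, 7)), cap = 0)
  expect_true("HMB" %in% r7$review_flags)
  expect_false("HMB_PERSISTENT" %in% r7$review_flags)
})

test_that("leaf descriptions match their codes", {
  c1 <- leaf_info("C1")
  expect_match(c1$characteristics, "eumenorrheic", ignore.case = TRUE)
  expect_false(c1$medical_review)
  f <- leaf_info("F")
  expect_match(f$clinical, "Oligomenorrheic")
  expect_true(f$medical_review)
  expect_match(f$characteristics, "[Mm]edical review")
  expect_error(leaf_info("Z9"), class = "cyclehealth_error_UNKNOWN_CODE")
  # every leaf code resolves and maps to one hormonal profile id
  for (code in c("A1", "A2", "FHA", "B1", "B1_PROBABLE_OV", "C1", "D1",
                 "D2", "E", "F", "HC"))
    expect_true(nzchar(leaf_info(code)$profile_id))
})

test_that("classification is deterministic and its path walks the tree", {
  sim <- simulate_individual("LPD_LOW_P4", n_cycles = 6, seed = 3)
  r1 <- classify(sim$log, cap = 3)
  r2 <- classify(sim$log, cap = 3)
  expect_identical(classification_to_json(r1), classification_to_json(r2))
  expect_valid_path(r1)
  expect_valid_path(classify(sim$log, cap = 0))
  expect_valid_path(classify(year_log(9), cap = 0,
                             as_of = as.Date("2024-01-01") + 364))
  m16 <- individual_meta("a", age_years = 16, menarche_reached = FALSE)
  expect_valid_path(classify(symptom_only_log(meta = m16), cap = 1))
})

test_that("raising the tier cap never yields a less specific leaf", {
  vague <- c("B1", "B1_PROBABLE_OV")
  for (ph in cyclehealth:::all_phenotypes()) {
    sim <- simulate_individual(ph, n_cycles = 8, seed = 17,
                               noise = noise_spec(bbt_sd = 0))
    leaves <- vapply(0:3, function(cap)
      classify(sim$log, cap = cap, as_of = sim$truth$as_of)$leaf,
      character(1))
    for (t in 1:3) {
      expect_true(leaves[t + 1] == leaves[t] ||
                    (leaves[t] %in% vague &&
                       leaves[t + 1] %in% c("B1_PROBABLE_OV", "C1", "D1",
                                            "D2", "E")),
                  info = sprintf("%s: caps %d->%d gave %s->%s", ph,
                                 t - 1, t, leaves[t], leaves[t + 1]))
    }
    expect_equal(leaves[4], sim$truth$intended_leaf, info = ph)
  }
})

test_that("deleting events above the cap never changes a capped result", {
  tiers <- event_tiers()
  for (ph in cyclehealth:::all_phenotypes()) {
    sim <- simulate_individual(ph, n_cycles = 6, seed = 23)
    for (cap in 0:3) {
      full <- classify(sim$log, cap = cap, as_of = sim$truth$as_of)
      keep <- tiers[sim$log$events$kind] <= cap
      stripped <- cyclehealth:::new_observation_log(
        sim$log$meta, sim$log$events[keep, , drop = FALSE])
      red <- classify(stripped, cap = cap, as_of = sim$truth$as_of)
      expect_identical(classification_to_json(full),
                       classification_to_json(red),
                       info = sprintf("%s cap %d", ph, cap))
    }
  }
})

test_that("thresholds are overridable but validated", {
  th <- thresholds(regular_max_days = 38)
  expect_equal(classify_natural_cycle(cycle_fixture(37), regular_annual(),
                                      cap = 0, th = th)$leaf, "B1")
  expect_error(thresholds(bogus_key = 1),
               class = "cyclehealth_error_BAD_PAYLOAD")
  expect_error(thresholds(regular_min_days = 40),
               class = "cyclehealth_error_BAD_PAYLOAD")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("hmb_exclusive_ml: 100", cfg)
  expect_equal(load_thresholds(cfg)$hmb_exclusive_ml, 100)
  expect_equal(load_thresholds(cfg)$regular_max_days, 35)
})
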