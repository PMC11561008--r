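test_that("each contraception category maps to exactly one leaf", {
  cats <- setdiff(cyclehealth:::contraception_categories(), "NONE")
  leaves <- vapply(cats, function(cc) classify_contraception(cc)$code,
                   character(1))
  expect_equal(length(unique(leaves)), length(cats))  # injective
  expect_setequal(leaves, c("O1.1", "O1.2", "O1.3", "O2", "H1", "H2",
                            "H3", "H4", "B1.1"))
  expect_error(classify_contraception("NONE"),
               class = "cyclehealth_error_UNKNOWN_CATEGORY")
})

test_that("leaf regimen models carry the published constants", {
  tri <- classify_contraception("OCP_COMBINED_TRI")
  expect_equal(tri$code, "O1.3")
  expect_equal(tri$schedule$phase_structure$span_days, c(7L, 7L, 7L))
  expect_equal(sum(tri$schedule$phase_structure$progestin == "step-up"), 2)
  expect_equal(tri$schedule$active_days, 21L)
  expect_equal(tri$schedule$hormone_free_days, 7L)

  cu <- classify_contraception("IUD_COPPER")
  expect_equal(cu$code, "B1.1")
  expect_equal(cu$ovulation_suppressed, "NO")
  expect_true(cu$reenter_natural_tree)

  inj <- classify_contraception("INJECTION")
  expect_equal(inj$code, "H4")
  expect_equal(inj$schedule$redose_interval_weeks, 13L)

  iud <- classify_contraception("IUD_HORMONAL")
  expect_equal(iud$ovulation_suppressed, "DECREASES_OVER_TIME")

  pop <- classify_contraception("OCP_PROGESTIN_ONLY")
  expect_equal(pop$schedule$active_days, 28L)
  expect_equal(pop$schedule$hormone_free_days, 0L)
})

test_that("the standard 21/7 regimen tiles over the horizon", {
  leaf <- classify_contraception("OCP_COMBINED_MONO")
  s <- expand_schedule(leaf, as.Date("2025-01-01"), 56)
  day_of <- function(d) as.integer(d - as.Date("2025-01-01")) + 1L
  active <- day_of(s$days$date[s$days$day_type == "active"])
  free <- day_of(s$days$date[s$days$day_type == "hormone_free"])
  expect_equal(active, c(1:21, 29:49))
  expect_equal(free, c(22:28, 50:56))
  expect_equal(s$flags, character(0))
})

test_that("extended use skips hormone-free windows and flags overuse", {
  leaf <- classify_contraception("OCP_COMBINED_MONO")
  s <- expand_schedule(leaf, as.Date("2025-01-01"), 84, repeat_extended = 2)
  first_free <- min(s$days$date[s$days$day_type == "hormone_free"])
  expect_equal(as.integer(first_free - as.Date("2025-01-01")) + 1L, 64L)
  expect_equal(s$flags, character(0))  # 2 repeats needs no review

  s4 <- expand_schedule(leaf, as.Date("2025-01-01"), 200,
                        repeat_extended = 4)
  expect_true("EXTENDED_USE_REVIEW" %in% s4$flags)
})

test_that("schedule tiling conserves days over whole regimens", {
  for (cat in c("OCP_COMBINED_MONO", "OCP_COMBINED_TRI",
                "OCP_PROGESTIN_ONLY", "VAGINAL_RING")) {
    leaf <- classify_contraception(cat)
    sch <- leaf$schedule
    for (k in 0:3) {
      reg_len <- sch$active_days * (k + 1) + sch$hormone_free_days
      for (reps in 1:2) {
        s <- expand_schedule(leaf, as.Date("2025-01-01"), reg_len * reps,
                             repeat_extended = k)
        expect_equal(sum(s$days$day_type == "active"),
                     sch$active_days * (k + 1) * reps)
        expect_equal(sum(s$days$day_type == "hormone_free"),
                     sch$hormone_free_days * reps)
      }
    }
  }
})

test_that("expected withdrawal bleeds fall only on hormone-free days", {
  for (cat in c("OCP_COMBINED_MONO", "OCP_COMBINED_BI", "OCP_COMBINED_TRI",
                "OCP_PROGESTIN_ONLY", "VAGINAL_RING")) {
    leaf <- classify_contraception(cat)
    for (horizon in c(30, 365, 730)) for (k in c(0, 3, 6)) {
      s <- expand_schedule(leaf, as.Date("2024-03-01"), horizon,
                           repeat_extended = k)
      expect_true(all(s$days$day_type[s$days$expected_withdrawal_bleed] ==
                        "hormone_free"))
    }
  }
})

test_that("device leaves yield milestones rather than daily regimens", {
  inj <- expand_schedule(classify_contraception("INJECTION"),
                         as.Date("2025-01-01"), 365)
  expect_null(inj$days)
  redoses <- inj$milestones$date[inj$milestones$event == "redose"]
  expect_equal(as.integer(diff(redoses)), rep(91L, length(redoses) - 1))

  iud <- expand_schedule(classify_contraception("IUD_HORMONAL"),
                         as.Date("2025-01-01"), 6 * 365)
  expect_true("replacement_due" %in% iud$milestones$event)
  # nothing due inside a short horizon: structured error
  expect_error(expand_schedule(classify_contraception("IUD_HORMONAL"),
                               as.Date("2025-01-01"), 30),
               class = "cyclehealth_error_NO_SCHEDULE")
})

test_that("monitoring compatibility follows the group rules", {
  nat <- compatible_methods("NATURAL")
  expect_true(all(c("urinary_lh", "blood_p4", "cycle_duration") %in%
                    nat$method[nat$usable]))
  ocp <- compatible_methods("O1.1")
  usable <- ocp$method[ocp$usable]
  expect_false(any(c("cycle_duration", "urinary_lh", "blood_p4") %in% usable))
  expect_true(all(c("symptoms", "bbt", "ocp_schedule", "ocp_brand") %in%
                    usable))
  h1 <- compatible_methods("H1")
  expect_true("cervical_mucus" %in% h1$method[h1$usable])
  expect_false("blood_p4" %in% h1$method[h1$usable])
  # copper IUD keeps every natural method
  cu <- compatible_methods(classify_contraception("IUD_COPPER"))
  expect_true(all(c("cycle_duration", "urinary_lh", "blood_p4") %in%
                    cu$method[cu$usable]))
  expect_error(compatible_methods("X9"),
               class = "cyclehealth_error_UNKNOWN_CODE")
})
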