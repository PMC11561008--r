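# Monitoring-plan generation at the published frequencies, respecting the
# monitoring-tier cap and method-group compatibility.
#
# Frequency conventions (config arguments): "quarterly" = every 91 days from
# plan start, "monthly" = every 30 days.

#' Scheduled urinary LH test days for one cycle
#'
#' Testing starts on cycle day 8 and continues until a positive result; a
#' block of at most 12 scheduled tests covers the advised ~6-12 testing
#' days, truncated so tests stop a week before the expected next onset:
#' days 8 through `min(19, expected_length - 7)`.
#'
#' @param cycle_start Date of the cycle's first bleed day.
#' @param expected_length Expected cycle length in days (>= 21).
#' @param start_day First testing day of the cycle (default 8).
#' @param max_tests Cap on scheduled tests per cycle (default 12).
#' @return Vector of Dates.
#' @export
#' @examples
#' length(lh_test_days(as.Date("2025-03-01"), 28))  # 12
lh_test_days <- function(cycle_start, expected_length,
                         start_day = 8L, max_tests = 12L) {
  if (expected_length < 21)
    ch_abort("BAD_PAYLOAD",
             sprintf("expected_length must be >= 21 days, got %s",
                     expected_length))
  cycle_start <- as.Date(cycle_start)
  last_day <- min(start_day + max_tests - 1L, expected_length - 7L)
  if (last_day < start_day) return(as.Date(character()))
  cycle_start + (seq.int(start_day, last_day) - 1L)
}

#' Confirmatory mid-luteal blood-test day after a positive LH test
#'
#' The mid-luteal serum progesterone draw is interpretable 7-9 days after
#' the positive urinary LH test. The default target is the earliest window
#' day (+7), which maximises the chance of falling mid-luteal even for
#' short luteal phases; the full window is preserved.
#'
#' @param lh_positive Date of the positive urinary LH test.
#' @return A list: `target` (Date, +7), `window` (Dates, +7 to +9).
#' @export
#' @examples
#' blood_test_day(as.Date("2025-03-01"))$target  # 2025-03-08
blood_test_day <- function(lh_positive) {
  lh_positive <- as.Date(lh_positive)
  list(target = lh_positive + 7L, window = lh_positive + 7:9)
}

#' Named life-cycle stage stubs
#'
#' Pregnancy, postpartum, peri-menopause and menopause are enumerated but
#' their monitoring profiles are not implemented in this version.
#'
#' @param stage One of `PREGNANCY`, `POSTPARTUM`, `PERI_MENOPAUSE`,
#'   `MENOPAUSE`.
#' @export
life_stage_profile <- function(stage = c("PREGNANCY", "POSTPARTUM",
                                         "PERI_MENOPAUSE", "MENOPAUSE")) {
  stage <- match.arg(stage)
  ch_abort("NOT_IMPLEMENTED",
           sprintf("life-cycle stage %s is enumerated but not implemented",
                   stage))
}

plan_profiles <- function() {
  c("DEFAULT", "ENDOMETRIOSIS", "PCOS", "PMS_PMDD", "HMB")
}

# method -> minimum tier needed to collect it
method_tiers <- function() {
  c(cycle_duration = 0L, blood_loss = 0L, symptoms = 1L, bbt = 1L,
    cervical_mucus = 1L, urinary_lh = 2L, blood_p4 = 3L,
    ocp_schedule = 0L, ocp_brand = 0L, wellness = 1L,
    pain_medication = 1L, fitness_check = 1L, health_biometrics = 1L)
}

#' Build a dated monitoring plan
#'
#' Generates monitoring items over the horizon at the recommended
#' frequencies, restricted twice: by the monitoring-tier cap (no item whose
#' method needs a deeper tier) and by method-group compatibility (no item a
#' hormonal contraceptive user cannot meaningfully collect, see
#' [compatible_methods()]). Naturally menstruating individuals at tier 2+
#' get a per-cycle urinary LH block ([lh_test_days()]); at tier 3 each
#' recorded positive LH test schedules one confirmatory mid-luteal blood
#' test ([blood_test_day()]), capped at quarterly frequency. Pill users get
#' a monthly schedule-of-use review and a quarterly brand review. Disorder
#' profiles add their published items (e.g. `HMB`: per-cycle bleeding
#' volume rating and quarterly iron-status biometrics).
#'
#' @param status Optional `cycle_classification` (used for the individual
#'   id; the plan itself is driven by `contraception` and `profile`).
#' @param contraception `"NATURAL"` or a `contraception_leaf`.
#' @param start,horizon_days Plan window (`horizon_days >= 1`).
#' @param profile One of `DEFAULT`, `ENDOMETRIOSIS`, `PCOS`, `PMS_PMDD`,
#'   `HMB`.
#' @param tier_cap Monitoring-tier cap 0-3.
#' @param expected_cycle_length Expected cycle length for placing per-cycle
#'   blocks (days).
#' @param cycle_starts Optional known/expected cycle onset dates within the
#'   horizon; defaults to tiling `expected_cycle_length` from `start`.
#' @param lh_positives Dates of recorded positive LH tests (re-planning
#'   truncates that cycle's remaining scheduled tests and adds the blood
#'   draw).
#' @param quarterly_days,monthly_days Frequency conventions.
#' @return A `monitoring_plan`: `individual_id`, `horizon`, `profile`,
#'   `tier_cap`, and `items` (data.frame `date`, `method`, `tier`, `note`,
#'   sorted by date then method).
#' @export
#' @examples
#' p <- build_plan(contraception = "NATURAL", start = as.Date("2025-01-01"),
#'                 horizon_days = 28, tier_cap = 3)
#' head(subset(p$items, method == "urinary_lh"))
build_plan <- function(status = NULL, contraception = "NATURAL",
                       start, horizon_days,
                       profile = "DEFAULT", tier_cap = 3,
                       expected_cycle_length = 28,
                       cycle_starts = NULL, lh_positives = NULL,
                       quarterly_days = 91L, monthly_days = 30L) {
  if (horizon_days < 1)
    ch_abort("BAD_PAYLOAD", "horizon_days must be >= 1")
  profile <- match.arg(profile, plan_profiles())
  if (!tier_cap %in% 0:3)
    ch_abort("BAD_PAYLOAD", "tier_cap must be 0-3")
  start <- as.Date(start)
  end <- start + horizon_days - 1L
  compat <- compatible_methods(contraception)
  usable <- compat$method[compat$usable]
  # non-cycle methods always collectable
  usable <- c(usable, "blood_loss", "wellness", "pain_medication",
              "fitness_check", "health_biometrics")
  tiers <- method_tiers()
  all_days <- seq(start, end, by = 1)
  if (is.null(cycle_starts))
    cycle_starts <- seq(start, end, by = expected_cycle_length)
  cycle_starts <- as.Date(cycle_starts)

  items <- list()
  emit <- function(dates, method, note) {
    dates <- dates[dates >= start & dates <= end]
    if (!length(dates)) return(invisible())
    items[[length(items) + 1L]] <<- data.frame(
      date = dates, method = method, tier = unname(tiers[method]),
      note = note, stringsAsFactors = FALSE)
  }
  allowed <- function(method)
    method %in% usable && tiers[method] <= tier_cap

  # profile requirements that the group/cap cannot satisfy are a structured
  # error, not a silently thinner plan
  required <- switch(profile,
    HMB = c("blood_loss", "cycle_duration"),
    PCOS = "cycle_duration",
    ENDOMETRIOSIS = "symptoms",
    PMS_PMDD = "symptoms",
    DEFAULT = character())
  conflict <- required[!vapply(required, allowed, logical(1))]
  if (length(conflict))
    ch_abort("INCOMPATIBLE_PROFILE",
             sprintf("profile %s requires methods unavailable for this group/tier: %s",
                     profile, paste(conflict, collapse = ", ")),
             data = conflict)

  # daily items
  if (allowed("cycle_duration"))
    emit(all_days, "cycle_duration", "record bleeding yes/no (and day count)")
  if (allowed("symptoms"))
    emit(all_days, "symptoms",
         "daily symptom survey at roughly the same time of day")
  if (allowed("bbt"))
    emit(all_days, "bbt", "basal body temperature on waking, before activity")

  # per-cycle items
  for (cs in seq_along(cycle_starts)) {
    cstart <- cycle_starts[cs]
    if (allowed("cervical_mucus"))
      emit(cstart, "cervical_mucus",
           "rate cervical mucus on 1-4 days of your choosing this cycle")
    if (allowed("urinary_lh")) {
      days <- lh_test_days(cstart, expected_cycle_length)
      pos_in_cycle <- lh_positives[lh_positives >= cstart &
                                     lh_positives < cstart +
                                       expected_cycle_length]
      if (length(pos_in_cycle))
        days <- days[days <= min(pos_in_cycle)]
      emit(days, "urinary_lh",
           "urinary LH test; stop after the first positive result")
    }
  }

  # confirmatory blood tests: one per recorded positive, quarterly cap
  if (allowed("blood_p4") && length(lh_positives)) {
    targets <- do.call(c, lapply(sort(as.Date(lh_positives)),
                                 function(d) blood_test_day(d)$target))
    keep <- c()
    last <- as.Date("1900-01-01")
    for (d in seq_along(targets)) {
      if (as.numeric(targets[d] - last) >= quarterly_days || !length(keep)) {
        keep <- c(keep, d); last <- targets[d]
      }
    }
    emit(targets[keep], "blood_p4",
         "mid-luteal serum progesterone, 7-9 days after the positive LH test")
  }

  # pill users: schedule-of-use and brand reviews
  if (allowed("ocp_schedule"))
    emit(seq(start, end, by = monthly_days), "ocp_schedule",
         "review actual pill-taking schedule incl. extended active-pill use")
  if (allowed("ocp_brand"))
    emit(seq(start, end, by = quarterly_days), "ocp_brand",
         "review brand/generation (doses vary between brands)")

  # disorder profiles
  if (profile == "HMB") {
    emit(cycle_starts, "blood_loss",
         "rate bleeding volume lost per day across this menses")
    emit(seq(start, end, by = quarterly_days), "health_biometrics",
         "health biometrics, specifically iron status")
    emit(seq(start, end, by = monthly_days), "fitness_check",
         "fitness and exercise performance measures")
  } else if (profile == "ENDOMETRIOSIS") {
    emit(cycle_starts, "pain_medication",
         "per cycle: pain, fatigue, dose and frequency of pain medication")
    emit(seq(start, end, by = quarterly_days), "health_biometrics",
         "nutrition and exercise programme review")
  } else if (profile == "PCOS") {
    emit(seq(start, end, by = quarterly_days), "health_biometrics",
         "nutrition, body composition, iron/inflammation/diabetic/CVD parameters")
  } else if (profile == "PMS_PMDD") {
    emit(cycle_starts, "wellness",
         "watch symptom window 1-5 days before and 1-3 days during menses")
  }

  items <- if (length(items)) do.call(rbind, items)
           else data.frame(date = as.Date(character()), method = character(),
                           tier = integer(), note = character())
  items <- items[order(items$date, items$method), , drop = FALSE]
  rownames(items) <- NULL
  structure(list(
    individual_id = if (!is.null(status)) status$individual_id
                    else NA_character_,
    horizon = c(start = start, end = end),
    profile = profile,
    tier_cap = as.integer(tier_cap),
    items = items
  ), class = "monitoring_plan")
}

#' @export
print.monitoring_plan <- function(x, ...) {
  cat(sprintf("<monitoring_plan> %s to %s, profile %s, tier cap %d: %d items\n",
              format(x$horizon[["start"]]), format(x$horizon[["end"]]),
              x$profile, x$tier_cap, nrow(x$items)))
  print(table(x$items$method))
  invisible(x)
}
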