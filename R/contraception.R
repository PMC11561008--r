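# Hormonal-contraception taxonomy, regimen schedule models, and monitoring
# compatibility.

contraception_leaf_table <- function() {
  list(
    O1.1 = list(code = "O1.1",
      description = paste("Monophasic combined oral contraceptive pill:",
        "ethinylestradiol and progestin at the same low dose throughout the",
        "21 active-pill days, then 7 hormone-free days."),
      ovulation_suppressed = "YES"),
    O1.2 = list(code = "O1.2",
      description = paste("Biphasic combined oral contraceptive pill:",
        "constant ethinylestradiol with a progestin step-up in the second",
        "half of the active-pill phase."),
      ovulation_suppressed = "YES"),
    O1.3 = list(code = "O1.3",
      description = paste("Triphasic combined oral contraceptive pill:",
        "constant ethinylestradiol with progestin increasing every 7 days",
        "across three 7-day spans."),
      ovulation_suppressed = "YES"),
    O2 = list(code = "O2",
      description = paste("Progestin-only pill ('mini-pill'): low-dose",
        "progestin for 28 days, unless an optional 7-day pill-free period",
        "is completed."),
      ovulation_suppressed = "LIKELY"),
    H1 = list(code = "H1",
      description = paste("Hormonal intrauterine device: slow-release",
        "progestin inside the uterus, typically lasting 5 years. The dose",
        "declines over time, so ovulation may start to occur more readily",
        "in the later years of the device's life."),
      ovulation_suppressed = "DECREASES_OVER_TIME"),
    H2 = list(code = "H2",
      description = paste("Hormonal implant: subdermal rods with",
        "slow-release progestin, typically lasting 5 years; ovulation is",
        "likely suppressed for the duration of use."),
      ovulation_suppressed = "LIKELY"),
    H3 = list(code = "H3",
      description = paste("Vaginal ring: low-dose ethinylestradiol and",
        "progestin, typically worn 3 of every 4 weeks (can be worn",
        "continuously)."),
      ovulation_suppressed = "YES"),
    H4 = list(code = "H4",
      description = paste("Contraceptive injection (depot progestin):",
        "moderate progestin dose, re-dosed every 13 weeks."),
      ovulation_suppressed = "YES"),
    B1.1 = list(code = "B1.1",
      description = paste("Copper intrauterine device: no synthetic",
        "hormones and does not stop ovulation; the user remains naturally",
        "menstruating and re-enters the natural-cycle decision tree.",
        "Lasts 3, 5 or 10 years depending on the type."),
      ovulation_suppressed = "NO")
  )
}

category_to_leaf <- function() {
  c(OCP_COMBINED_MONO = "O1.1", OCP_COMBINED_BI = "O1.2",
    OCP_COMBINED_TRI = "O1.3", OCP_PROGESTIN_ONLY = "O2",
    IUD_HORMONAL = "H1", IMPLANT = "H2", VAGINAL_RING = "H3",
    INJECTION = "H4", IUD_COPPER = "B1.1")
}

default_schedule_model <- function(code, rec = NULL) {
  active <- function(default) {
    if (!is.null(rec) && !is.null(rec$active_days)) rec$active_days
    else default
  }
  free <- function(default) {
    if (!is.null(rec) && !is.null(rec$hormone_free_days)) rec$hormone_free_days
    else default
  }
  switch(code,
    O1.1 = list(active_days = active(21L), hormone_free_days = free(7L),
      phase_structure = data.frame(span_days = 21L, estrogen = "constant",
                                   progestin = "constant"),
      redose_interval_weeks = NA_integer_, wear_pattern = NA_character_,
      replacement_years = NA_real_),
    O1.2 = list(active_days = active(21L), hormone_free_days = free(7L),
      phase_structure = data.frame(span_days = c(10L, 11L),
                                   estrogen = c("constant", "constant"),
                                   progestin = c("constant", "step-up")),
      redose_interval_weeks = NA_integer_, wear_pattern = NA_character_,
      replacement_years = NA_real_),
    O1.3 = list(active_days = active(21L), hormone_free_days = free(7L),
      phase_structure = data.frame(span_days = c(7L, 7L, 7L),
                                   estrogen = rep("constant", 3),
                                   progestin = c("constant", "step-up",
                                                 "step-up")),
      redose_interval_weeks = NA_integer_, wear_pattern = NA_character_,
      replacement_years = NA_real_),
    O2 = list(active_days = active(28L), hormone_free_days = free(0L),
      phase_structure = data.frame(span_days = 28L, estrogen = "none",
                                   progestin = "constant"),
      redose_interval_weeks = NA_integer_, wear_pattern = NA_character_,
      replacement_years = NA_real_),
    H1 = list(active_days = NA_integer_, hormone_free_days = NA_integer_,
      phase_structure = NULL, redose_interval_weeks = NA_integer_,
      wear_pattern = NA_character_, replacement_years = 5),
    H2 = list(active_days = NA_integer_, hormone_free_days = NA_integer_,
      phase_structure = NULL, redose_interval_weeks = NA_integer_,
      wear_pattern = NA_character_, replacement_years = 5),
    H3 = list(active_days = 21L, hormone_free_days = 7L,
      phase_structure = data.frame(span_days = 21L, estrogen = "constant",
                                   progestin = "constant"),
      redose_interval_weeks = NA_integer_, wear_pattern = "3 of 4 weeks",
      replacement_years = NA_real_),
    H4 = list(active_days = NA_integer_, hormone_free_days = NA_integer_,
      phase_structure = NULL, redose_interval_weeks = 13L,
      wear_pattern = NA_character_, replacement_years = NA_real_),
    B1.1 = list(active_days = NA_integer_, hormone_free_days = NA_integer_,
      phase_structure = NULL, redose_interval_weeks = NA_integer_,
      wear_pattern = NA_character_, replacement_years = 5)
  )
}

#' Classify a contraception record to its taxonomy leaf
#'
#' Deterministic, total and injective on the category enumeration: each
#' hormonal category maps to exactly one leaf of the contraception decision
#' tree. The copper IUD maps to `B1.1`, carries no synthetic hormones, does
#' not suppress ovulation, and routes back to the naturally-menstruating
#' tree.
#'
#' @param rec A [contraception_record()] (category must not be `NONE`), or a
#'   bare category string.
#' @return A `contraception_leaf`: `code`, `description`,
#'   `ovulation_suppressed` (`YES`/`LIKELY`/`DECREASES_OVER_TIME`/`NO`),
#'   `schedule` (regimen model or milestone-only), `extended_use_repeats`,
#'   `reenter_natural_tree` (TRUE for the copper IUD).
#' @export
#' @examples
#' classify_contraception("INJECTION")$schedule$redose_interval_weeks  # 13
classify_contraception <- function(rec) {
  if (is.character(rec)) rec <- contraception_record(rec)
  stopifnot(inherits(rec, "contraception_record"))
  if (rec$category == "NONE")
    ch_abort("UNKNOWN_CATEGORY", "category NONE has no contraception leaf")
  map <- category_to_leaf()
  if (!rec$category %in% names(map))
    ch_abort("UNKNOWN_CATEGORY",
             sprintf("unknown contraception category %s", rec$category))
  code <- unname(map[rec$category])
  info <- contraception_leaf_table()[[code]]
  structure(list(
    code = code,
    description = info$description,
    ovulation_suppressed = info$ovulation_suppressed,
    schedule = default_schedule_model(code, rec),
    extended_use_repeats = rec$extended_use_repeats,
    reenter_natural_tree = identical(code, "B1.1")
  ), class = "contraception_leaf")
}

#' @export
print.contraception_leaf <- function(x, ...) {
  cat(sprintf("<contraception_leaf> %s (ovulation suppressed: %s)\n%s\n",
              x$code, x$ovulation_suppressed, x$description))
  invisible(x)
}

#' Expand a contraception regimen into a dated schedule
#'
#' Tiles the regimen over the horizon. Pill and ring regimens alternate
#' active and hormone-free days; `repeat_extended = k` skips `k`
#' hormone-free windows before taking one (extended use), and extended use
#' beyond 3 repeats of the active phase raises the `EXTENDED_USE_REVIEW`
#' flag. Days inside a hormone-free window are marked as the
#' expected-withdrawal-bleed window — a withdrawal bleed is not a menstrual
#' bleed, since no ovulation occurred. Injection leaves yield re-dose
#' milestones every 13 weeks; device leaves (IUDs, implant) carry only a
#' replacement milestone.
#'
#' @param leaf A `contraception_leaf` from [classify_contraception()].
#' @param start Start date of the first regimen day.
#' @param horizon_days Number of days to schedule.
#' @param repeat_extended Hormone-free windows skipped per cycle of use;
#'   defaults to the record's `extended_use_repeats`.
#' @return A list of class `contraception_schedule`: `days` (data.frame
#'   `date`, `day_type` in `active`/`hormone_free`,
#'   `expected_withdrawal_bleed` logical), `milestones` (data.frame `date`,
#'   `event`), `flags` (character).
#' @export
#' @examples
#' leaf <- classify_contraception("OCP_COMBINED_MONO")
#' s <- expand_schedule(leaf, as.Date("2025-01-01"), 56)
#' table(s$days$day_type)
expand_schedule <- function(leaf, start, horizon_days,
                            repeat_extended = NULL) {
  stopifnot(inherits(leaf, "contraception_leaf"), horizon_days >= 1)
  start <- as.Date(start)
  if (is.null(repeat_extended)) repeat_extended <- leaf$extended_use_repeats
  if (repeat_extended < 0)
    ch_abort("BAD_PAYLOAD", "repeat_extended must be non-negative")
  sch <- leaf$schedule
  flags <- character()
  milestones <- data.frame(date = as.Date(character()), event = character())

  if (!is.na(sch$redose_interval_weeks)) {
    dates <- seq(start, by = sch$redose_interval_weeks * 7,
                 length.out = ceiling(horizon_days /
                                        (sch$redose_interval_weeks * 7)) + 1)
    dates <- dates[dates < start + horizon_days]
    milestones <- data.frame(date = dates, event = "redose")
  }
  if (!is.na(sch$replacement_years)) {
    due <- start + round(sch$replacement_years * 365.25)
    if (due < start + horizon_days)
      milestones <- rbind(milestones,
                          data.frame(date = due, event = "replacement_due"))
  }

  if (is.na(sch$active_days)) {
    if (nrow(milestones) == 0)
      ch_abort("NO_SCHEDULE",
               sprintf("leaf %s has no daily regimen and no milestones in the horizon",
                       leaf$code))
    return(structure(list(days = NULL, milestones = milestones,
                          flags = flags),
                     class = "contraception_schedule"))
  }

  if (repeat_extended > 3) flags <- c(flags, "EXTENDED_USE_REVIEW")

  # one extended regimen = (repeat_extended + 1) active blocks + one
  # hormone-free window (a zero-length window for continuous regimens)
  block <- c(rep("active", sch$active_days * (repeat_extended + 1L)),
             rep("hormone_free", sch$hormone_free_days))
  if (!length(block))
    ch_abort("NO_SCHEDULE", sprintf("leaf %s regimen has zero length",
                                    leaf$code))
  day_type <- rep(block, length.out = horizon_days)
  days <- data.frame(
    date = seq(start, by = 1, length.out = horizon_days),
    day_type = day_type,
    expected_withdrawal_bleed = day_type == "hormone_free",
    stringsAsFactors = FALSE)
  structure(list(days = days, milestones = milestones, flags = flags),
            class = "contraception_schedule")
}

#' Monitoring methods compatible with a contraception group
#'
#' Which monitoring variables remain usable and informative for a given
#' group. Cycle-duration tracking, urinary LH tests and mid-luteal blood
#' progesterone cannot be used by hormonal contraceptive users: the
#' synthetic hormones prevent the natural fluctuations those methods read.
#' Basal body temperature stays available to pill users (natural
#' temperature changes may still be present), cervical mucus observation
#' stays available to hormonal IUD and implant users (progestin thickening
#' of mucus is a known effect), and symptom tracking is universal. Copper
#' IUD users are naturally menstruating and keep every method.
#'
#' @param leaf_or_natural A `contraception_leaf`, a leaf code string, or
#'   `"NATURAL"` for a naturally menstruating individual.
#' @return A data.frame: `method`, `usable` (logical), `frequency`, `note`.
#' @export
#' @examples
#' subset(compatible_methods("NATURAL"), usable)$method
compatible_methods <- function(leaf_or_natural = "NATURAL") {
  code <- if (inherits(leaf_or_natural, "contraception_leaf"))
    leaf_or_natural$code else as.character(leaf_or_natural)
  if (!code %in% c("NATURAL", names(contraception_leaf_table())))
    ch_abort("UNKNOWN_CODE", sprintf("unknown group %s", deparse(code)))

  natural <- code %in% c("NATURAL", "B1.1")
  ocp <- code %in% c("O1.1", "O1.2", "O1.3", "O2")
  iud_implant <- code %in% c("H1", "H2")

  methods <- data.frame(
    method = c("cycle_duration", "symptoms", "urinary_lh", "bbt",
               "cervical_mucus", "blood_p4", "ocp_schedule", "ocp_brand"),
    usable = c(natural,
               TRUE,
               natural,
               natural || ocp,
               natural || iud_implant,
               natural,
               ocp,
               ocp),
    frequency = c("daily", "daily", "per_cycle_6_12_days", "daily",
                  "per_cycle_1_4_days", "quarterly", "monthly", "quarterly"),
    note = c(
      "regularity of bleeds; >35 days prolonged, <21 days potential luteal phase defect; not usable under OCP",
      "collect every day at roughly the same time of day; avoid retrospective recall",
      "start on cycle day 8 and continue until a positive result",
      if (ocp) "natural temperature changes may still be present in OCP users"
      else "morning measurement before any activity; indicative of ovulation",
      if (iud_implant)
        "thickening of cervical mucus is a noted effect of the low-dose synthetic progestin"
      else "egg-white to thick/paste-like after ovulation",
      "mid-luteal draw 7-9 days after a positive urinary LH test; >16 nmol/L eumenorrheic",
      "record actual pill-taking pattern incl. extended use of the active pill",
      "brand/generation review; synthetic doses vary between brands"),
    stringsAsFactors = FALSE)
  methods
}
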