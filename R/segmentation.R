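# Cycle segmentation: turn an observation log into per-cycle evidence.
#
# Conventions (fixed package-wide):
#   * cycle-day numbering is 1-based, day 1 = first bleed day of the cycle;
#   * a bleed onset is a BLEED day with no BLEED on the previous calendar day
#     (multi-day menses merge into one onset; spotting is not distinguished);
#   * luteal length counts the LH-positive day itself through the last day
#     before the next onset: luteal = length_days - lh_positive_day + 1.

#' Segment an observation log into menstrual cycles
#'
#' A new cycle starts at each bleed onset; it ends the day before the next
#' onset. All non-bleed events dated within a cycle are attached to it. The
#' final cycle is open (unknown length). A log with zero bleed events yields
#' an empty table flagged `no_bleeds` — amenorrhea is a classification
#' outcome, not a segmentation error.
#'
#' @param log An `observation_log`.
#' @return A data.frame of class `cycle_table`, one row per cycle:
#'   `index`, `onset` (Date), `length_days` (NA for the open final cycle),
#'   `bleed_days` (list of 1-based cycle days), `lh_positive_day` (first
#'   positive urinary LH test, cycle day, NA if none), `lh_tests_done`,
#'   `luteal_length_days`, `midluteal_p4_nmol_l` (serum P4 recorded 7-9 days
#'   after the positive LH test, NA otherwise), `p4_any_nmol_l` (max serum P4
#'   anywhere in the cycle, NA if none drawn), `bbt_shift_day`,
#'   `blood_loss_ml` (per-menses total attached to the menses' first day).
#'   Attribute `no_bleeds` is TRUE when the log had no bleed events.
#' @export
#' @examples
#' log <- simulate_individual("EUMENORRHEIC", n_cycles = 3, seed = 1)$log
#' segment_cycles(log)[, c("index", "onset", "length_days")]
segment_cycles <- function(log) {
  stopifnot(inherits(log, "observation_log"))
  ev <- log$events
  bleed_dates <- sort(unique(ev$date[ev$kind == "BLEED"]))
  empty <- data.frame(index = integer(), onset = as.Date(character()),
                      length_days = integer())
  if (!length(bleed_dates)) {
    out <- empty
    class(out) <- c("cycle_table", "data.frame")
    attr(out, "no_bleeds") <- TRUE
    return(out)
  }
  is_onset <- !((bleed_dates - 1) %in% bleed_dates)
  onsets <- bleed_dates[is_onset]
  n <- length(onsets)
  length_days <- c(as.integer(diff(onsets)), NA_integer_)
  cycle_end <- c(onsets[-1] - 1, max(ev$date))  # open cycle: observed end

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    in_cycle <- ev$date >= onsets[i] & ev$date <= cycle_end[i]
    cev <- ev[in_cycle, , drop = FALSE]
    cday <- as.integer(cev$date - onsets[i]) + 1L

    bleeds <- sort(cday[cev$kind == "BLEED"])

    lh_idx <- which(cev$kind == "LH_TEST")
    lh_pos <- lh_idx[vapply(cev$payload[lh_idx], isTRUE, logical(1))]
    lh_positive_day <- if (length(lh_pos)) min(cday[lh_pos]) else NA_integer_
    lh_tests_done <- length(lh_idx)

    luteal <- if (!is.na(length_days[i]) && !is.na(lh_positive_day))
      length_days[i] - lh_positive_day + 1L else NA_integer_

    p4_idx <- which(cev$kind == "SERUM_P4")
    p4_vals <- vapply(cev$payload[p4_idx], as.numeric, numeric(1))
    p4_any <- if (length(p4_vals)) max(p4_vals) else NA_real_
    midluteal <- NA_real_
    if (!is.na(lh_positive_day) && length(p4_idx)) {
      in_window <- cday[p4_idx] >= lh_positive_day + 7L &
                   cday[p4_idx] <= lh_positive_day + 9L
      if (any(in_window)) midluteal <- p4_vals[which(in_window)[1]]
    }

    bbt_idx <- which(cev$kind == "BBT")
    bbt_shift <- NA_integer_
    if (length(bbt_idx) >= 9) {
      ndays <- as.integer(cycle_end[i] - onsets[i]) + 1L
      temps <- rep(NA_real_, ndays)
      temps[cday[bbt_idx]] <- vapply(cev$payload[bbt_idx], as.numeric,
                                     numeric(1))
      bbt_shift <- detect_bbt_shift(temps)
      if (is.null(bbt_shift)) bbt_shift <- NA_integer_
    }

    loss_idx <- which(cev$kind == "BLOOD_LOSS_ESTIMATE")
    loss <- if (length(loss_idx))
      sum(vapply(cev$payload[loss_idx], as.numeric, numeric(1)))
    else NA_real_

    rows[[i]] <- list(index = i, onset = onsets[i],
                      length_days = length_days[i],
                      bleed_days = list(bleeds),
                      lh_positive_day = lh_positive_day,
                      lh_tests_done = lh_tests_done,
                      luteal_length_days = luteal,
                      midluteal_p4_nmol_l = midluteal,
                      p4_any_nmol_l = p4_any,
                      bbt_shift_day = bbt_shift,
                      blood_loss_ml = loss)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(index = r$index, onset = r$onset,
                    length_days = r$length_days,
                    lh_positive_day = r$lh_positive_day,
                    lh_tests_done = r$lh_tests_done,
                    luteal_length_days = r$luteal_length_days,
                    midluteal_p4_nmol_l = r$midluteal_p4_nmol_l,
                    p4_any_nmol_l = r$p4_any_nmol_l,
                    bbt_shift_day = r$bbt_shift_day,
                    blood_loss_ml = r$blood_loss_ml)
    d$bleed_days <- r$bleed_days
    d
  }))
  rownames(out) <- NULL
  class(out) <- c("cycle_table", "data.frame")
  attr(out, "no_bleeds") <- FALSE
  out
}

#' Annual bleed frequency from a log
#'
#' Counts bleed onsets in the 365-day window ending at `as_of`. When the log
#' observes less than the full window, the count is annualised
#' (`count * 365 / observed_span`) and flagged `extrapolated`; the classifier
#' treats extrapolated counts conservatively (they never trigger the
#' oligomenorrhea leaf on their own).
#'
#' @param log An `observation_log`.
#' @param as_of End of the 365-day window (Date); defaults to the last event.
#' @return A list: `count` (possibly annualised), `raw_count`, `coverage`
#'   (observed span / 365), `extrapolated` (logical).
#' @export
bleeds_per_year <- function(log, as_of = NULL) {
  stopifnot(inherits(log, "observation_log"))
  ev <- log$events
  if (!nrow(ev))
    return(list(count = 0, raw_count = 0L, coverage = 0, extrapolated = TRUE))
  if (is.null(as_of)) as_of <- max(ev$date)
  as_of <- as.Date(as_of)
  window_start <- as_of - 364L
  observed_start <- max(window_start, min(ev$date))
  span <- as.numeric(as_of - observed_start) + 1
  if (span <= 0)
    return(list(count = 0, raw_count = 0L, coverage = 0, extrapolated = TRUE))

  bleed_dates <- sort(unique(ev$date[ev$kind == "BLEED"]))
  onsets <- bleed_dates[!((bleed_dates - 1) %in% bleed_dates)]
  raw <- sum(onsets >= window_start & onsets <= as_of)
  coverage <- span / 365
  if (coverage >= 1) {
    list(count = raw, raw_count = as.integer(raw), coverage = 1,
         extrapolated = FALSE)
  } else {
    list(count = raw * 365 / span, raw_count = as.integer(raw),
         coverage = coverage, extrapolated = TRUE)
  }
}

#' Luteal phase length of a closed cycle
#'
#' Days from the LH-positive day through the day before the next onset,
#' inclusive of the LH-positive day: `length_days - lh_positive_day + 1`.
#' Luteal phases shorter than 14 days are evidence for a luteal phase
#' defect.
#'
#' @param cycle One row of a [segment_cycles()] table (or any list with
#'   `length_days` and `lh_positive_day`).
#' @return Integer luteal length, or `NA` if the cycle is open or no
#'   positive LH test was recorded.
#' @export
luteal_length <- function(cycle) {
  len <- cycle$length_days
  lh <- cycle$lh_positive_day
  if (is.null(len) || is.null(lh) || is.na(len) || is.na(lh))
    return(NA_integer_)
  as.integer(len - lh + 1L)
}

#' Detect a biphasic basal-body-temperature shift
#'
#' Progesterone raises basal body temperature in the second (luteal) half of
#' an ovulatory cycle. This detector applies the classic three-over-six
#' rule: the shift day is the first day `d` whose temperature, and those of
#' the two following recorded days, all strictly exceed the maximum of the
#' previous six recorded temperatures, with the third of the three at least
#' `threshold_c` above that maximum (standard exception: when the third
#' temperature clears the maximum but not the margin, a fourth recorded
#' temperature at least `threshold_c` above it completes the shift). The
#' result is advisory
#' evidence only; it never substitutes for LH or progesterone testing in the
#' decision tree.
#'
#' @param temps Numeric vector of temperatures (degC) indexed by cycle day;
#'   `NA` for unrecorded days. At least 9 recorded values are required.
#' @param threshold_c Rise above the prior six-day maximum (degC).
#' @return The 1-based cycle day of the shift, or `NULL` if no shift found.
#'   Adding a constant to all temperatures leaves the result unchanged.
#' @export
#' @examples
#' temps <- c(rep(36.4, 14), rep(36.8, 14))
#' detect_bbt_shift(temps)  # 15
detect_bbt_shift <- function(temps, threshold_c = 0.2) {
  recorded <- which(!is.na(temps))
  if (length(recorded) < 9)
    ch_abort("INSUFFICIENT_DATA",
             sprintf("need >= 9 recorded temperatures, got %d",
                     length(recorded)))
  for (pos in seq_along(recorded)) {
    if (pos < 7 || pos + 2 > length(recorded)) next
    prev6 <- temps[recorded[(pos - 6):(pos - 1)]]
    trio <- temps[recorded[pos:(pos + 2)]]
    m <- max(prev6)
    if (all(trio > m)) {
      if (trio[3] >= m + threshold_c) return(recorded[pos])
      if (pos + 3 <= length(recorded) &&
          temps[recorded[pos + 3]] >= m + threshold_c)
        return(recorded[pos])
    }
  }
  NULL
}
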