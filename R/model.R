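# Event-log domain model: individual metadata, dated self-monitoring events,
# contraception records, and the CSV/JSON interchange used by everything
# downstream.

#' Event kinds and their monitoring tiers
#'
#' Each event kind belongs to a monitoring tier. The tier expresses how much
#' personal health detail the observation carries: tier 0 is bleed-date-level
#' information (including per-menses blood-loss estimates and the
#' contraception record needed to route the decision tree), tier 1 adds daily
#' symptoms, basal body temperature and cervical mucus, tier 2 adds urinary
#' LH ovulation tests, and tier 3 adds mid-luteal serum progesterone.
#' Classification at a tier cap never reads events above the cap.
#'
#' @return Named integer vector mapping event kind to tier.
#' @export
#' @examples
#' event_tiers()
event_tiers <- function() {
  c(BLEED = 0L, BLOOD_LOSS_ESTIMATE = 0L, CONTRACEPTION = 0L,
    SYMPTOM = 1L, BBT = 1L, CERVICAL_MUCUS = 1L,
    LH_TEST = 2L, SERUM_P4 = 3L)
}

event_kinds <- function() names(event_tiers())

contraception_categories <- function() {
  c("NONE", "OCP_COMBINED_MONO", "OCP_COMBINED_BI", "OCP_COMBINED_TRI",
    "OCP_PROGESTIN_ONLY", "IUD_HORMONAL", "IMPLANT", "VAGINAL_RING",
    "INJECTION", "IUD_COPPER")
}

#' Individual metadata
#'
#' @param individual_id Opaque identifier string.
#' @param age_years Non-negative age in years.
#' @param menarche_reached `TRUE`, `FALSE`, or `NA` (unknown).
#' @param sex_assignment_note Optional free text; never read by the
#'   classifier (sex and gender are not binary; the note is carried verbatim).
#' @param secondary_sex_characteristics_present `TRUE`, `FALSE`, or `NA`.
#' @return An object of class `individual_meta`.
#' @export
individual_meta <- function(individual_id,
                            age_years = NA_real_,
                            menarche_reached = NA,
                            sex_assignment_note = NA_character_,
                            secondary_sex_characteristics_present = NA) {
  if (!is.na(age_years) && age_years < 0)
    ch_abort("BAD_PAYLOAD", "age_years must be non-negative")
  structure(list(
    individual_id = as.character(individual_id),
    age_years = as.numeric(age_years),
    menarche_reached = as.logical(menarche_reached),
    sex_assignment_note = as.character(sex_assignment_note),
    secondary_sex_characteristics_present =
      as.logical(secondary_sex_characteristics_present)
  ), class = "individual_meta")
}

#' Contraception record
#'
#' @param category One of [contraception_categories()].
#' @param active_days,hormone_free_days Pill regimen (pill categories only);
#'   defaults follow the standard 21/7 combined regimen when the category is
#'   a combined pill and 28/0 for the progestin-only pill.
#' @param extended_use_repeats Number of hormone-free windows skipped before
#'   taking one (0 = standard cycling).
#' @param start_date Date the method started.
#' @param brand_note Free text; no brand database is modelled.
#' @return An object of class `contraception_record`.
#' @export
contraception_record <- function(category,
                                 active_days = NULL,
                                 hormone_free_days = NULL,
                                 extended_use_repeats = 0L,
                                 start_date = NA,
                                 brand_note = NA_character_) {
  category <- match.arg(category, contraception_categories())
  pill <- category %in% c("OCP_COMBINED_MONO", "OCP_COMBINED_BI",
                          "OCP_COMBINED_TRI", "OCP_PROGESTIN_ONLY")
  if (!pill && (!is.null(active_days) || !is.null(hormone_free_days)))
    ch_abort("BAD_PAYLOAD", "pill regimen fields only apply to pill categories")
  if (pill) {
    if (is.null(active_days))
      active_days <- if (category == "OCP_PROGESTIN_ONLY") 28L else 21L
    if (is.null(hormone_free_days))
      hormone_free_days <- if (category == "OCP_PROGESTIN_ONLY") 0L else 7L
  }
  if (extended_use_repeats < 0)
    ch_abort("BAD_PAYLOAD", "extended_use_repeats must be non-negative")
  structure(list(
    category = category,
    active_days = if (pill) as.integer(active_days) else NULL,
    hormone_free_days = if (pill) as.integer(hormone_free_days) else NULL,
    extended_use_repeats = as.integer(extended_use_repeats),
    start_date = if (is.na(start_date[1])) NA else as.Date(start_date),
    brand_note = as.character(brand_note)
  ), class = "contraception_record")
}

# Payload validation per event kind. Returns the coerced payload or aborts
# with BAD_PAYLOAD naming `row`.
coerce_payload <- function(kind, value, row = NULL) {
  num <- function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (length(x) != 1 || is.na(x))
      ch_abort("BAD_PAYLOAD", sprintf("%s payload is not a number: %s",
                                      kind, deparse(v)), row)
    x
  }
  switch(kind,
    BLEED = {
      # optional volume rating (ordinal); empty/NA means plain bleed day
      if (is.null(value) || length(value) == 0 || all(is.na(value)) ||
          identical(value, "")) NA_real_ else num(value)
    },
    LH_TEST = {
      v <- tolower(as.character(value))
      if (!v %in% c("positive", "negative", "true", "false"))
        ch_abort("BAD_PAYLOAD",
                 sprintf("LH_TEST payload must be positive/negative, got %s",
                         deparse(value)), row)
      v %in% c("positive", "true")
    },
    BBT = {
      x <- num(value)
      if (x < 30 || x > 45)
        ch_abort("BAD_PAYLOAD",
                 sprintf("BBT %.1f outside plausible 30-45 degC range", x), row)
      x
    },
    SERUM_P4 = {
      x <- num(value)
      if (x < 0)
        ch_abort("BAD_PAYLOAD", "SERUM_P4 must be non-negative", row)
      x
    },
    CERVICAL_MUCUS = {
      x <- num(value)
      if (x != round(x) || x < 0)
        ch_abort("BAD_PAYLOAD", "CERVICAL_MUCUS must be a non-negative ordinal",
                 row)
      as.integer(x)
    },
    SYMPTOM = {
      if (is.character(value)) value <- jsonlite::fromJSON(value)
      if (!is.list(value) && !(is.numeric(value) && !is.null(names(value))))
        ch_abort("BAD_PAYLOAD", "SYMPTOM payload must be a named score map",
                 row)
      as.list(value)
    },
    CONTRACEPTION = {
      if (is.character(value)) value <- jsonlite::fromJSON(value)
      if (inherits(value, "contraception_record")) return(value)
      if (!is.list(value) || is.null(value$category))
        ch_abort("BAD_PAYLOAD", "CONTRACEPTION payload must name a category",
                 row)
      do.call(contraception_record, value)
    },
    BLOOD_LOSS_ESTIMATE = {
      x <- num(value)
      if (x < 0)
        ch_abort("BAD_PAYLOAD", "BLOOD_LOSS_ESTIMATE must be non-negative", row)
      x
    },
    ch_abort("BAD_PAYLOAD", sprintf("unknown event kind %s", deparse(kind)),
             row)
  )
}

new_observation_log <- function(meta, events) {
  structure(list(meta = meta, events = events), class = "observation_log")
}

#' @export
print.observation_log <- function(x, ...) {
  cat(sprintf("<observation_log> individual %s: %d events (%s to %s)\n",
              x$meta$individual_id, nrow(x$events),
              if (nrow(x$events)) format(min(x$events$date)) else "-",
              if (nrow(x$events)) format(max(x$events$date)) else "-"))
  print(table(x$events$kind))
  invisible(x)
}

# Canonical ordering: ascending date, ties broken by kind name.
order_events <- function(events) {
  events[order(events$date, events$kind), , drop = FALSE]
}

#' Build a validated observation log from tabular event rows
#'
#' The sole input to cycle segmentation and classification. Rows must all
#' belong to one individual; dates must be real ISO-8601 calendar dates;
#' payloads are coerced and range-checked per kind (e.g. basal body
#' temperature must lie in 30-45 degC, serum progesterone must be
#' non-negative). Duplicate `(date, kind)` pairs for the measurement kinds
#' BLEED, LH_TEST, BBT and SERUM_P4 are an error, not last-wins:
#' auditability over convenience.
#'
#' @param rows A data.frame with columns `individual_id`, `date`, `kind`,
#'   `value` (`value` may be a character column with JSON for structured
#'   payloads, or a list column of ready payloads).
#' @param meta Optional [individual_meta()]; if omitted, a minimal one is
#'   built from the `individual_id` column (age unknown, menarche unknown).
#' @return An `observation_log`: `meta` plus a date-sorted event table with a
#'   `payload` list column. Sorting is deterministic (date, then kind name),
#'   so shuffled input rows yield an identical log.
#' @export
#' @examples
#' rows <- data.frame(
#'   individual_id = "a01",
#'   date = c("2025-01-03", "2025-01-01", "2025-01-02"),
#'   kind = c("SERUM_P4", "BLEED", "LH_TEST"),
#'   value = c("20.1", "", "positive"))
#' log <- parse_event_log(rows)
#' log$events$kind
parse_event_log <- function(rows, meta = NULL) {
  if (is.null(rows) || nrow(rows) == 0)
    ch_abort("EMPTY_LOG", "no event rows supplied")
  need <- c("individual_id", "date", "kind", "value")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    ch_abort("BAD_PAYLOAD", paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  ids <- unique(as.character(rows$individual_id))
  if (length(ids) != 1)
    ch_abort("MIXED_INDIVIDUALS",
             paste("rows mix individuals:", paste(ids, collapse = ", ")))
  dates <- rep(as.Date(NA), nrow(rows))
  for (i in seq_len(nrow(rows))) {
    d <- tryCatch(as.Date(as.character(rows$date[i]), format = "%Y-%m-%d"),
                  error = function(e) as.Date(NA))
    if (is.na(d))
      ch_abort("BAD_DATE", sprintf("unparseable date %s",
                                   deparse(as.character(rows$date[i]))), i)
    dates[i] <- d
  }
  kinds <- as.character(rows$kind)
  bad <- which(!kinds %in% event_kinds())
  if (length(bad))
    ch_abort("BAD_PAYLOAD", sprintf("unknown event kind %s",
                                    deparse(kinds[bad[1]])), bad[1])
  payloads <- vector("list", nrow(rows))
  raw_values <- if (is.list(rows$value)) rows$value else as.list(rows$value)
  for (i in seq_len(nrow(rows)))
    payloads[[i]] <- coerce_payload(kinds[i], raw_values[[i]], row = i)

  events <- data.frame(date = dates, kind = kinds, stringsAsFactors = FALSE)
  events$payload <- payloads
  events <- order_events(events)
  rownames(events) <- NULL

  meas <- events$kind %in% c("BLEED", "LH_TEST", "BBT", "SERUM_P4")
  key <- paste(events$date, events$kind)
  dup <- meas & duplicated(key)
  if (any(dup)) {
    j <- which(dup)[1]
    ch_abort("BAD_PAYLOAD",
             sprintf("duplicate (%s, %s) measurement", events$date[j],
                     events$kind[j]), j)
  }
  if (is.null(meta)) meta <- individual_meta(ids)
  new_observation_log(meta, events)
}

#' Non-fatal quality checks on a parsed log
#'
#' Returns structured warnings without modifying the log: tracking gaps
#' longer than 60 days between consecutive events (`GAP`), and serum
#' progesterone measurements with no preceding positive urinary LH test
#' (`ORPHAN_P4` — the mid-luteal blood draw is only interpretable 7-9 days
#' after a detected LH surge).
#'
#' @param log An `observation_log`.
#' @param gap_days Gap length (days) above which a `GAP` warning is emitted.
#' @return A data.frame of warning records (`kind`, `message`, `detail`);
#'   zero rows when the log is clean.
#' @export
validate_log <- function(log, gap_days = 60) {
  stopifnot(inherits(log, "observation_log"))
  warnings <- list()
  ev <- log$events
  if (nrow(ev) >= 2) {
    d <- sort(unique(ev$date))
    gaps <- as.numeric(diff(d))
    for (i in which(gaps > gap_days)) {
      warnings[[length(warnings) + 1L]] <- ch_warning_record(
        "GAP",
        sprintf("no events for %d days between %s and %s",
                gaps[i], d[i], d[i + 1]),
        sprintf("%s..%s", d[i], d[i + 1]))
    }
  }
  p4 <- ev[ev$kind == "SERUM_P4", , drop = FALSE]
  if (nrow(p4)) {
    lh <- ev[ev$kind == "LH_TEST", , drop = FALSE]
    pos_dates <- lh$date[vapply(lh$payload, isTRUE, logical(1))]
    for (i in seq_len(nrow(p4))) {
      if (!length(pos_dates) || !any(pos_dates < p4$date[i])) {
        warnings[[length(warnings) + 1L]] <- ch_warning_record(
          "ORPHAN_P4",
          sprintf("serum P4 on %s has no preceding positive LH test",
                  p4$date[i]),
          as.character(p4$date[i]))
      }
    }
  }
  if (!length(warnings))
    return(data.frame(kind = character(), message = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, warnings)
}

# --- CSV / JSON interchange -------------------------------------------------

payload_to_string <- function(kind, payload) {
  if (kind %in% c("SYMPTOM"))
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA)))
  if (kind == "CONTRACEPTION") {
    p <- unclass(payload)
    p$start_date <- if (is.null(p$start_date) || all(is.na(p$start_date)))
      NULL else format(p$start_date)
    p <- p[!vapply(p, is.null, logical(1))]
    return(as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA)))
  }
  if (kind == "LH_TEST") return(if (isTRUE(payload)) "positive" else "negative")
  if (length(payload) == 1 && is.na(payload)) return("")
  format(payload, scientific = FALSE, trim = TRUE, digits = 15)
}

#' Write an observation log as interchange CSV
#'
#' Columns `individual_id,date,kind,value`; structured payloads (symptom
#' maps, contraception records) are JSON-encoded in `value`. UTF-8.
#' [parse_event_log()] on the written file reproduces the log exactly
#' (round-trip identity).
#'
#' @param log An `observation_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "observation_log"))
  ev <- log$events
  out <- data.frame(
    individual_id = rep(log$meta$individual_id, nrow(ev)),
    date = format(ev$date),
    kind = ev$kind,
    value = vapply(seq_len(nrow(ev)),
                   function(i) payload_to_string(ev$kind[i], ev$payload[[i]]),
                   character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an interchange CSV into an observation log
#'
#' @param path CSV file written by [write_event_log()] (or by hand with the
#'   same header).
#' @param meta Optional [individual_meta()] to attach.
#' @return An `observation_log`.
#' @export
read_event_log <- function(path, meta = NULL) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  parse_event_log(rows, meta = meta)
}
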