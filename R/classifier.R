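# Decision-tree classification of menstrual cycle status.
#
# The engine walks the adjacency from decision_tree(); every answer is a
# pure predicate of the readable evidence, so identical inputs always give
# identical results and the reported node path is the audit trail. Evidence
# above the requested monitoring-tier cap is deleted before anything else
# reads the log (the privacy contract): a capped classification is
# indistinguishable from one on a log that never contained the deeper data.

tier_filter <- function(log, cap) {
  tiers <- event_tiers()
  keep <- tiers[log$events$kind] <= cap
  new_observation_log(log$meta,
                      log$events[keep, , drop = FALSE])
}

# Evidence extracted from one (closed) cycle row, honouring the tier cap.
cycle_evidence <- function(cycle, cap) {
  if (is.null(cycle)) {
    return(list(length = NA_integer_, lh_tests = 0L,
                lh_positive_day = NA_integer_, luteal = NA_integer_,
                midluteal_p4 = NA_real_, p4_any = NA_real_))
  }
  g <- function(nm, default) {
    v <- cycle[[nm]]
    if (is.null(v) || length(v) == 0) default else v
  }
  ev <- list(length = g("length_days", NA_integer_),
             lh_tests = g("lh_tests_done", 0L),
             lh_positive_day = g("lh_positive_day", NA_integer_),
             luteal = g("luteal_length_days", NA_integer_),
             midluteal_p4 = g("midluteal_p4_nmol_l", NA_real_),
             p4_any = g("p4_any_nmol_l", NA_real_))
  if (is.na(ev$luteal) && !is.na(ev$length) && !is.na(ev$lh_positive_day))
    ev$luteal <- as.integer(ev$length - ev$lh_positive_day + 1L)
  if (cap < 2) {
    ev$lh_tests <- 0L
    ev$lh_positive_day <- NA_integer_
    ev$luteal <- NA_integer_
  }
  if (cap < 3) {
    ev$midluteal_p4 <- NA_real_
    ev$p4_any <- NA_real_
  }
  ev
}

# Predicate table: node id -> answer, given the evidence context.
tree_predicates <- function(ctx) {
  th <- ctx$th
  annual_oligo <- !isTRUE(ctx$annual$extrapolated) &&
    ctx$annual$count <= th$min_annual_bleeds_exclusive
  length_oligo <- !is.na(ctx$ev$length) &&
    ctx$ev$length > th$regular_max_days
  oligo <- if (identical(ctx$oligo_rule, "window")) {
    # individual level: decided on the fully observed 365-day window when
    # available; falls back to the cycle-length criterion on partial logs
    if (!isTRUE(ctx$annual$extrapolated)) annual_oligo else length_oligo
  } else {
    length_oligo || annual_oligo
  }
  list(
    q_menarche = isTRUE(ctx$menarche),
    q_age15 = !is.na(ctx$age) &&
      ctx$age >= th$primary_amenorrhea_age_years,
    q_age14_nosec = !is.na(ctx$age) &&
      ctx$age >= th$primary_amenorrhea_age_no_secondary_years &&
      isFALSE(ctx$secondary),
    q_contraception = isTRUE(ctx$has_hc),
    q_recent_bleed = isTRUE(ctx$recent_bleed),
    q_oligo = oligo,
    q_short_cycle = !is.na(ctx$ev$length) &&
      ctx$ev$length < th$regular_min_days,
    q_lh_tested = ctx$cap >= 2 && ctx$ev$lh_tests > 0,
    q_lh_positive = !is.na(ctx$ev$lh_positive_day),
    q_short_luteal = !is.na(ctx$ev$luteal) &&
      ctx$ev$luteal < th$short_luteal_exclusive_days,
    q_p4_available = ctx$cap >= 3 && !is.na(ctx$ev$midluteal_p4),
    q_p4_above = !is.na(ctx$ev$midluteal_p4) &&
      ctx$ev$midluteal_p4 > th$p4_confirm_exclusive_nmol_l
  )
}

walk_tree <- function(tree, start, predicates) {
  node <- start
  path <- list()
  for (guard in seq_len(length(tree$nodes) + 1L)) {
    if (node %in% tree$leaves)
      return(list(leaf = node,
                  node_path = if (length(path)) do.call(rbind, path)
                              else data.frame(node = character(),
                                              question = character(),
                                              answer = character())))
    nd <- tree$nodes[[node]]
    if (is.null(nd))
      ch_abort("BAD_PAYLOAD", sprintf("tree has no node %s", node))
    ans <- isTRUE(predicates[[node]])
    path[[length(path) + 1L]] <- data.frame(
      node = node, question = nd$question,
      answer = if (ans) "yes" else "no", stringsAsFactors = FALSE)
    node <- if (ans) nd$yes else nd$no
  }
  ch_abort("BAD_PAYLOAD", "decision tree walk did not terminate")
}

# Ovulation status for a leaf given readable evidence.
ovulation_status_for <- function(leaf, ev, cap, th) {
  confirmed_any <- cap >= 3 && !is.na(ev$p4_any) && ev$p4_any > 0
  lh_pos <- !is.na(ev$lh_positive_day)
  switch(leaf,
    C1 = "CONFIRMED",
    D1 = "CONFIRMED",
    E = "ABSENT",
    B1_PROBABLE_OV = "PROBABLE",
    D2 = if (confirmed_any) "CONFIRMED" else if (lh_pos) "PROBABLE"
         else "UNKNOWN",
    F = if (confirmed_any) "CONFIRMED" else if (lh_pos) "PROBABLE"
        else "UNKNOWN",
    "UNKNOWN")
}

#' Classify one closed cycle on the natural-cycle subtree
#'
#' Walks the natural-cycle questions for a single closed cycle: prolonged
#' cycle / low annual frequency first (oligomenorrhea), then short cycle,
#' then the ovulation-evidence chain (LH tests done? any positive? luteal
#' phase short? mid-luteal progesterone available and above 16 nmol/L?).
#' A positive urinary LH test makes ovulation *probable*; only measurable
#' mid-luteal serum progesterone *confirms* it, so a regular cycle with a
#' positive LH test but no blood test stays at `B1_PROBABLE_OV` rather than
#' being promoted to an ovulation-confirmed leaf.
#'
#' @param cycle One closed-cycle row from [segment_cycles()], or a list with
#'   fields `length_days`, `lh_tests_done`, `lh_positive_day`,
#'   `luteal_length_days` (optional; derived from the other two),
#'   `midluteal_p4_nmol_l`, `p4_any_nmol_l`.
#' @param annual Annual bleed context as returned by [bleeds_per_year()]
#'   (`count` and `extrapolated` are read).
#' @param cap Monitoring-tier cap 0-3; evidence above the cap is never read.
#' @param th [thresholds()].
#' @return A list: `leaf`, `ovulation_status` (UNKNOWN/ABSENT/PROBABLE/
#'   CONFIRMED), `node_path` (data.frame of question/answer pairs).
#' @export
#' @examples
#' cyc <- list(length_days = 28, lh_tests_done = 7, lh_positive_day = 14,
#'             midluteal_p4_nmol_l = 20, p4_any_nmol_l = 20)
#' classify_natural_cycle(cyc, annual = list(count = 12,
#'                        extrapolated = FALSE))$leaf  # "C1"
classify_natural_cycle <- function(cycle, annual, cap = 3,
                                   th = thresholds()) {
  if (is.data.frame(cycle)) {
    stopifnot(nrow(cycle) == 1)
    cycle <- as.list(cycle)
  }
  if (is.null(cycle$length_days) || is.na(cycle$length_days))
    ch_abort("BAD_PAYLOAD", "classify_natural_cycle requires a closed cycle")
  ev <- cycle_evidence(cycle, cap)
  ctx <- list(ev = ev, annual = annual, cap = cap, th = th,
              oligo_rule = "cycle")
  tree <- decision_tree()
  res <- walk_tree(tree, tree$natural_subtree_root, tree_predicates(ctx))
  res$ovulation_status <- ovulation_status_for(res$leaf, ev, cap, th)
  res
}

#' Review flags from segmented evidence
#'
#' Non-diagnostic flags mirroring the leaf evidence plus the heavy
#' menstrual bleeding (HMB) criteria: per-menses blood loss strictly above
#' 80 ml raises `HMB`; heavy loss in more than 7 cycles escalates to
#' `HMB_PERSISTENT`. Every flag means "medical review required" — none is a
#' diagnosis.
#'
#' @param log An `observation_log` (already tier-filtered if a cap applies).
#' @param cycles A [segment_cycles()] table for `log`.
#' @param th [thresholds()].
#' @param as_of Window end for the annual bleed count.
#' @return Character vector of flags, sorted; possibly empty. Possible
#'   values: `HMB`, `HMB_PERSISTENT`, `SHORT_LUTEAL`, `LOW_P4`, `OLIGO`,
#'   `EXTRAPOLATED_COUNT`.
#' @export
review_flags <- function(log, cycles, th = thresholds(), as_of = NULL) {
  flags <- character()
  if (nrow(cycles)) {
    loss <- cycles$blood_loss_ml
    heavy <- !is.na(loss) & loss > th$hmb_exclusive_ml
    if (any(heavy)) flags <- c(flags, "HMB")
    if (sum(heavy) > th$hmb_complaint_cycles)
      flags <- c(flags, "HMB_PERSISTENT")
    luteal <- cycles$luteal_length_days
    if (any(!is.na(luteal) & luteal < th$short_luteal_exclusive_days))
      flags <- c(flags, "SHORT_LUTEAL")
    p4 <- cycles$midluteal_p4_nmol_l
    if (any(!is.na(p4) & p4 > 0 & p4 <= th$p4_confirm_exclusive_nmol_l))
      flags <- c(flags, "LOW_P4")
    len <- cycles$length_days
    annual <- bleeds_per_year(log, as_of)
    if (any(!is.na(len) & len > th$regular_max_days) ||
        (!annual$extrapolated &&
         annual$count <= th$min_annual_bleeds_exclusive))
      flags <- c(flags, "OLIGO")
    if (annual$extrapolated) flags <- c(flags, "EXTRAPOLATED_COUNT")
  }
  sort(unique(flags))
}

#' Classify an individual's menstrual cycle status
#'
#' Walks the full decision tree on the evidence readable at the requested
#' monitoring-tier cap:
#'
#' 1. no menarche and under 15 -> `A1` (pre-menarche); no menarche at 15+,
#'    or at 14+ with no secondary sex characteristics -> `A2` (primary
#'    amenorrhea, medical review);
#' 2. active hormonal contraception other than a copper IUD -> `HC`
#'    (hand-off to [classify_contraception()]; a copper IUD user remains on
#'    the naturally-menstruating path);
#' 3. menarche established but no bleed for 3 months (90 days) or more
#'    before `as_of` -> `FHA` (secondary amenorrhea, medical review);
#' 4. otherwise the natural-cycle subtree is walked per closed cycle
#'    ([classify_natural_cycle()]); the individual-level leaf is that of
#'    the most recent closed cycle, except that oligomenorrhea is decided
#'    on the 365-day window: with a fully observed year, 9 or fewer bleed
#'    onsets -> `F` and more than 9 -> not `F`; with partial observation
#'    the annualised count is flagged `EXTRAPOLATED_COUNT` and never
#'    triggers `F` on its own (the most recent cycle's length decides).
#'
#' @param log An `observation_log`.
#' @param cap Monitoring-tier cap 0-3 (see [event_tiers()]). Evidence above
#'   the cap is deleted before classification — the privacy contract.
#' @param as_of Classification date; defaults to the last event date.
#' @param th [thresholds()].
#' @return An object of class `cycle_classification`: `leaf`,
#'   `ovulation_status`, `node_path` (root-to-leaf audit trail),
#'   `review_flags`, `per_cycle` (data.frame: cycle index, leaf, ovulation
#'   status), `tier_used`, `as_of`, `annual`, and for `HC` the
#'   `contraception_leaf` code.
#' @export
#' @examples
#' sim <- simulate_individual("EUMENORRHEIC", n_cycles = 6, seed = 7)
#' res <- classify(sim$log, cap = 3)
#' res$leaf
classify <- function(log, cap = 3, as_of = NULL, th = thresholds()) {
  stopifnot(inherits(log, "observation_log"))
  if (!cap %in% 0:3)
    ch_abort("BAD_PAYLOAD", "cap must be an integer tier 0-3")
  if (nrow(log$events) == 0 && is.null(as_of))
    ch_abort("EMPTY_LOG", "log has no events and no as_of date given")
  flog <- tier_filter(log, cap)
  if (is.null(as_of)) as_of <- max(flog$events$date)
  as_of <- as.Date(as_of)

  meta <- flog$meta
  has_bleeds <- any(flog$events$kind == "BLEED")
  menarche <- meta$menarche_reached
  if (is.na(menarche)) menarche <- has_bleeds
  if (!menarche && is.na(meta$age_years))
    ch_abort("MISSING_AGE",
             "age is required to classify when menarche has not occurred")

  # active hormonal contraception (most recent record at or before as_of)
  contra <- flog$events[flog$events$kind == "CONTRACEPTION" &
                          flog$events$date <= as_of, , drop = FALSE]
  hc_record <- NULL
  if (nrow(contra)) {
    rec <- contra$payload[[nrow(contra)]]
    if (!rec$category %in% c("NONE", "IUD_COPPER")) hc_record <- rec
  }

  bleed_dates <- flog$events$date[flog$events$kind == "BLEED"]
  recent_bleed <- length(bleed_dates) > 0 &&
    as.numeric(as_of - max(bleed_dates)) < th$amenorrhea_days

  cycles <- segment_cycles(flog)
  closed <- cycles[!is.na(cycles$length_days), , drop = FALSE]
  annual <- bleeds_per_year(flog, as_of)

  last_cycle <- if (nrow(closed)) as.list(closed[nrow(closed), ]) else NULL
  ctx <- list(
    menarche = menarche, age = meta$age_years,
    secondary = meta$secondary_sex_characteristics_present,
    has_hc = !is.null(hc_record), recent_bleed = recent_bleed,
    ev = cycle_evidence(last_cycle, cap),
    annual = annual, cap = cap, th = th, oligo_rule = "window")

  tree <- decision_tree()
  res <- walk_tree(tree, tree$root, tree_predicates(ctx))

  per_cycle <- data.frame(cycle = integer(), leaf = character(),
                          ovulation_status = character(),
                          stringsAsFactors = FALSE)
  if (res$leaf %in% c("B1", "B1_PROBABLE_OV", "C1", "D1", "D2", "E", "F") &&
      nrow(closed)) {
    pc <- lapply(seq_len(nrow(closed)), function(i) {
      r <- classify_natural_cycle(closed[i, ], annual, cap, th)
      data.frame(cycle = closed$index[i], leaf = r$leaf,
                 ovulation_status = r$ovulation_status,
                 stringsAsFactors = FALSE)
    })
    per_cycle <- do.call(rbind, pc)
  }

  flags <- review_flags(flog, cycles, th, as_of)
  if (res$leaf == "FHA") flags <- c(flags, "AMENORRHEA")
  if (leaf_info(res$leaf)$medical_review || "HMB" %in% flags)
    flags <- c(flags, "MEDICAL_REVIEW")
  flags <- sort(unique(flags))

  status <- ovulation_status_for(res$leaf, ctx$ev, cap, th)

  structure(list(
    individual_id = meta$individual_id,
    leaf = res$leaf,
    ovulation_status = status,
    node_path = res$node_path,
    review_flags = flags,
    per_cycle = per_cycle,
    tier_used = as.integer(cap),
    as_of = as_of,
    annual = annual,
    contraception_leaf = if (!is.null(hc_record))
      classify_contraception(hc_record)$code else NA_character_
  ), class = "cycle_classification")
}

#' @export
print.cycle_classification <- function(x, ...) {
  info <- leaf_info(x$leaf)
  cat(sprintf("<cycle_classification> %s as of %s (tier %d)\n",
              x$individual_id, format(x$as_of), x$tier_used))
  cat(sprintf("  leaf: %s - %s\n", x$leaf, info$clinical))
  cat(sprintf("  ovulation: %s\n", x$ovulation_status))
  if (length(x$review_flags))
    cat("  flags:", paste(x$review_flags, collapse = ", "), "\n")
  if (nrow(x$per_cycle)) {
    cat(sprintf("  per-cycle leaves: %s\n",
                paste(x$per_cycle$leaf, collapse = " ")))
  }
  invisible(x)
}

#' Serialize a classification deterministically
#'
#' Field order, date formatting and number formatting are fixed, so two
#' classifications of the same log at the same cap and date serialize to
#' byte-identical JSON.
#'
#' @param x A `cycle_classification`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
classification_to_json <- function(x, pretty = FALSE) {
  stopifnot(inherits(x, "cycle_classification"))
  payload <- list(
    individual_id = x$individual_id,
    as_of = format(x$as_of),
    tier_used = x$tier_used,
    leaf = x$leaf,
    leaf_clinical = leaf_info(x$leaf)$clinical,
    ovulation_status = x$ovulation_status,
    review_flags = as.list(x$review_flags),
    node_path = x$node_path[, c("node", "answer")],
    per_cycle = x$per_cycle,
    annual_bleeds = list(count = x$annual$count,
                         coverage = x$annual$coverage,
                         extrapolated = x$annual$extrapolated),
    contraception_leaf = x$contraception_leaf
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                na = "null", pretty = pretty))
}
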