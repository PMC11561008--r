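# Fixture builders: every log used in tests is generated in code.

# rows in interchange-CSV shape
make_rows <- function(dates, kinds, values, id = "t01") {
  data.frame(individual_id = id, date = as.character(dates),
             kind = kinds, value = as.character(values),
             stringsAsFactors = FALSE)
}

# a log of single-day bleed onsets (plus optional extras), via the parser
bleed_log <- function(onsets, id = "t01", meta = NULL, extra_rows = NULL,
                      menses_days = 1L) {
  dates <- as.Date(unlist(lapply(as.Date(onsets), function(o)
    as.character(o + 0:(menses_days - 1)))))
  rows <- make_rows(dates, "BLEED", "", id = id)
  if (!is.null(extra_rows)) rows <- rbind(rows, extra_rows)
  if (is.null(meta)) meta <- individual_meta(id, age_years = 28,
                                             menarche_reached = TRUE)
  parse_event_log(rows, meta = meta)
}

# minimal non-bleeding log (one symptom event) for menarche/amenorrhea paths
symptom_only_log <- function(date = as.Date("2025-06-01"), meta) {
  rows <- make_rows(date, "SYMPTOM", '{"energy": 3}')
  parse_event_log(rows, meta = meta)
}

# a closed-cycle evidence list for classify_natural_cycle()
cycle_fixture <- function(length_days, lh_positive_day = NA_integer_,
                          lh_tests_done = NULL, midluteal_p4 = NA_real_,
                          p4_any = NULL) {
  if (is.null(lh_tests_done))
    lh_tests_done <- if (is.na(lh_positive_day)) 0L else 7L
  if (is.null(p4_any)) p4_any <- midluteal_p4
  list(length_days = as.integer(length_days),
       lh_positive_day = as.integer(lh_positive_day),
       lh_tests_done = as.integer(lh_tests_done),
       midluteal_p4_nmol_l = as.numeric(midluteal_p4),
       p4_any_nmol_l = as.numeric(p4_any))
}

regular_annual <- function() list(count = 12, extrapolated = FALSE)

# intended leaves of the seven natural phenotypes, in sorted order
natural_phenotype_leaves <- function() {
  sort(vapply(cyclehealth:::natural_phenotypes(),
              function(ph) phenotype_profile(ph)$intended_leaf,
              character(1)))
}

# a full-year log with k evenly spaced bleed onsets, 3-day menses
year_log <- function(k, start = as.Date("2024-01-01"), menses_days = 3L) {
  onsets <- start + round((seq_len(k) - 1) * 365 / k)
  bleed_log(onsets, menses_days = menses_days)
}

# validate that a node_path is a root-to-leaf walk in the adjacency
expect_valid_path <- function(result, start = NULL) {
  tree <- decision_tree()
  if (is.null(start)) start <- tree$root
  node <- start
  path <- result$node_path
  for (i in seq_len(nrow(path))) {
    expect_identical(path$node[i], node)
    nd <- tree$nodes[[node]]
    node <- if (path$answer[i] == "yes") nd$yes else nd$no
  }
  expect_identical(node, result$leaf)
}
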