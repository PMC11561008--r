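# Synthetic-log simulator: generates observation logs with ground truth for
# each hormonal phenotype on the qualitative continuum (eumenorrheic,
# luteal-phase-defect variants, anovulatory, oligomenorrheic, amenorrheic)
# and for hormonal-contraception regimens, powering every recovery test.
#
# Hormone curves are arbitrary-unit piecewise shapes: only the ordinal
# relations (estrogen peak before the LH spike; progesterone peak strictly
# after it) and the serum-progesterone nmol/L scale are contractual.

# urinary LH positivity threshold (arbitrary units): the 1-day surge (100)
# is positive and baseline (5) is negative with a 10x margin
lh_threshold <- function() 50

natural_phenotypes <- function() {
  c("EUMENORRHEIC", "LPD_LOW_P4", "LPD_SHORT", "ANOVULATORY", "OLIGO",
    "FHA", "PRIMARY_AMENORRHEA")
}

all_phenotypes <- function() {
  c(natural_phenotypes(), "OCP_USER", "HORMONAL_IUD_USER")
}

#' Phenotype profile: the study conditions for one simulated hormonal type
#'
#' Returns the generating parameters for a phenotype: cycle-length
#' distribution (truncated to its support), ovulation placement, mid-luteal
#' serum progesterone plateau (nmol/L), basal-body-temperature shift (degC),
#' bleed duration, per-menses loss distribution, default individual
#' metadata, and the leaf the classifier is expected to assign at full
#' monitoring. Amenorrheic phenotypes generate zero bleed onsets.
#'
#' @param name One of `r paste(all_phenotypes(), collapse = ", ")`.
#' @return A list of class `phenotype_profile`.
#' @export
#' @examples
#' phenotype_profile("EUMENORRHEIC")$intended_leaf  # "C1"
phenotype_profile <- function(name) {
  name <- match.arg(name, all_phenotypes())
  base <- list(
    name = name,
    cycle_length_dist = c(mean = 28, sd = 2, min = 26, max = 32),
    # luteal length = luteal_offset + jitter, truncated to [luteal_min,
    # luteal_max] so the phenotype's luteal class is preserved; ovulation
    # day = length - luteal + 1 then always falls in the testable window
    luteal_offset = 14, ovulation_sd = 1,
    luteal_min = 14, luteal_max = 16,
    ovulatory = TRUE,
    luteal_p4_level = 20, bbt_shift_c = 0.35,
    bleed_duration_days = 5,
    loss_ml_dist = c(mean = 40, sd = 10),
    age_years = 28, menarche_reached = TRUE, secondary = TRUE,
    contraception = NA_character_,
    bleeding = TRUE,
    intended_leaf = "C1")
  p <- switch(name,
    EUMENORRHEIC = base,
    LPD_LOW_P4 = utils::modifyList(base, list(
      luteal_p4_level = 10, intended_leaf = "D1")),
    LPD_SHORT = utils::modifyList(base, list(
      cycle_length_dist = c(mean = 27, sd = 1.5, min = 24, max = 30),
      luteal_offset = 12, luteal_min = 12, luteal_max = 13,
      luteal_p4_level = 18, intended_leaf = "D2")),
    ANOVULATORY = utils::modifyList(base, list(
      ovulatory = FALSE, luteal_p4_level = 0, bbt_shift_c = 0,
      intended_leaf = "E")),
    OLIGO = utils::modifyList(base, list(
      cycle_length_dist = c(mean = 45, sd = 6, min = 36, max = 60),
      ovulatory = FALSE, luteal_p4_level = 0, bbt_shift_c = 0,
      intended_leaf = "F")),
    FHA = utils::modifyList(base, list(
      bleeding = FALSE, ovulatory = FALSE, luteal_p4_level = 0,
      bbt_shift_c = 0, intended_leaf = "FHA")),
    PRIMARY_AMENORRHEA = utils::modifyList(base, list(
      bleeding = FALSE, ovulatory = FALSE, luteal_p4_level = 0,
      bbt_shift_c = 0, age_years = 16, menarche_reached = FALSE,
      intended_leaf = "A2")),
    OCP_USER = utils::modifyList(base, list(
      bleeding = FALSE, ovulatory = FALSE, luteal_p4_level = 0,
      bbt_shift_c = 0, contraception = "OCP_COMBINED_MONO",
      intended_leaf = "HC")),
    HORMONAL_IUD_USER = utils::modifyList(base, list(
      bleeding = FALSE, ovulatory = FALSE, luteal_p4_level = 0,
      bbt_shift_c = 0, contraception = "IUD_HORMONAL",
      intended_leaf = "HC")))
  structure(p, class = c("phenotype_profile", "list"))
}

#' Noise specification for the observation model
#'
#' @param bbt_sd Gaussian noise on daily basal body temperature (degC).
#' @param p4_sd Gaussian noise on the serum progesterone draw (nmol/L).
#' @param lh_false_negative,lh_false_positive Per-test flip probabilities
#'   for the urinary LH result.
#' @param miss_rate Probability that any scheduled observation (LH test,
#'   temperature, blood draw) is independently skipped — an adherence /
#'   survey-fatigue model.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(bbt_sd = 0.05, p4_sd = 0,
                       lh_false_negative = 0, lh_false_positive = 0,
                       miss_rate = 0) {
  stopifnot(bbt_sd >= 0, p4_sd >= 0,
            lh_false_negative >= 0, lh_false_negative <= 1,
            lh_false_positive >= 0, lh_false_positive <= 1,
            miss_rate >= 0, miss_rate <= 1)
  structure(list(bbt_sd = bbt_sd, p4_sd = p4_sd,
                 lh_false_negative = lh_false_negative,
                 lh_false_positive = lh_false_positive,
                 miss_rate = miss_rate), class = c("noise_spec", "list"))
}

#' Latent daily hormone states for one cycle
#'
#' Piecewise parametric curves in arbitrary units: estrone-3-glucuronide
#' (E1G, urinary estrogen metabolite) rises through the follicular phase to
#' a pre-ovulatory peak; LH shows a 1-day surge on the ovulation day
#' (absent for anovulatory phenotypes); pregnanediol glucuronide (PdG,
#' urinary progesterone metabolite) and latent serum progesterone follow a
#' bell centred 7 days after ovulation, whose plateau equals the
#' phenotype's `luteal_p4_level` in nmol/L. For anovulatory phenotypes the
#' LH maximum stays below the urinary-test positivity threshold and serum
#' progesterone stays at baseline.
#'
#' @param phenotype A [phenotype_profile()] or its name.
#' @param cycle_length Length of the cycle (days), within the phenotype's
#'   support.
#' @param ovulation_day Cycle day of ovulation, or `NULL` for anovulatory
#'   phenotypes (supplying one for an anovulatory phenotype is a
#'   `BAD_PHENOTYPE` error).
#' @return A data.frame: `day`, `e1g`, `pdg`, `lh`, `fsh`,
#'   `serum_p4_nmol_l`.
#' @export
#' @examples
#' h <- hormone_profile("EUMENORRHEIC", 28, 14)
#' which.max(h$lh)           # 14
#' h$serum_p4_nmol_l[21]     # > 16
hormone_profile <- function(phenotype, cycle_length, ovulation_day = NULL) {
  if (is.character(phenotype)) phenotype <- phenotype_profile(phenotype)
  stopifnot(inherits(phenotype, "phenotype_profile"))
  dist <- phenotype$cycle_length_dist
  if (phenotype$bleeding &&
      (cycle_length < dist[["min"]] || cycle_length > dist[["max"]]))
    ch_abort("BAD_PHENOTYPE",
             sprintf("cycle length %d outside support [%d, %d] for %s",
                     cycle_length, dist[["min"]], dist[["max"]],
                     phenotype$name))
  if (!phenotype$ovulatory && !is.null(ovulation_day))
    ch_abort("BAD_PHENOTYPE",
             sprintf("%s is anovulatory; ovulation_day must be NULL",
                     phenotype$name))
  if (phenotype$ovulatory && is.null(ovulation_day))
    ch_abort("BAD_PHENOTYPE", "ovulatory phenotype needs an ovulation_day")
  day <- seq_len(cycle_length)
  if (phenotype$ovulatory) {
    ov <- ovulation_day
    e1g <- 15 + 85 * pmax(0, 1 - abs(day - (ov - 1)) / (ov - 1))
    lh <- ifelse(day == ov, 100, 5)
    peak <- ov + 7
    bell <- exp(-(day - peak)^2 / (2 * 3^2))
    serum_p4 <- phenotype$luteal_p4_level * bell
    pdg <- 0.3 + serum_p4 / 2
    fsh <- 10 + 5 * exp(-(day - 3)^2 / 8)
  } else {
    e1g <- rep(20, cycle_length)
    lh <- rep(5, cycle_length)
    serum_p4 <- rep(0, cycle_length)
    pdg <- rep(0.3, cycle_length)
    fsh <- rep(10, cycle_length)
  }
  data.frame(day = day, e1g = e1g, pdg = pdg, lh = lh, fsh = fsh,
             serum_p4_nmol_l = serum_p4)
}

# stable per-individual stream: derived from the global seed and index,
# kept below 2^31 - 1
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973 + 1) %%
               2147483646) + 1L
}

draw_trunc_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(n * 2 + 4, mean, sd))
    x <- x[x >= lo & x <= hi]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

#' Simulate one individual's observation log with ground truth
#'
#' Draws cycle lengths and ovulation days from the phenotype profile,
#' renders the latent hormone curves, then *observes* them: bleed events for
#' the bleed duration from each onset with a per-menses blood-loss estimate;
#' urinary LH tests on the planner's schedule ([lh_test_days()]), positive
#' when the latent LH is at or above the positivity threshold, stopping
#' after the first positive, with optional false-result flips; a serum
#' progesterone draw 7 days after a positive test; daily basal body
#' temperature with the phenotype's luteal shift plus Gaussian noise; and a
#' per-cycle symptom survey. Each scheduled observation is independently
#' skipped with probability `miss_rate` (adherence model). Contraception
#' phenotypes instead record their method and any expected withdrawal
#' bleeding inside hormone-free windows. The same seed always reproduces a
#' byte-identical log.
#'
#' @param phenotype A [phenotype_profile()] or its name.
#' @param n_cycles Number of cycles (or 30-day months for non-bleeding
#'   phenotypes) to simulate.
#' @param noise A [noise_spec()].
#' @param seed Integer seed (mandatory: no implicit randomness).
#' @param individual_id Identifier for the log.
#' @param start_date First day of the log.
#' @return A list: `log` (an `observation_log`) and `truth` (phenotype
#'   name, intended leaf, onset dates, cycle lengths, ovulation cycle-days,
#'   luteal lengths, mid-luteal serum progesterone values, `as_of`).
#' @export
#' @examples
#' sim <- simulate_individual("EUMENORRHEIC", n_cycles = 6, seed = 7,
#'                            noise = noise_spec(bbt_sd = 0))
#' classify(sim$log, cap = 3)$leaf  # "C1"
simulate_individual <- function(phenotype, n_cycles = 12,
                                noise = noise_spec(), seed,
                                individual_id = NULL,
                                start_date = as.Date("2024-01-01")) {
  if (missing(seed) || is.null(seed))
    ch_abort("BAD_PAYLOAD", "simulate_individual requires an explicit seed")
  if (is.character(phenotype)) phenotype <- phenotype_profile(phenotype)
  stopifnot(inherits(phenotype, "phenotype_profile"),
            inherits(noise, "noise_spec"), n_cycles >= 1)
  set.seed(as.integer(seed))
  start_date <- as.Date(start_date)
  if (is.null(individual_id))
    individual_id <- sprintf("sim-%s-%d", tolower(phenotype$name),
                             as.integer(seed))
  meta <- individual_meta(
    individual_id, age_years = phenotype$age_years,
    menarche_reached = phenotype$menarche_reached,
    secondary_sex_characteristics_present = phenotype$secondary)

  dates <- list(); kinds <- list(); payloads <- list()
  add <- function(date, kind, payload) {
    i <- length(dates) + 1L
    dates[[i]] <<- date; kinds[[i]] <<- kind; payloads[[i]] <<- payload
  }
  keep_obs <- function() noise$miss_rate == 0 ||
    stats::runif(1) >= noise$miss_rate

  truth <- list(phenotype = phenotype$name,
                intended_leaf = phenotype$intended_leaf,
                onsets = as.Date(character()),
                cycle_lengths = integer(), ovulation_days = integer(),
                luteal_lengths = integer(), midluteal_p4 = numeric())

  if (!is.na(phenotype$contraception)) {
    # contraception phenotype: method record + schedule-driven observations
    rec <- contraception_record(phenotype$contraception,
                                start_date = start_date)
    add(start_date, "CONTRACEPTION", rec)
    horizon <- n_cycles * 28L
    leafc <- classify_contraception(rec)
    if (!is.null(leafc$schedule) && !is.na(leafc$schedule$active_days)) {
      sch <- expand_schedule(leafc, start_date, horizon)
      wd <- sch$days$date[sch$days$expected_withdrawal_bleed]
      # withdrawal bleeding on the middle days of each hormone-free window
      runs <- split(wd, cumsum(c(TRUE, diff(wd) > 1)))
      for (r in runs) {
        bd <- r[seq_len(min(3, length(r))) + 1]
        bd <- bd[!is.na(bd)]
        for (d in seq_along(bd)) add(bd[d], "BLEED", NA_real_)
      }
    }
    for (d in 0:(horizon - 1)) {
      if (keep_obs())
        add(start_date + d, "BBT",
            round(36.4 + stats::rnorm(1, 0, max(noise$bbt_sd, 1e-9)), 3))
    }
  } else if (!phenotype$bleeding) {
    # amenorrheic phenotypes: daily temperature, weekly symptoms, no bleeds
    horizon <- n_cycles * 30L
    for (d in 0:(horizon - 1)) {
      if (keep_obs())
        add(start_date + d, "BBT",
            round(36.4 + stats::rnorm(1, 0, max(noise$bbt_sd, 1e-9)), 3))
      if (d %% 7 == 0)
        add(start_date + d, "SYMPTOM",
            list(energy = round(stats::runif(1, 1, 5))))
    }
  } else {
    dist <- phenotype$cycle_length_dist
    lengths <- draw_trunc_int(n_cycles, dist[["mean"]], dist[["sd"]],
                              dist[["min"]], dist[["max"]])
    onsets <- start_date + c(0, cumsum(lengths[-n_cycles]))
    expected_len <- as.integer(round(dist[["mean"]]))
    truth$onsets <- onsets
    truth$cycle_lengths <- lengths

    for (i in seq_len(n_cycles)) {
      len <- lengths[i]; onset <- onsets[i]
      ov <- NA_integer_
      if (phenotype$ovulatory) {
        luteal <- as.integer(round(stats::rnorm(1, phenotype$luteal_offset,
                                                phenotype$ovulation_sd)))
        luteal <- max(phenotype$luteal_min,
                      min(luteal, phenotype$luteal_max))
        ov <- len - luteal + 1L
        ov <- max(8L, min(ov, min(19L, len - 8L)))
      }
      truth$ovulation_days <- c(truth$ovulation_days, ov)
      truth$luteal_lengths <- c(truth$luteal_lengths,
                                if (is.na(ov)) NA_integer_
                                else len - ov + 1L)
      hormones <- hormone_profile(phenotype, len,
                                  if (is.na(ov)) NULL else ov)

      # menses
      for (b in 0:(phenotype$bleed_duration_days - 1))
        if (b < len) add(onset + b, "BLEED", NA_real_)
      loss <- max(5, stats::rnorm(1, phenotype$loss_ml_dist[["mean"]],
                                  phenotype$loss_ml_dist[["sd"]]))
      add(onset, "BLOOD_LOSS_ESTIMATE", round(loss, 1))

      # urinary LH tests on the planner schedule, stop at first positive
      test_dates <- lh_test_days(onset, expected_len)
      pos_date <- as.Date(NA)
      for (td in seq_along(test_dates)) {
        cd <- as.integer(test_dates[td] - onset) + 1L
        if (cd > len) break
        if (!keep_obs()) next
        pos <- hormones$lh[cd] >= lh_threshold()
        if (pos && noise$lh_false_negative > 0 &&
            stats::runif(1) < noise$lh_false_negative) pos <- FALSE
        if (!pos && noise$lh_false_positive > 0 &&
            stats::runif(1) < noise$lh_false_positive) pos <- TRUE
        add(test_dates[td], "LH_TEST", pos)
        if (pos) { pos_date <- test_dates[td]; break }
      }

      # confirmatory serum draw 7 days after the positive urine test
      p4_val <- NA_real_
      if (!is.na(pos_date)) {
        draw_date <- blood_test_day(pos_date)$target
        cd <- as.integer(draw_date - onset) + 1L
        if (cd <= len && keep_obs()) {
          p4_val <- max(0, hormones$serum_p4_nmol_l[cd] +
                          stats::rnorm(1, 0, max(noise$p4_sd, 1e-9)))
          add(draw_date, "SERUM_P4", round(p4_val, 2))
        }
      }
      truth$midluteal_p4 <- c(truth$midluteal_p4, p4_val)

      # daily basal body temperature with the luteal shift
      shift_from <- if (is.na(ov)) Inf else ov + 1L
      for (cd in seq_len(len)) {
        if (!keep_obs()) next
        temp <- 36.4 + if (cd >= shift_from) phenotype$bbt_shift_c else 0
        add(onset + cd - 1L, "BBT",
            round(temp + stats::rnorm(1, 0, max(noise$bbt_sd, 1e-9)), 3))
      }

      add(onset, "SYMPTOM", list(cramps = round(stats::runif(1, 0, 5))))
    }
  }

  events <- data.frame(date = as.Date(unlist(lapply(dates, as.numeric)),
                                      origin = "1970-01-01"),
                       kind = unlist(kinds), stringsAsFactors = FALSE)
  events$payload <- payloads
  events <- order_events(events)
  rownames(events) <- NULL
  log <- new_observation_log(meta, events)
  truth$as_of <- max(events$date)
  list(log = log, truth = truth)
}

#' Phenotype recovery experiment
#'
#' Simulates `n_per_phenotype` individuals per phenotype (per-individual
#' seeds derived deterministically from the global seed), classifies each
#' at the given monitoring-tier cap, and cross-tabulates the intended leaf
#' against the assigned leaf.
#'
#' @param n_per_phenotype Individuals per phenotype (>= 1).
#' @param noise A [noise_spec()].
#' @param cap Monitoring-tier cap used for classification.
#' @param seed Global integer seed.
#' @param phenotypes Phenotype names; defaults to the seven natural
#'   phenotypes.
#' @param n_cycles Cycles simulated per individual.
#' @return A list: `confusion` (table intended x assigned), `recovery`
#'   (named per-phenotype recovery rate), `overall` (fraction of the
#'   diagonal), `n_per_phenotype`.
#' @export
#' @examples
#' \donttest{
#' r <- recovery_experiment(5, noise_spec(bbt_sd = 0), cap = 3, seed = 1)
#' r$overall  # 1 under zero noise at full monitoring
#' }
recovery_experiment <- function(n_per_phenotype, noise = noise_spec(),
                                cap = 3, seed,
                                phenotypes = natural_phenotypes(),
                                n_cycles = 8) {
  if (missing(seed) || is.null(seed))
    ch_abort("BAD_PAYLOAD", "recovery_experiment requires an explicit seed")
  stopifnot(n_per_phenotype >= 1)
  intended <- character(); assigned <- character()
  idx <- 0L
  for (ph in phenotypes) {
    for (i in seq_len(n_per_phenotype)) {
      idx <- idx + 1L
      sim <- simulate_individual(ph, n_cycles = n_cycles, noise = noise,
                                 seed = derive_seed(seed, idx))
      res <- classify(sim$log, cap = cap, as_of = sim$truth$as_of)
      intended <- c(intended, sim$truth$intended_leaf)
      assigned <- c(assigned, res$leaf)
    }
  }
  levels_all <- sort(unique(c(intended, assigned)))
  confusion <- table(intended = factor(intended, levels_all),
                     assigned = factor(assigned, levels_all))
  per_ph <- vapply(split(intended == assigned, intended), mean, numeric(1))
  list(confusion = confusion, recovery = per_ph,
       overall = mean(intended == assigned),
       n_per_phenotype = n_per_phenotype)
}
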