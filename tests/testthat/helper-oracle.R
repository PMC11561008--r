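# Independent flat re-implementation of the per-cycle leaf criteria, used
# as the oracle for boundary sweeps and the two-oracle agreement check. It
# evaluates each leaf's published predicate directly on the evidence (no
# tree walk, its own literal constants) and resolves by fixed precedence.

oracle_natural_leaf <- function(length_days, annual_count,
                                annual_extrapolated, cap,
                                lh_tests_done, lh_positive_day,
                                midluteal_p4, p4_any = midluteal_p4) {
  # readable evidence at this tier cap
  if (cap < 2) {
    lh_tests_done <- 0
    lh_positive_day <- NA
  }
  if (cap < 3) {
    midluteal_p4 <- NA
    p4_any <- NA
  }
  lh_pos <- !is.na(lh_positive_day)
  luteal <- if (lh_pos) length_days - lh_positive_day + 1 else NA

  # leaf predicates, each a direct transcription of its published criteria
  pred_oligo <- length_days > 35 ||
    (!annual_extrapolated && annual_count <= 9)
  pred_short_cycle <- length_days < 21
  pred_untested <- lh_tests_done == 0
  pred_anovulatory <- lh_tests_done > 0 && !lh_pos
  pred_short_luteal <- lh_pos && !is.na(luteal) && luteal < 14
  pred_probable_only <- lh_pos && is.na(midluteal_p4)
  pred_eumenorrheic <- lh_pos && !is.na(midluteal_p4) && midluteal_p4 > 16
  pred_low_p4 <- lh_pos && !is.na(midluteal_p4) && midluteal_p4 <= 16

  if (pred_oligo) return("F")
  if (pred_short_cycle) return("D2")
  if (pred_untested) return("B1")
  if (pred_anovulatory) return("E")
  if (pred_short_luteal) return("D2")
  if (pred_probable_only) return("B1_PROBABLE_OV")
  if (pred_eumenorrheic) return("C1")
  if (pred_low_p4) return("D1")
  stop("oracle: unreachable evidence combination")
}

# random but internally coherent evidence vectors for the agreement check
random_evidence <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(15:60, 1)
    tests <- sample(0:12, 1)
    pos_day <- NA_integer_
    if (tests > 0 && runif(1) < 0.6)
      pos_day <- sample(8:min(19, len - 1), 1)
    p4 <- NA_real_
    if (!is.na(pos_day) && runif(1) < 0.7)
      p4 <- round(runif(1, 0, 30), 1)
    out[[i]] <- list(length_days = len,
                     annual_count = sample(0:15, 1),
                     annual_extrapolated = runif(1) < 0.3,
                     cap = sample(0:3, 1),
                     lh_tests_done = tests,
                     lh_positive_day = pos_day,
                     midluteal_p4 = p4)
  }
  out
}
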