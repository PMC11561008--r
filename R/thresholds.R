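#' Classification thresholds
#'
#' Every scalar criterion used by the decision trees and review flags, with
#' the published defaults. All keys can be overridden (e.g. from a YAML
#' config via [load_thresholds()]), but the defaults are the contract:
#'
#' * `regular_min_days` (21) / `regular_max_days` (35): a regular menstrual
#'   cycle lasts 21-35 days inclusive; longer is prolonged
#'   (oligomenorrhea evidence), shorter suggests a luteal phase defect.
#' * `min_annual_bleeds_exclusive` (9): naturally menstruating individuals
#'   have more than 9 bleeds per year; 9 or fewer is oligomenorrhea.
#' * `short_luteal_exclusive_days` (14): a next bleed fewer than 14 days
#'   after a positive LH test marks a short luteal phase.
#' * `p4_confirm_exclusive_nmol_l` (16): mid-luteal serum progesterone
#'   strictly above 16 nmol/L confirms an adequate luteal phase
#'   (eumenorrheic); at or below, a luteal phase defect. Any measurable
#'   progesterone confirms that ovulation occurred.
#' * `amenorrhea_months` (3) / `amenorrhea_days` (90): bleeding stopped for
#'   3 months (90 days) or more after established menarche is secondary
#'   amenorrhea.
#' * `primary_amenorrhea_age_years` (15): no menarche by 15 is primary
#'   amenorrhea; `primary_amenorrhea_age_no_secondary_years` (14) applies
#'   when no secondary sex characteristics are present.
#' * `hmb_exclusive_ml` (80): per-menses blood loss strictly above 80 ml is
#'   heavy menstrual bleeding; `hmb_complaint_cycles` (7): heavy bleeding in
#'   more than 7 cycles escalates the flag.
#'
#' @param ... Named overrides of any key above.
#' @return A named list of thresholds (class `cycle_thresholds`).
#' @export
#' @examples
#' thresholds()$regular_max_days
#' thresholds(regular_max_days = 38)$regular_max_days
thresholds <- function(...) {
  defaults <- list(
    regular_min_days = 21,
    regular_max_days = 35,
    min_annual_bleeds_exclusive = 9,
    short_luteal_exclusive_days = 14,
    p4_confirm_exclusive_nmol_l = 16,
    amenorrhea_months = 3,
    amenorrhea_days = 90,
    primary_amenorrhea_age_years = 15,
    primary_amenorrhea_age_no_secondary_years = 14,
    hmb_exclusive_ml = 80,
    hmb_complaint_cycles = 7
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    ch_abort("BAD_PAYLOAD", paste("unknown threshold keys:",
                                  paste(unknown, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  bad <- vapply(defaults, function(x) !is.numeric(x) || x <= 0, logical(1))
  if (any(bad))
    ch_abort("BAD_PAYLOAD", paste("thresholds must be positive numbers:",
                                  paste(names(defaults)[bad], collapse = ", ")))
  if (defaults$regular_min_days >= defaults$regular_max_days)
    ch_abort("BAD_PAYLOAD", "regular_min_days must be < regular_max_days")
  structure(defaults, class = c("cycle_thresholds", "list"))
}

#' Load thresholds from a YAML config file
#'
#' Keys absent from the file keep their published defaults.
#'
#' @param path YAML file with any subset of the [thresholds()] keys.
#' @return A `cycle_thresholds` list.
#' @export
load_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(thresholds, cfg)
}
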