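# Leaf codes, their clinical/lay descriptions, hormonal-profile ids, and the
# decision-tree adjacency loader.

leaf_codes <- function() {
  c("A1", "A2", "FHA", "B1", "B1_PROBABLE_OV", "C1", "D1", "D2", "E", "F",
    "HC")
}

leaf_table <- function() {
  tab <- rbind(
    data.frame(code = "A1",
      clinical = "Pre-menarche",
      nonclinical = "First period has not yet happened",
      characteristics = paste("Less than 15 years of age;",
        "pre-commencement of the menstrual cycle."),
      profile_id = "flat_prepubertal", medical_review = FALSE),
    data.frame(code = "A2",
      clinical = "Primary amenorrhea",
      nonclinical = "No first period by the expected age",
      characteristics = paste("No menstrual bleed by the age of 15 years",
        "despite secondary sex characteristics being present, or by the age",
        "of 14 years with no secondary sex characteristics present.",
        "Medical support is required for review of the absent menstrual",
        "cycle."),
      profile_id = "flat_prepubertal", medical_review = TRUE),
    data.frame(code = "FHA",
      clinical = "Functional hypothalamic amenorrhea / secondary amenorrhea",
      nonclinical = "Periods have stopped for 3 months or more",
      characteristics = paste("Menstrual bleeding has stopped for 3 months",
        "or more after menarche was established; may result from",
        "psychological, nutritional or physical stressors. All other",
        "medical causes must be excluded by a clinician; no medication or",
        "contraception explains the absence. Medical review required."),
      profile_id = "flat_suppressed", medical_review = TRUE),
    data.frame(code = "B1",
      clinical = "Naturally menstruating",
      nonclinical = "Regular periods, no hormonal contraception",
      characteristics = paste("Regular menstrual bleeds, typically within a",
        "21-35 day cycle, and more than 9 menstrual bleeds a year. Cannot",
        "yet be classified as eumenorrheic, luteal phase defect or",
        "anovulatory because urinary ovulation (LH surge) tests and blood",
        "tests have not been completed; ovulation is unconfirmed."),
      profile_id = "unconfirmed_biphasic", medical_review = FALSE),
    data.frame(code = "B1_PROBABLE_OV",
      clinical = "Naturally menstruating, probable ovulation",
      nonclinical = "Regular periods with a positive ovulation test",
      characteristics = paste("Regular menstrual bleeds with a positive",
        "urinary LH test, so ovulation is probable. A mid-luteal blood",
        "progesterone test 7-9 days after the positive urine test is",
        "needed to confirm ovulation and the second-phase hormone level."),
      profile_id = "unconfirmed_biphasic", medical_review = FALSE),
    data.frame(code = "C1",
      clinical = "Eumenorrheic (biphasic, confirmed ovulation)",
      nonclinical = "Regular periods with confirmed ovulation and healthy second-half hormones",
      characteristics = paste("Regular menstrual bleeds within a 21-35 day",
        "cycle, positive urinary LH test confirming the surge, luteal",
        "phase around 14 days, and mid-luteal blood progesterone above 16",
        "nmol/L, confirming ovulation and two distinct hormonal phases:",
        "eumenorrheic."),
      profile_id = "biphasic_ovulatory", medical_review = FALSE),
    data.frame(code = "D1",
      clinical = "Luteal phase defect (low progesterone)",
      nonclinical = "Ovulation happened but second-half hormone levels are low",
      characteristics = paste("Cycles of 21-35 days with 9 or more cycles a",
        "year and a positive urinary LH test, but mid-luteal blood",
        "progesterone at or below 16 nmol/L. The presence of progesterone,",
        "even at low levels, confirms ovulation occurred. Often missed",
        "because cycle length does not change. Medical review required."),
      profile_id = "blunted_luteal", medical_review = TRUE),
    data.frame(code = "D2",
      clinical = "Luteal phase defect (short luteal phase / short cycle)",
      nonclinical = "The second half of the cycle is too short",
      characteristics = paste("The next menstrual bleed starts fewer than 14",
        "days after a positive urinary LH test (or the whole cycle is",
        "shorter than 21 days). Ovulation is probable; a mid-luteal blood",
        "test in the second half of the cycle and medical review are",
        "required."),
      profile_id = "short_luteal", medical_review = TRUE),
    data.frame(code = "E",
      clinical = "Anovulatory cycle",
      nonclinical = "No ovulation detected this cycle",
      characteristics = paste("Menstrual bleeds may be regular (every 21-35",
        "days, 9 or more a year) but urinary ovulation tests are negative:",
        "no LH surge detected. Lack of ovulation is confirmed by low",
        "mid-luteal blood progesterone."),
      profile_id = "monophasic_anovulatory", medical_review = FALSE),
    data.frame(code = "F",
      clinical = "Oligomenorrheic (prolonged cycle)",
      nonclinical = "Long or infrequent cycles",
      characteristics = paste("Menstrual bleeds occur less regularly, every",
        "35 days or more, with 9 or fewer bleeds in a year. Cycles can be",
        "ovulatory or anovulatory; confirmation requires urinary LH testing",
        "and phase-specific blood tests. Medical review required."),
      profile_id = "prolonged_irregular", medical_review = TRUE),
    data.frame(code = "HC",
      clinical = "Hormonal contraception user",
      nonclinical = "Using hormonal contraception",
      characteristics = paste("Exogenous synthetic hormones suppress the",
        "natural hormonal cycle; bleeding during hormone-free windows is a",
        "withdrawal bleed, not a menstrual bleed. Continue with the",
        "contraception decision tree to identify the method and its",
        "monitoring options."),
      profile_id = "exogenous_suppressed", medical_review = FALSE)
  )
  rownames(tab) <- tab$code
  tab
}

#' Describe a classification leaf
#'
#' Returns the clinical description, the lay (non-clinical) description, the
#' characteristics text, the hormonal-continuum profile id linking the leaf
#' to its qualitative hormone profile, and whether the leaf carries a
#' medical-review notice. The engine is educational, not diagnostic: every
#' review notice means "medical review required", never a diagnosis.
#'
#' @param code A leaf code (one of `r paste(leaf_codes(), collapse = ", ")`).
#' @return A one-row list with fields `code`, `clinical`, `nonclinical`,
#'   `characteristics`, `profile_id`, `medical_review`.
#' @export
#' @examples
#' leaf_info("C1")$clinical
leaf_info <- function(code) {
  tab <- leaf_table()
  if (length(code) != 1 || !code %in% tab$code)
    ch_abort("UNKNOWN_CODE", sprintf("unknown leaf code %s", deparse(code)))
  as.list(tab[code, ])
}

# --- decision-tree adjacency ------------------------------------------------

tree_cache <- new.env(parent = emptyenv())

#' The decision-tree adjacency
#'
#' The tree is shipped as data (`inst/extdata/decision_tree.yaml`), not
#' code: each question node names its yes/no child, which is either another
#' question or a leaf code. [classify()] walks this adjacency, so the full
#' node path it reports is by construction a root-to-leaf walk, and
#' alternative question orderings can be tested by supplying a different
#' file.
#'
#' @param path Optional path to an alternative adjacency YAML.
#' @return A list: `root`, `natural_subtree_root`, `leaves`, and `nodes`
#'   (named list of `question`/`yes`/`no`).
#' @export
decision_tree <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(tree_cache$default)) return(tree_cache$default)
    path <- system.file("extdata", "decision_tree.yaml",
                        package = "cyclehealth", mustWork = TRUE)
    tree <- read_tree_yaml(path)
    tree_cache$default <- tree
    return(tree)
  }
  read_tree_yaml(path)
}

read_tree_yaml <- function(path) {
  tree <- yaml::read_yaml(path)
  # yaml 1.1 may parse bare yes/no keys as TRUE/FALSE; normalise
  tree$nodes <- lapply(tree$nodes, function(nd) {
    names(nd) <- vapply(names(nd), function(nm) {
      if (nm %in% c("TRUE", "yes", "y")) "yes"
      else if (nm %in% c("FALSE", "no", "n")) "no"
      else nm
    }, character(1))
    nd
  })
  stopifnot(all(c("root", "natural_subtree_root", "leaves", "nodes") %in%
                  names(tree)))
  for (nm in names(tree$nodes)) {
    nd <- tree$nodes[[nm]]
    kids <- c(nd$yes, nd$no)
    ok <- kids %in% c(names(tree$nodes), tree$leaves)
    if (!all(ok))
      ch_abort("BAD_PAYLOAD",
               sprintf("tree node %s has unknown child %s", nm,
                       kids[!ok][1]))
  }
  tree
}
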