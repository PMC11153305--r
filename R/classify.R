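#' Classify the change in HbA1c between baseline and a follow-up visit
#'
#' Individual HbA1c change is categorised on the mmol/mol scale with an
#' inclusive 5 mmol/mol (0.5 percentage point) threshold: `improved` when the
#' final value is at least `threshold` lower than baseline, `deteriorated`
#' when at least `threshold` higher, `stable` otherwise. Percent-scale inputs
#' should be converted with [hba1c_percent_to_mmol()] first — the threshold is
#' never applied independently on the % scale.
#'
#' @param baseline,final HbA1c in mmol/mol, > 0.
#' @param threshold Category threshold in mmol/mol (default 5).
#' @return One of `"improved"`, `"stable"`, `"deteriorated"`.
#' @examples
#' classify_hba1c_change(52, 47)    # improved (boundary inclusive)
#' classify_hba1c_change(52, 56.9)  # stable
#' classify_hba1c_change(52, 57)    # deteriorated
#' @export
classify_hba1c_change <- function(baseline, final, threshold = 5) {
  .check_positive(baseline, "baseline HbA1c")
  .check_positive(final, "final HbA1c")
  stopifnot(threshold > 0)
  delta <- final - baseline
  ifelse(delta <= -threshold, "improved",
         ifelse(delta >= threshold, "deteriorated", "stable"))
}

#' Classify the change in glucose-lowering medication between two regimens
#'
#' `increased` if any drug's daily dose rose or any new drug appeared;
#' otherwise `decreased` if any drug's dose fell or a drug was stopped;
#' otherwise `stable`. Escalation dominates in mixed changes (one drug up,
#' another down) because any escalation signals failed glycaemic control.
#' Dose comparison is exact — doses are discrete tablet multiples, so no
#' tolerance band is applied.
#'
#' @param baseline,final [regimen()] objects.
#' @return One of `"decreased"`, `"stable"`, `"increased"`.
#' @examples
#' classify_medication_change(regimen("metformin", 1000), regimen("metformin", 500))
#' @export
classify_medication_change <- function(baseline, final) {
  stopifnot(inherits(baseline, "regimen"), inherits(final, "regimen"))
  drugs <- union(baseline$drug_name, final$drug_name)
  b <- structure(baseline$daily_dose, names = baseline$drug_name)
  f <- structure(final$daily_dose, names = final$drug_name)
  bdose <- ifelse(drugs %in% names(b), b[drugs], 0)
  fdose <- ifelse(drugs %in% names(f), f[drugs], 0)
  if (any(fdose > bdose)) return("increased")
  if (any(fdose < bdose)) return("decreased")
  "stable"
}

#' Composite glycaemic-management category
#'
#' Combines the medication-change and HbA1c-change categories into the
#' composite endpoint. The full decision table (medication, HbA1c):
#' \itemize{
#'   \item (decreased, improved/stable) -> improved: less drug support without
#'     meaningful HbA1c worsening.
#'   \item (decreased, deteriorated) -> deteriorated, with `tie_break_applied`
#'     set: participants who used less medication but whose HbA1c rose beyond
#'     the threshold are not formally covered by the category definitions and
#'     are conservatively called deteriorated.
#'   \item (stable, improved) -> improved; (stable, stable) -> stable;
#'     (stable, deteriorated) -> deteriorated.
#'   \item (increased, anything) -> deteriorated: escalation of drug treatment
#'     marks failed glycaemic management regardless of the achieved HbA1c.
#' }
#'
#' @param hba1c_category `"improved"`, `"stable"` or `"deteriorated"`.
#' @param medication_category `"decreased"`, `"stable"` or `"increased"`.
#' @return List with `category` and `tie_break_applied`.
#' @export
classify_glycaemic_management <- function(hba1c_category, medication_category) {
  h <- match.arg(hba1c_category, c("improved", "stable", "deteriorated"))
  m <- match.arg(medication_category, c("decreased", "stable", "increased"))
  tie <- FALSE
  if (m == "increased") {
    cat <- "deteriorated"
  } else if (m == "decreased") {
    if (h == "deteriorated") { cat <- "deteriorated"; tie <- TRUE }
    else cat <- "improved"
  } else { # medication stable
    cat <- switch(h, improved = "improved", stable = "stable",
                  deteriorated = "deteriorated")
  }
  list(category = cat, tie_break_applied = tie)
}

#' Classify a cohort's glycaemic outcomes at a follow-up timepoint
#'
#' Runs the three classifiers over every participant with both a baseline and
#' a follow-up visit, and tabulates arm-by-category counts for the three
#' endpoints. Participants missing the follow-up visit (loss to follow-up)
#' are excluded and logged in `excluded`.
#'
#' @param cohort A cohort as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @param timepoint Follow-up timepoint in months: 6 or 12.
#' @param drug_table A [drug_table][load_drug_table] used to resolve regimens.
#' @param threshold HbA1c category threshold in mmol/mol.
#' @return A list with `results` (one row per classified participant:
#'   participant_id, arm, hba1c_category, medication_category,
#'   glycaemic_management, tie_break_applied), `tables` (named list of
#'   arm x category count matrices for `medication`, `hba1c`,
#'   `glycaemic_management`), and `excluded` (data.frame of participant_id
#'   and reason).
#' @export
classify_cohort <- function(cohort, timepoint, drug_table = default_drug_table(),
                            threshold = 5) {
  stopifnot(timepoint %in% c(6, 12))
  visits <- cohort$visits
  base <- visits[visits$timepoint_months == 0, ]
  fin <- visits[visits$timepoint_months == timepoint, ]
  ids <- unique(base$participant_id)

  rows <- list(); excl <- list()
  for (id in ids) {
    b <- base[base$participant_id == id, ]
    f <- fin[fin$participant_id == id, ]
    if (nrow(f) == 0 || is.na(f$hba1c_mmol_mol[1])) {
      excl[[length(excl) + 1]] <- data.frame(
        participant_id = id, reason = sprintf("no %d-month visit", timepoint),
        stringsAsFactors = FALSE)
      next
    }
    hc <- classify_hba1c_change(b$hba1c_mmol_mol[1], f$hba1c_mmol_mol[1],
                                threshold)
    mc <- classify_medication_change(.visit_regimen(b), .visit_regimen(f))
    g <- classify_glycaemic_management(hc, mc)
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = id, arm = b$arm[1], hba1c_category = hc,
      medication_category = mc, glycaemic_management = g$category,
      tie_break_applied = g$tie_break_applied, stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), arm = character(),
               hba1c_category = character(), medication_category = character(),
               glycaemic_management = character(),
               tie_break_applied = logical(), stringsAsFactors = FALSE)
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(), reason = character(),
               stringsAsFactors = FALSE)

  arms <- c("FMD", "control")
  tab <- function(col, levels) {
    m <- t(sapply(arms, function(a)
      table(factor(results[[col]][results$arm == a], levels = levels))))
    rownames(m) <- arms
    m
  }
  tables <- list(
    medication = tab("medication_category", c("decreased", "stable", "increased")),
    hba1c = tab("hba1c_category", c("improved", "stable", "deteriorated")),
    glycaemic_management = tab("glycaemic_management",
                               c("improved", "stable", "deteriorated"))
  )
  list(results = results, tables = tables, excluded = excluded)
}

# regimen from the wide drug_k_name / drug_k_dose visit columns
.visit_regimen <- function(visit_row) {
  nm_cols <- grep("^drug_[0-9]+_name$", names(visit_row), value = TRUE)
  drugs <- character(); doses <- numeric()
  for (nc in nm_cols) {
    dc <- sub("_name$", "_dose", nc)
    nm <- visit_row[[nc]][1]
    if (!is.na(nm) && nzchar(nm)) {
      drugs <- c(drugs, nm)
      doses <- c(doses, visit_row[[dc]][1])
    }
  }
  regimen(drugs, doses)
}
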