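#' Score a cohort's visits: MES, HbA1c (%), MES-corrected HbA1c
#'
#' Adds per-visit columns `mes_total` (total medication effect score of the
#' visit's regimen), `hba1c_percent` (NGSP scale) and `hba1c_corrected`
#' (HbA1c % + total MES) to the cohort's visit table.
#'
#' @param cohort A `glycman_cohort`.
#' @param drug_table A [drug_table][load_drug_table].
#' @return The cohort with augmented `visits`.
#' @export
score_cohort <- function(cohort, drug_table = default_drug_table()) {
  v <- cohort$visits
  v$mes_total <- vapply(seq_len(nrow(v)), function(i)
    total_mes(.visit_regimen(v[i, ]), drug_table)$total, 0)
  v$hba1c_percent <- ifelse(is.na(v$hba1c_mmol_mol), NA_real_,
                            hba1c_mmol_to_percent(pmax(v$hba1c_mmol_mol, 1)))
  v$hba1c_corrected <- v$hba1c_percent + v$mes_total
  out <- cohort
  out$visits <- v
  out
}

#' Run the full glycaemic-outcome analysis pipeline
#'
#' read/simulate -> score -> classify -> test -> report. Computes, for the
#' chosen analysis set: per-visit MES and MES-corrected HbA1c; the three
#' categorical endpoints (medication change, HbA1c change, glycaemic
#' management) at the requested timepoint with arm-by-category tables and
#' association tests under the expected-count test-selection rule; the
#' stopped-medication and additional-medication 2x2 endpoints; optionally
#' linear mixed-model treatment effects for the continuous outcomes with
#' Benjamini-Hochberg correction of the secondary ones. Deterministic given
#' its inputs.
#'
#' @param cohort A `glycman_cohort` (from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param drug_table A [drug_table][load_drug_table].
#' @param analysis_set `"ITT"` or `"PP"`.
#' @param timepoint Follow-up months for the categorical endpoints.
#' @param fit_effects Fit mixed-model treatment effects (needs visits at
#'   baseline and both follow-ups for stable estimates; disable for minimal
#'   fixture cohorts).
#' @return A `trial_report` list; see Details.
#' @export
run_pipeline <- function(cohort, drug_table = default_drug_table(),
                         analysis_set = "ITT", timepoint = 12,
                         fit_effects = TRUE) {
  scored <- score_cohort(cohort, drug_table)
  sel <- select_analysis_set(scored, analysis_set)
  if (!any(sel$visits$arm == "FMD") || !any(sel$visits$arm == "control")) {
    stop("analysis requires both arms to be non-empty", call. = FALSE)
  }

  cls <- classify_cohort(sel, timepoint, drug_table)
  tests <- lapply(cls$tables, association_test)

  two_by_two <- .medication_2x2_tables(sel, timepoint)
  tests$stopped_medication <- association_test(two_by_two$stopped)
  tests$additional_medication <- association_test(two_by_two$additional)

  effects <- NULL; bh <- NULL
  if (fit_effects) {
    outs <- intersect(c("hba1c_mmol_mol", "mes_total", "hba1c_corrected",
                        "weight_kg"),
                      names(sel$visits))
    effects <- lapply(outs, function(o)
      fit_treatment_effect(sel$visits, o, timepoint = timepoint))
    names(effects) <- outs
    secondary <- setdiff(outs, c("hba1c_mmol_mol", "mes_total"))
    if (length(secondary)) {
      p <- vapply(effects[secondary], function(e) e$p_value, 0)
      adj <- benjamini_hochberg(p)
      bh <- data.frame(outcome = secondary, p_raw = unname(p),
                       p_adjusted = adj$adjusted, rejected = adj$rejected,
                       stringsAsFactors = FALSE)
    }
  }

  tables_pct <- lapply(cls$tables, function(m)
    round(100 * m / rowSums(m)))
  report <- list(
    analysis_set = analysis_set, timepoint = timepoint,
    n_classified = c(FMD = sum(cls$results$arm == "FMD"),
                     control = sum(cls$results$arm == "control")),
    category_tables = cls$tables,
    category_percentages = tables_pct,
    excluded = cls$excluded,
    association_tests = tests,
    two_by_two = two_by_two,
    treatment_effects = effects,
    bh_secondary = bh,
    provenance = list(
      source = cohort$provenance,
      analysis_set = analysis_set, timepoint = timepoint,
      hash = .fnv1a(c(utils::capture.output(utils::str(cohort$visits)),
                      analysis_set, timepoint))
    )
  )
  class(report) <- "trial_report"
  report
}

# 2x2 endpoint tables among classified (both-visit) participants:
# stopped = on drug at baseline, drug-free at follow-up;
# additional = a drug name present at follow-up that was absent at baseline.
.medication_2x2_tables <- function(cohort, timepoint) {
  v <- cohort$visits
  base <- v[v$timepoint_months == 0, ]
  fin <- v[v$timepoint_months == timepoint, ]
  common <- intersect(base$participant_id, fin$participant_id)
  stopped <- matrix(0L, 2, 2, dimnames = list(c("FMD", "control"),
                                              c("yes", "no")))
  added <- stopped
  for (id in common) {
    b <- .visit_regimen(base[base$participant_id == id, ])
    f <- .visit_regimen(fin[fin$participant_id == id, ])
    arm <- base$arm[base$participant_id == id][1]
    s <- nrow(b) > 0 && nrow(f) == 0
    a <- length(setdiff(f$drug_name, b$drug_name)) > 0
    stopped[arm, if (s) "yes" else "no"] <- stopped[arm, if (s) "yes" else "no"] + 1L
    added[arm, if (a) "yes" else "no"] <- added[arm, if (a) "yes" else "no"] + 1L
  }
  list(stopped = stopped, additional = added)
}

#' Serialise a trial report to JSON
#'
#' @param report A `trial_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- report
  out$association_tests <- lapply(out$association_tests, unclass)
  out$treatment_effects <- lapply(out$treatment_effects, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report> ", x$analysis_set, " analysis at ", x$timepoint,
      " months; classified FMD ", x$n_classified[["FMD"]], " / control ",
      x$n_classified[["control"]], "\n", sep = "")
  for (nm in c("medication", "hba1c", "glycaemic_management")) {
    cat("\n", nm, " (p = ",
        format(x$association_tests[[nm]]$p_value, digits = 3), ", ",
        x$association_tests[[nm]]$test_used, "):\n", sep = "")
    print(x$category_tables[[nm]])
  }
  if (!is.null(x$treatment_effects)) {
    cat("\ntreatment effects:\n")
    for (e in x$treatment_effects) print(e)
  }
  invisible(x)
}

# tiny FNV-1a string hash for provenance fingerprints (no external deps)
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
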