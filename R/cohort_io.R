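#' Read a cohort from the canonical long-format CSV
#'
#' One row per participant-visit. Required columns: `participant_id`, `arm`
#' (`FMD`/`control`), `sex`, `weight_stratum`, `timepoint_months` (0/6/12),
#' `hba1c_mmol_mol`, `weight_kg`, `compliance_flag`; any number of
#' `drug_<k>_name` / `drug_<k>_dose` pairs; optional OGTT columns
#' `glucose_<t>` / `insulin_<t>`. Schema violations are reported with the
#' offending column or participant; a duplicated (participant, timepoint)
#' pair is a hard error.
#'
#' @param path CSV file path.
#' @return A `glycman_cohort` (list with `visits`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "arm", "sex", "weight_stratum",
                "timepoint_months", "hba1c_mmol_mol", "weight_kg",
                "compliance_flag")
  miss <- setdiff(required, names(v))
  if (length(miss)) stop("cohort file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad_tp <- !v$timepoint_months %in% c(0, 6, 12)
  if (any(bad_tp)) {
    stop("invalid timepoint_months at data row(s) ",
         paste(utils::head(which(bad_tp)), collapse = ", "),
         " (allowed: 0, 6, 12)", call. = FALSE)
  }
  key <- paste(v$participant_id, v$timepoint_months)
  if (anyDuplicated(key)) {
    dup <- v$participant_id[duplicated(key)][1]
    stop("duplicated participant-timepoint row for participant '", dup, "'",
         call. = FALSE)
  }
  bad_arm <- !v$arm %in% c("FMD", "control")
  if (any(bad_arm)) stop("invalid arm value(s): ",
                         paste(unique(v$arm[bad_arm]), collapse = ", "),
                         call. = FALSE)
  v$compliance_flag <- as.logical(v$compliance_flag)
  for (col in names(v)) {          # empty CSV fields are missing values
    if (is.character(v[[col]])) v[[col]][v[[col]] == ""] <- NA_character_
  }
  structure(list(visits = v, provenance = list(source = path)),
            class = "glycman_cohort")
}

#' Write a cohort to the canonical long-format CSV
#'
#' @param cohort A `glycman_cohort`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$visits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build a cohort realising given joint outcome-category counts
#'
#' Test/fixture constructor: given, per arm, a 3x3 matrix of joint counts
#' (rows = medication category decreased/stable/increased, columns = HbA1c
#' category improved/stable/deteriorated), builds a minimal cohort whose
#' 12-month classification reproduces exactly those counts. Within the
#' "decreased" row, `n_stopped` participants stop metformin entirely (rest
#' halve the dose); within the "increased" row, `n_added` gain a second drug
#' (rest step the dose up). Optional extra participants with a missing
#' 12-month visit emulate loss to follow-up.
#'
#' @param joint Named list with elements `FMD` and `control`, each a 3x3
#'   count matrix as above.
#' @param n_stopped,n_added Named numeric (`FMD`, `control`).
#' @param n_lost Named numeric: participants with baseline only.
#' @param compliant_joint Optional named list like `joint` giving, for each
#'   arm, the joint counts among protocol-compliant participants (must be
#'   cellwise <= `joint`); defaults to everyone compliant.
#' @return A `glycman_cohort`.
#' @export
cohort_from_categories <- function(joint,
                                   n_stopped = c(FMD = 0, control = 0),
                                   n_added = c(FMD = 0, control = 0),
                                   n_lost = c(FMD = 0, control = 0),
                                   compliant_joint = NULL) {
  med_levels <- c("decreased", "stable", "increased")
  hba_levels <- c("improved", "stable", "deteriorated")
  # baseline 52 mmol/mol; finals chosen safely inside each category
  final_for <- c(improved = 45, stable = 52, deteriorated = 59)
  rows <- list()
  idn <- 0
  for (arm in c("FMD", "control")) {
    J <- joint[[arm]]
    CJ <- if (is.null(compliant_joint)) J else compliant_joint[[arm]]
    stopifnot(all(dim(J) == c(3, 3)), all(CJ <= J))
    left_stop <- n_stopped[[arm]]; left_add <- n_added[[arm]]
    for (mi in 1:3) for (hi in 1:3) {
      k <- J[mi, hi]
      if (k == 0) next
      n_comp <- CJ[mi, hi]
      for (j in seq_len(k)) {
        idn <- idn + 1
        id <- sprintf("%s%03d", substr(arm, 1, 1), idn)
        med <- med_levels[mi]
        base_dose <- 1000; d2n <- NA_character_; d2d <- NA_real_
        if (med == "decreased") {
          if (left_stop > 0) { fin_dose <- 0; left_stop <- left_stop - 1 }
          else fin_dose <- 500
        } else if (med == "stable") {
          fin_dose <- base_dose
        } else {
          if (left_add > 0) {
            fin_dose <- base_dose; d2n <- "gliclazide"; d2d <- 30
            left_add <- left_add - 1
          } else fin_dose <- 1500
        }
        compliant <- j <= n_comp
        mk <- function(tp, hba, dose, dn2 = NA_character_, dd2 = NA_real_) {
          data.frame(participant_id = id, arm = arm, sex = "M",
                     weight_stratum = "upto100kg", timepoint_months = tp,
                     hba1c_mmol_mol = hba, weight_kg = 90,
                     compliance_flag = compliant,
                     drug_1_name = if (dose > 0) "metformin" else NA_character_,
                     drug_1_dose = if (dose > 0) dose else NA_real_,
                     drug_2_name = dn2, drug_2_dose = dd2,
                     stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1]] <- mk(0, 52, base_dose)
        rows[[length(rows) + 1]] <- mk(12, final_for[[hba_levels[hi]]],
                                       fin_dose, d2n, d2d)
      }
    }
    for (j in seq_len(n_lost[[arm]])) {
      idn <- idn + 1
      id <- sprintf("%sL%02d", substr(arm, 1, 1), j)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = id, arm = arm, sex = "M",
        weight_stratum = "upto100kg", timepoint_months = 0,
        hba1c_mmol_mol = 52, weight_kg = 90, compliance_flag = FALSE,
        drug_1_name = "metformin", drug_1_dose = 1000,
        drug_2_name = NA_character_, drug_2_dose = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  visits <- do.call(rbind, rows)
  rownames(visits) <- NULL
  structure(list(visits = visits,
                 provenance = list(source = "cohort_from_categories")),
            class = "glycman_cohort")
}
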