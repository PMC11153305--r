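#' Drug specification tables for medication effect scoring
#'
#' A drug table lists, for each glucose-lowering drug, its maximum
#' recommended daily dose and its adjustment factor: the expected maximal
#' HbA1c reduction (in percentage points) when the drug is used as
#' monotherapy at the maximum dose. The factors are not universal constants;
#' the defaults shipped in `inst/extdata/drug_table.json` are typical values
#' from the medication-effect-score literature and are user-overridable —
#' nothing in the scoring logic hard-codes a factor.
#'
#' @param path Path to a JSON file: an array of objects with fields
#'   `name`, `class`, `max_daily_dose`, `dose_unit`, `adjustment_factor`.
#' @return A `drug_table`: a data.frame with one row per drug.
#' @export
load_drug_table <- function(path) {
  if (!file.exists(path)) stop("drug table file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as_drug_table(raw)
}

#' @rdname load_drug_table
#' @param x A data.frame with the drug-table columns.
#' @export
as_drug_table <- function(x) {
  needed <- c("name", "class", "max_daily_dose", "dose_unit", "adjustment_factor")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("drug table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[needed]
  for (i in seq_len(nrow(x))) {
    if (!is.finite(x$max_daily_dose[i]) || x$max_daily_dose[i] <= 0) {
      stop("drug table entry '", x$name[i], "': max_daily_dose must be > 0",
           call. = FALSE)
    }
    if (!is.finite(x$adjustment_factor[i]) || x$adjustment_factor[i] <= 0) {
      stop("drug table entry '", x$name[i], "': adjustment_factor must be > 0",
           call. = FALSE)
    }
  }
  if (anyDuplicated(x$name)) {
    stop("drug table has duplicated name(s): ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("drug_table", "data.frame")
  x
}

#' @rdname load_drug_table
#' @export
default_drug_table <- function() {
  load_drug_table(system.file("extdata", "drug_table.json", package = "glycman"))
}

#' Construct a single drug specification
#'
#' Convenience constructor used in examples and tests; equivalent to one row
#' of a drug table.
#'
#' @param name Drug name (unique within a table).
#' @param max_daily_dose Maximum recommended daily dose, > 0.
#' @param adjustment_factor Expected maximal HbA1c reduction (percentage
#'   points) at the maximum monotherapy dose, > 0.
#' @param class Drug class label.
#' @param dose_unit Dosing unit, e.g. `"mg"` or `"IU"`.
#' @export
drug_spec <- function(name, max_daily_dose, adjustment_factor,
                      class = "unspecified", dose_unit = "mg") {
  as_drug_table(data.frame(
    name = name, class = class, max_daily_dose = max_daily_dose,
    dose_unit = dose_unit, adjustment_factor = adjustment_factor,
    stringsAsFactors = FALSE
  ))
}

#' @export
print.drug_table <- function(x, ...) {
  cat("<drug_table> ", nrow(x), " drug(s)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a drug regimen
#'
#' A regimen is a participant's set of prescriptions at one visit: at most
#' one prescription per drug, non-negative daily doses. A zero dose is
#' equivalent to the drug being absent; an empty regimen (diet-only
#' treatment) is valid.
#'
#' @param drug_name Character vector of drug names.
#' @param daily_dose Numeric vector of daily doses, same length, all >= 0.
#' @return A `regimen` data.frame with columns `drug_name`, `daily_dose`.
#' @examples
#' regimen("metformin", 1000)
#' regimen()  # diet only
#' @export
regimen <- function(drug_name = character(), daily_dose = numeric()) {
  if (length(drug_name) != length(daily_dose)) {
    stop("drug_name and daily_dose must have equal length", call. = FALSE)
  }
  if (any(!is.finite(daily_dose)) || any(daily_dose < 0)) {
    stop("daily_dose must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(drug_name)) {
    stop("regimen has duplicated drug(s): ",
         paste(unique(drug_name[duplicated(drug_name)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(drug_name = as.character(drug_name),
                    daily_dose = as.numeric(daily_dose),
                    stringsAsFactors = FALSE)
  # zero dose == drug absent
  out <- out[out$daily_dose > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regimen", "data.frame")
  out
}
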