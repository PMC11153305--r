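#' Medication effect score (MES) for a single prescription
#'
#' The MES of a drug at a given dose is the HbA1c reduction (percentage
#' points) expected if that dose were used as monotherapy:
#' \deqn{MES = \min(dose / max\_dose, 1) \times adjustment\ factor}
#' The ratio is capped at 1 because the adjustment factor already represents
#' the maximal monotherapy effect; a supra-maximal dose cannot be expected
#' to do more. Capping is flagged so audits can see it happened.
#'
#' @param drug_name Name of the drug; must resolve in `table`.
#' @param daily_dose Actual daily dose, >= 0, in the drug's dosing unit.
#' @param table A [drug_table][load_drug_table].
#' @return A list with `score` (numeric) and `capped` (logical).
#' @examples
#' tab <- drug_spec("metformin", 2000, 1.5)
#' drug_mes("metformin", 1000, tab)$score  # 0.75
#' @export
drug_mes <- function(drug_name, daily_dose, table) {
  stopifnot(inherits(table, "drug_table"))
  if (!is.finite(daily_dose) || daily_dose < 0) {
    stop("daily_dose must be finite and >= 0", call. = FALSE)
  }
  i <- match(drug_name, table$name)
  if (is.na(i)) stop("unknown drug: '", drug_name, "'", call. = FALSE)
  ratio <- daily_dose / table$max_daily_dose[i]
  capped <- ratio > 1
  list(score = min(ratio, 1) * table$adjustment_factor[i], capped = capped)
}

#' Total medication effect score of a regimen
#'
#' Sums the per-drug MES over a multidrug regimen. A total MES of 2.5 is
#' read as a maximal expected HbA1c decrease of 2.5 percentage points for
#' that regimen. An empty (diet-only) regimen scores 0.
#'
#' @param r A [regimen()].
#' @param table A [drug_table][load_drug_table].
#' @return A `mes_result`: list with `per_drug` (named numeric), `total`
#'   and `capped_flags` (character vector of capped drug names).
#' @examples
#' tab <- default_drug_table()
#' total_mes(regimen("metformin", 1500), tab)$total
#' @export
total_mes <- function(r, table) {
  stopifnot(inherits(r, "regimen"), inherits(table, "drug_table"))
  unknown <- setdiff(r$drug_name, table$name)
  if (length(unknown)) {
    stop("unknown drug(s) in regimen: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  per <- numeric(0)
  capped <- character(0)
  for (i in seq_len(nrow(r))) {
    m <- drug_mes(r$drug_name[i], r$daily_dose[i], table)
    per[r$drug_name[i]] <- m$score
    if (m$capped) capped <- c(capped, r$drug_name[i])
  }
  structure(list(per_drug = per, total = sum(per), capped_flags = capped),
            class = "mes_result")
}

#' @export
print.mes_result <- function(x, ...) {
  cat("<mes_result> total MES =", format(x$total), "\n")
  if (length(x$per_drug)) {
    for (nm in names(x$per_drug)) {
      cat("  ", nm, ": ", format(x$per_drug[[nm]]),
          if (nm %in% x$capped_flags) " [dose capped at max]" else "", "\n",
          sep = "")
    }
  } else cat("  (no glucose-lowering drugs)\n")
  invisible(x)
}

#' HbA1c corrected for glucose-lowering medication use
#'
#' Adds the total MES to the measured HbA1c (both on the % scale): a
#' participant whose HbA1c is held at 6.9% by a regimen expected to lower
#' HbA1c by 0.7 points is scored as 7.6% — the glycaemic control they would
#' be expected to show without drug support. Strictly increasing in both
#' arguments.
#'
#' @param hba1c_percent Measured HbA1c on the NGSP % scale, > 0.
#' @param mes_total Total MES in HbA1c percentage points, >= 0.
#' @return MES-corrected HbA1c (%).
#' @examples
#' mes_corrected_hba1c(6.9, 0.7)  # 7.6
#' @export
mes_corrected_hba1c <- function(hba1c_percent, mes_total) {
  .check_positive(hba1c_percent, "HbA1c (%)")
  if (any(!is.finite(mes_total)) || any(mes_total < 0)) {
    stop("mes_total must be finite and >= 0", call. = FALSE)
  }
  hba1c_percent + mes_total
}
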