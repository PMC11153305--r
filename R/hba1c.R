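#' Convert HbA1c between IFCC (mmol/mol) and NGSP (%) scales
#'
#' Clinical trials in Europe report glycated haemoglobin on the IFCC scale
#' (mmol/mol) while the medication effect score and much of the older
#' literature work on the NGSP percentage scale. The two are related by the
#' NGSP master-equation linear form \eqn{\% = 0.09148 \times mmol/mol + 2.152}.
#'
#' @param x Numeric vector of HbA1c values, strictly positive.
#' @return Numeric vector on the other scale.
#' @examples
#' hba1c_mmol_to_percent(52.2)  # 6.9 (to 1 decimal)
#' hba1c_percent_to_mmol(hba1c_mmol_to_percent(48))  # 48
#' @export
hba1c_mmol_to_percent <- function(x) {
  .check_positive(x, "HbA1c (mmol/mol)")
  0.09148 * x + 2.152
}

#' @rdname hba1c_mmol_to_percent
#' @export
hba1c_percent_to_mmol <- function(x) {
  .check_positive(x, "HbA1c (%)")
  (x - 2.152) / 0.09148
}

.check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be finite and > 0", call. = FALSE)
  }
  invisible(x)
}
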