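#' Construct an OGTT curve
#'
#' Timed glucose/insulin samples from a 2-hour oral glucose tolerance test,
#' in SI units as measured in the clinic. The fasting (t = 0) sample must be
#' present; post-load samples may be missing down to two.
#'
#' @param times Sampling times in minutes, strictly increasing, starting at 0.
#' @param glucose Plasma glucose in mmol/l, > 0 at every time.
#' @param insulin Plasma insulin in pmol/l, >= 0 at every time.
#' @return An `ogtt_curve` list.
#' @examples
#' ogtt_curve(c(0, 30, 60, 90, 120), c(8.3, 11.5, 13.3, 12.0, 10.5),
#'            c(156, 420, 540, 480, 360))
#' @export
ogtt_curve <- function(times, glucose, insulin) {
  stopifnot(length(times) == length(glucose), length(times) == length(insulin))
  if (times[1] != 0) stop("fasting (t = 0) sample required", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(times) < 3) stop("need the fasting sample and >= 2 post-load samples",
                              call. = FALSE)
  if (any(glucose <= 0)) stop("glucose must be > 0 everywhere", call. = FALSE)
  if (any(insulin < 0)) stop("insulin must be >= 0", call. = FALSE)
  structure(list(times = times, glucose = glucose, insulin = insulin,
                 units = c(glucose = "mmol/l", insulin = "pmol/l")),
            class = "ogtt_curve")
}

# conversion constants: glucose mg/dl per mmol/l; insulin pmol/l per uU/ml.
# The insulin constant varies 6.0-6.945 across laboratories; 6.0 is used and
# recorded in units_note so downstream indices are auditable.
.GLUCOSE_MGDL_PER_MMOL <- 18.016
.INSULIN_PMOL_PER_UU <- 6.0

#' Convert an OGTT curve from SI to conventional units
#'
#' The Matsuda index is defined in conventional units (glucose mg/dl,
#' insulin uU/ml). Conversion: mg/dl = mmol/l x 18.016; uU/ml = pmol/l / 6.0.
#' The constants used are recorded in the returned curve's `units_note`.
#'
#' @param curve An [ogtt_curve()] in SI units.
#' @return An `ogtt_curve` in conventional units with a `units_note` field.
#' @export
convert_units <- function(curve) {
  stopifnot(inherits(curve, "ogtt_curve"))
  if (identical(unname(curve$units["glucose"]), "mg/dl")) return(curve)
  out <- curve
  out$glucose <- curve$glucose * .GLUCOSE_MGDL_PER_MMOL
  out$insulin <- curve$insulin / .INSULIN_PMOL_PER_UU
  out$units <- c(glucose = "mg/dl", insulin = "uU/ml")
  out$units_note <- sprintf(
    "glucose mg/dl = mmol/l x %.3f; insulin uU/ml = pmol/l / %.1f",
    .GLUCOSE_MGDL_PER_MMOL, .INSULIN_PMOL_PER_UU)
  out
}

#' Matsuda whole-body insulin-sensitivity index
#'
#' \deqn{10000 / \sqrt{G_0 I_0 \bar{G} \bar{I}}} in conventional units, where
#' the means are arithmetic means over all sampled values including the
#' fasting sample (the original formulation; a trapezoidal-mean variant is
#' available via `mean_method = "trapezoid"`).
#'
#' @param curve An [ogtt_curve()] (SI or conventional; converted as needed).
#' @param mean_method `"arithmetic"` (default) or `"trapezoid"` (time-weighted
#'   mean over the sampling interval).
#' @return Dimensionless index, > 0 for positive inputs.
#' @export
matsuda_index <- function(curve, mean_method = c("arithmetic", "trapezoid")) {
  mean_method <- match.arg(mean_method)
  cv <- convert_units(curve)
  g0 <- cv$glucose[1]; i0 <- cv$insulin[1]
  if (mean_method == "arithmetic") {
    gm <- mean(cv$glucose); im <- mean(cv$insulin)
  } else {
    span <- diff(range(cv$times))
    gm <- trapezoid_auc(cv$times, cv$glucose) / span
    im <- trapezoid_auc(cv$times, cv$insulin) / span
  }
  prod4 <- g0 * i0 * gm * im
  if (prod4 <= 0) stop("Matsuda index undefined: zero fasting or mean value",
                       call. = FALSE)
  10000 / sqrt(prod4)
}

#' Insulinogenic index (early insulin secretion)
#'
#' \eqn{(I_{30} - I_0) / (G_{30} - G_0)} in conventional units: the early
#' insulin response per unit of glucose excursion. Undefined when the
#' 30-minute glucose equals fasting glucose.
#'
#' @param curve An [ogtt_curve()] with samples at 0 and 30 minutes.
#' @return List with `value` and `negative_denominator` flag (glucose fell
#'   below fasting at 30 min — the ratio is reported but flagged).
#' @export
insulinogenic_index <- function(curve) {
  cv <- convert_units(curve)
  i30 <- match(30, cv$times)
  if (is.na(i30)) stop("insulinogenic index needs a 30-minute sample", call. = FALSE)
  dg <- cv$glucose[i30] - cv$glucose[1]
  di <- cv$insulin[i30] - cv$insulin[1]
  if (dg == 0) stop("insulinogenic index undefined: G30 == G0", call. = FALSE)
  list(value = di / dg, negative_denominator = dg < 0)
}

#' Disposition index (beta-cell function relative to insulin resistance)
#'
#' The product of the Matsuda insulin-sensitivity index and an insulin
#' secretion measure. The secretion measure is configurable because more than
#' one composition is in routine use: `"insulinogenic"` (default, the
#' 0-30 min ratio) or `"auc_ratio"` (total AUC_I / AUC_G over 0-120 min,
#' trapezoidal, conventional units).
#'
#' @param curve An [ogtt_curve()].
#' @param secretion_measure `"insulinogenic"` or `"auc_ratio"`.
#' @return List with `value`, `matsuda`, `secretion`, `secretion_measure`.
#' @export
disposition_index <- function(curve,
                              secretion_measure = c("insulinogenic", "auc_ratio")) {
  secretion_measure <- match.arg(secretion_measure)
  mats <- matsuda_index(curve)
  cv <- convert_units(curve)
  secr <- if (secretion_measure == "insulinogenic") {
    insulinogenic_index(curve)$value
  } else {
    trapezoid_auc(cv$times, cv$insulin) / trapezoid_auc(cv$times, cv$glucose)
  }
  list(value = mats * secr, matsuda = mats, secretion = secr,
       secretion_measure = secretion_measure)
}

#' Trapezoidal area under a sampled curve
#'
#' @param x Strictly increasing sampling points.
#' @param y Sampled values.
#' @export
trapezoid_auc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(diff(x) > 0))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
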