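#' Linear mixed-model treatment effect for a continuous outcome
#'
#' Fits the trial's longitudinal model by REML: follow-up (6- and 12-month)
#' values of the outcome with fixed effects for time (categorical) and
#' time-by-arm interaction, adjusted for the baseline value of the outcome
#' and the randomisation stratifiers (sex and the 100-kg weight stratum),
#' with a random intercept per participant. The reported effect is the
#' time-by-arm contrast at `timepoint` months (FMD minus control) with a
#' Wald 95% CI and normal-approximation p-value. Missing outcome values are
#' handled complete-case per timepoint; no imputation is performed.
#'
#' @param visits Long-format data.frame with columns `participant_id`, `arm`
#'   (`"FMD"`/`"control"`), `sex`, `weight_stratum`, `timepoint_months`
#'   (0/6/12) and the outcome column.
#' @param outcome Name of the outcome column.
#' @param timepoint Months at which to report the arm contrast (default 12).
#' @param adjust_for_weight Add a fixed effect for concurrent body weight
#'   (`weight_kg` column) over time — the post-hoc weight-adjusted model.
#' @return A `treatment_effect`: list with `outcome`, `timepoint`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `model_spec`, `n_obs`.
#' @export
fit_treatment_effect <- function(visits, outcome, timepoint = 12,
                                 adjust_for_weight = FALSE) {
  stopifnot(outcome %in% names(visits))
  tps <- sort(unique(visits$timepoint_months))
  if (length(tps) < 2 || !0 %in% tps) {
    stop("need baseline plus at least one follow-up timepoint", call. = FALSE)
  }
  if (!timepoint %in% tps) {
    stop("no visits at requested timepoint ", timepoint, call. = FALSE)
  }

  base <- visits[visits$timepoint_months == 0,
                 c("participant_id", outcome)]
  names(base)[2] <- "baseline_value"
  d <- visits[visits$timepoint_months != 0, ]
  d <- merge(d, base, by = "participant_id")
  d$value <- d[[outcome]]
  d <- d[!is.na(d$value) & !is.na(d$baseline_value), ]
  d$time <- factor(d$timepoint_months)
  d$arm <- factor(d$arm, levels = c("control", "FMD"))
  d$sex <- factor(d$sex)
  d$weight_stratum <- factor(d$weight_stratum)

  rhs <- "time + time:arm + baseline_value + sex + weight_stratum"
  if (adjust_for_weight) {
    if (!"weight_kg" %in% names(d)) stop("weight_kg column required", call. = FALSE)
    d <- d[!is.na(d$weight_kg), ]
    rhs <- paste(rhs, "+ weight_kg")
  }
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("mixed model failed to converge (optimizer code ", conv, ")",
         call. = FALSE)
  }

  coefs <- lme4::fixef(fit)
  term <- paste0("time", timepoint, ":armFMD")
  if (!term %in% names(coefs)) {
    stop("contrast term '", term, "' absent from the fit", call. = FALSE)
  }
  est <- unname(coefs[term])
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[term])
  z <- est / se
  structure(list(
    outcome = outcome, timepoint = timepoint, estimate = est,
    ci_low = est - stats::qnorm(0.975) * se,
    ci_high = est + stats::qnorm(0.975) * se,
    p_value = 2 * stats::pnorm(-abs(z)),
    model_spec = paste0("value ~ ", rhs, " + (1 | participant_id), REML"),
    n_obs = nrow(d)
  ), class = "treatment_effect")
}

#' @export
print.treatment_effect <- function(x, ...) {
  cat(sprintf("<treatment_effect> %s at %d months: %.2f (95%% CI %.2f, %.2f), p = %.3g\n",
              x$outcome, x$timepoint, x$estimate, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Subset a cohort to an analysis set
#'
#' Intention-to-treat (`"ITT"`) keeps every participant with baseline data,
#' analysed as randomised. Per-protocol (`"PP"`) keeps intervention-arm
#' participants who were compliant with the full programme and finished
#' follow-up, plus control-arm participants who finished follow-up. No
#' imputation in either set.
#'
#' @param cohort A cohort object (list with a `visits` data.frame including
#'   `compliance_flag`).
#' @param set `"ITT"` or `"PP"`.
#' @return The cohort with `visits` subset; attribute `analysis_set` records
#'   the choice.
#' @export
select_analysis_set <- function(cohort, set = c("ITT", "PP")) {
  set <- match.arg(set)
  v <- cohort$visits
  base_ids <- unique(v$participant_id[v$timepoint_months == 0 &
                                        !is.na(v$hba1c_mmol_mol)])
  keep <- base_ids
  if (set == "PP") {
    completers <- unique(v$participant_id[v$timepoint_months == 12 &
                                            !is.na(v$hba1c_mmol_mol)])
    info <- unique(v[v$timepoint_months == 0,
                     c("participant_id", "arm", "compliance_flag")])
    fmd_ok <- info$participant_id[info$arm == "FMD" &
                                    info$compliance_flag %in% TRUE]
    ctl_ok <- info$participant_id[info$arm == "control"]
    keep <- intersect(base_ids,
                      intersect(completers, c(fmd_ok, ctl_ok)))
    if (!any(info$participant_id %in% keep & info$arm == "FMD")) {
      warning("per-protocol FMD arm is empty", call. = FALSE)
    }
  }
  out <- cohort
  out$visits <- v[v$participant_id %in% keep, ]
  attr(out, "analysis_set") <- set
  out
}
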