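# independent enumeration oracle for the two-sided Fisher p-value: walk all
# tables with the observed margins via dhyper, sum those no more probable
# than the observed table (same point-probability convention, 1e-7 slack)
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

test_that("fisher_exact_2x2 matches hand-computed and degenerate cases", {
  expect_equal(round(fisher_exact_2x2(rbind(c(7, 36), c(2, 37))), 2), 0.16)
  expect_equal(fisher_exact_2x2(rbind(c(0, 10), c(0, 10))), 1)
  # two extreme tables out of choose(10, 5) equally-split arrangements
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5))), 2 / choose(10, 5),
               tolerance = 1e-12)
})

test_that("fisher_exact_2x2 agrees with the enumeration oracle and fisher.test", {
  set.seed(7)
  for (i in 1:200) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(m), fisher_oracle(m), tolerance = 1e-12)
    if (sum(m[1, ]) > 0 && sum(m[, 1]) > 0 &&
        sum(m[1, ]) < sum(m) && sum(m[, 1]) < sum(m)) {
      expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                   tolerance = 1e-7)
    }
  }
})

test_that("association_test selects Fisher only for sparse 2x2 tables", {
  sparse <- rbind(c(7, 36), c(2, 37))      # min expected 4.28
  r <- association_test(sparse)
  expect_equal(r$test_used, "fisher_exact")
  expect_lt(r$min_expected, 5)
  expect_true(is.na(r$statistic))

  dense <- rbind(c(1, 42), c(10, 29))      # min expected 5.23
  r2 <- association_test(dense)
  expect_equal(r2$test_used, "chi_squared_yates")
  expect_equal(r2$df, 1)
  expect_equal(r2$p_value,
               stats::chisq.test(dense, correct = TRUE)$p.value)

  wide <- rbind(c(23, 10, 10), c(3, 13, 23))
  r3 <- association_test(wide)
  expect_equal(r3$test_used, "chi_squared")
  expect_equal(r3$df, 2)
  expect_lt(r3$p_value, 0.001)

  ident <- rbind(c(10, 15, 5), c(10, 15, 5))
  expect_equal(association_test(ident)$p_value, 1)
  expect_error(association_test(rbind(c(0, 0), c(3, 4))), "degenerate")
})

test_that("association_test is invariant to row/column permutation", {
  set.seed(3)
  for (i in 1:25) {
    m <- matrix(rpois(4, 8) + 1, 2)
    p <- association_test(m)$p_value
    expect_equal(association_test(m[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(association_test(m[, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("benjamini_hochberg reproduces the step-up procedure", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))
  expect_equal(r$adjusted, rep(0.04, 4))

  expect_equal(benjamini_hochberg(0.037)$adjusted, 0.037)
  expect_false(any(benjamini_hochberg(rep(1, 5))$rejected))
  expect_length(benjamini_hochberg(numeric(0))$adjusted, 0)

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1))
    r <- benjamini_hochberg(p)
    expect_equal(r$adjusted, stats::p.adjust(p, "BH"))   # independent check
    # rejections are monotone in q
    r_strict <- benjamini_hochberg(p, q = 0.01)
    r_loose <- benjamini_hochberg(p, q = 0.2)
    expect_true(all(!r_strict$rejected | r_loose$rejected))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two_sample_t_test is the pooled-variance Student test", {
  a <- c(1, 2); b <- c(3, 5)
  r <- two_sample_t_test(a, b)
  sp2 <- (var(a) + var(b)) / 2              # equal n, pooled
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 2), tolerance = 1e-12)

  same <- c(1, 2, 3, 4)
  expect_equal(two_sample_t_test(same, same)$p_value, 1)
  zv <- two_sample_t_test(rep(2, 3), rep(2, 4))
  expect_true(zv$undefined)
  expect_equal(zv$p_value, 1)
  expect_error(two_sample_t_test(1, c(2, 3)), "n >= 2")
})

test_that("t-test p-values are uniform under the null", {
  set.seed(21)
  p <- replicate(400, two_sample_t_test(rnorm(25), rnorm(25))$p_value)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixed model recovers a null and flips sign under arm relabelling", {
  d <- make_effect_frame(300, seed = 5,
                         cfg = sim_config(n = 300,
                                          hba1c_effect = c("6" = 0, "12" = 0)))
  eff <- fit_treatment_effect(d, "hba1c_mmol_mol")
  # MC standard error of the estimate is roughly resid_sd/sqrt(n/4) ~ 0.5
  expect_lt(abs(eff$estimate), 2)
  expect_true(eff$ci_low <= eff$estimate && eff$estimate <= eff$ci_high)

  d2 <- make_effect_frame(300, seed = 6)
  e_fwd <- fit_treatment_effect(d2, "hba1c_mmol_mol")
  d2flip <- d2
  d2flip$arm <- ifelse(d2$arm == "FMD", "control", "FMD")
  e_rev <- fit_treatment_effect(d2flip, "hba1c_mmol_mol")
  expect_equal(e_rev$estimate, -e_fwd$estimate, tolerance = 1e-6)

  expect_error(fit_treatment_effect(d2[d2$timepoint_months == 0, ],
                                    "hba1c_mmol_mol"), "follow-up")
})

test_that("weight-adjusted post-hoc model fits and reports the contrast", {
  d <- make_effect_frame(200, seed = 9)
  e <- fit_treatment_effect(d, "hba1c_mmol_mol", adjust_for_weight = TRUE)
  expect_match(e$model_spec, "weight_kg")
  expect_true(is.finite(e$estimate) && is.finite(e$p_value))
})

test_that("analysis-set selection implements ITT and PP rules", {
  coh <- make_printed_cohort()
  itt <- select_analysis_set(coh, "ITT")
  # ITT keeps everyone with baseline data, including those lost to follow-up
  expect_equal(length(unique(itt$visits$participant_id)), 43 + 39 + 10)
  pp <- select_analysis_set(coh, "PP")
  ids <- unique(pp$visits$participant_id)
  arms <- pp$visits$arm[match(ids, pp$visits$participant_id)]
  expect_equal(sum(arms == "FMD"), 30)       # compliant completers only
  expect_equal(sum(arms == "control"), 39)   # control completers
  # all-compliant cohort: ITT and PP coincide on completers
  joint <- list(FMD = matrix(c(0, 0, 0, 0, 4, 0, 0, 0, 0), 3),
                control = matrix(c(0, 0, 0, 0, 4, 0, 0, 0, 0), 3))
  c2 <- cohort_from_categories(joint)
  expect_equal(sort(unique(select_analysis_set(c2, "PP")$visits$participant_id)),
               sort(unique(select_analysis_set(c2, "ITT")$visits$participant_id)))
  # zero compliant FMD -> empty PP arm, flagged
  c3 <- cohort_from_categories(joint, compliant_joint = list(
    FMD = matrix(0, 3, 3), control = joint$control))
  expect_warning(select_analysis_set(c3, "PP"), "empty")
})
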