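test_that("HbA1c change categories use an inclusive 5 mmol/mol boundary", {
  expect_equal(classify_hba1c_change(52, 47), "improved")     # delta -5 exactly
  expect_equal(classify_hba1c_change(52, 56.9), "stable")
  expect_equal(classify_hba1c_change(52, 57), "deteriorated") # delta +5 exactly
  expect_equal(classify_hba1c_change(52, 48.1), "stable")
  expect_error(classify_hba1c_change(0, 50), "> 0")
})

test_that("HbA1c classification is threshold-symmetric", {
  set.seed(1)
  b <- runif(200, 30, 90); f <- runif(200, 30, 90)
  for (i in seq_along(b)) {
    fwd <- classify_hba1c_change(b[i], f[i])
    rev <- classify_hba1c_change(f[i], b[i])
    expect_equal(fwd == "improved", rev == "deteriorated")
    expect_equal(fwd == "stable", rev == "stable")
  }
})

test_that("medication change detects dose moves, stops, additions", {
  m1000 <- regimen("metformin", 1000)
  expect_equal(classify_medication_change(m1000, regimen("metformin", 500)),
               "decreased")
  expect_equal(classify_medication_change(m1000, regimen()), "decreased")
  expect_equal(classify_medication_change(m1000, m1000), "stable")
  expect_equal(classify_medication_change(regimen(), regimen()), "stable")
  expect_equal(
    classify_medication_change(m1000,
                               regimen(c("metformin", "gliclazide"), c(1000, 30))),
    "increased")
  expect_equal(classify_medication_change(regimen(), m1000), "increased")
  # mixed change: escalation dominates
  expect_equal(
    classify_medication_change(regimen(c("metformin", "gliclazide"), c(1000, 60)),
                               regimen(c("metformin", "gliclazide"), c(500, 120))),
    "increased")
  # zero dose is the same as absence
  expect_equal(classify_medication_change(regimen("metformin", 0), regimen()),
               "stable")
})

test_that("glycaemic-management decision table is total over all 9 cases", {
  expected <- rbind(
    c(med = "decreased", hba = "improved",     out = "improved",     tie = FALSE),
    c("decreased", "stable",       "improved",     FALSE),
    c("decreased", "deteriorated", "deteriorated", TRUE),
    c("stable",    "improved",     "improved",     FALSE),
    c("stable",    "stable",       "stable",       FALSE),
    c("stable",    "deteriorated", "deteriorated", FALSE),
    c("increased", "improved",     "deteriorated", FALSE),
    c("increased", "stable",       "deteriorated", FALSE),
    c("increased", "deteriorated", "deteriorated", FALSE)
  )
  for (i in seq_len(nrow(expected))) {
    g <- classify_glycaemic_management(expected[i, 2], expected[i, 1])
    expect_equal(g$category, unname(expected[i, 3]))
    expect_equal(g$tie_break_applied, as.logical(expected[i, 4]))
    # flag fires exactly on (decreased, deteriorated)
    expect_equal(g$tie_break_applied,
                 expected[i, 1] == "decreased" && expected[i, 2] == "deteriorated")
  }
  expect_error(classify_glycaemic_management("better", "stable"))
})

test_that("classify_cohort conserves counts and logs exclusions", {
  coh <- make_printed_cohort()
  cls <- classify_cohort(coh, 12)
  expect_equal(nrow(cls$results), 43 + 39)
  for (tab in cls$tables) {
    expect_equal(unname(rowSums(tab)), c(43, 39))
  }
  expect_equal(nrow(cls$excluded), 10)   # 6 FMD + 4 control lost to follow-up
  expect_equal(sum(cls$results$tie_break_applied), 2)
  expect_true(all(cls$results$glycaemic_management[cls$results$tie_break_applied]
                  == "deteriorated"))
})

test_that("null cohort (no change anywhere) classifies all stable", {
  joint <- list(FMD = diag(0, 3), control = diag(0, 3))
  joint$FMD[2, 2] <- 5; joint$control[2, 2] <- 5
  coh <- cohort_from_categories(joint)
  cls <- classify_cohort(coh, 12)
  expect_true(all(cls$results$hba1c_category == "stable"))
  expect_true(all(cls$results$medication_category == "stable"))
  expect_true(all(cls$results$glycaemic_management == "stable"))
})

test_that("category encodings round-trip through the classifier", {
  coh <- make_printed_cohort()
  cls <- classify_cohort(coh, 12)
  expect_equal(unname(cls$tables$glycaemic_management),
               rbind(c(23, 10, 10), c(3, 13, 23)))
  expect_equal(unname(cls$tables$medication),
               rbind(c(17, 22, 4), c(2, 20, 17)))
  expect_equal(unname(cls$tables$hba1c),
               rbind(c(18, 19, 6), c(6, 22, 11)))
})
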