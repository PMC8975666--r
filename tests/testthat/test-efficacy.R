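test_that("response classification follows the stated boundaries", {
  expect_equal(as.character(classify_response(
    lesion_assessment(50, 0, undetectable = TRUE), duration_ok = TRUE)), "CR")
  # without the 4-week duration, disappearance counts as partial remission
  expect_equal(as.character(classify_response(
    lesion_assessment(50, 0, undetectable = TRUE), duration_ok = FALSE)), "PR")
  # +20% is progression (inclusive boundary)
  expect_equal(as.character(classify_response(
    lesion_assessment(100, 120))), "PD")
  expect_equal(as.character(classify_response(
    lesion_assessment(100, 119.9))), "SD")
  # -30% exactly is stable; strictly more shrinkage is partial remission
  expect_equal(as.character(classify_response(
    lesion_assessment(100, 70))), "SD")
  expect_equal(as.character(classify_response(
    lesion_assessment(100, 69.9))), "PR")
  # the standard dialect includes the 30% boundary in PR
  expect_equal(as.character(classify_response(
    lesion_assessment(100, 70), dialect = "standard")), "PR")
  # a new lesion dominates shrinkage
  expect_equal(as.character(classify_response(
    lesion_assessment(100, 50, new_lesion = TRUE))), "PD")
  expect_error(lesion_assessment(0, 10), "positive")
  expect_error(lesion_assessment(50, 5, undetectable = TRUE), "zero")
})

test_that("categories are exhaustive and mutually exclusive", {
  set.seed(77)
  for (i in 1:200) {
    a <- lesion_assessment(runif(1, 10, 150), runif(1, 0, 200),
                           new_lesion = runif(1) < 0.2)
    cat <- classify_response(a, duration_ok = runif(1) < 0.5)
    expect_length(cat, 1L)
    expect_false(is.na(cat))
    expect_true(as.character(cat) %in% c("CR", "PR", "SD", "PD"))
  }
})

test_that("efficacy rates reproduce the two-arm table and its invariants", {
  ctrl <- efficacy_rates(0, 4, 11, 5)
  expect_equal(ctrl$orr, 20.0)
  expect_equal(ctrl$dcr, 75.0)
  res <- efficacy_rates(0, 4, 14, 2)
  expect_equal(res$orr, 20.0)
  expect_equal(res$dcr, 90.0)
  allcr <- efficacy_rates(7, 0, 0, 0)
  expect_equal(allcr$orr, 100.0)
  expect_equal(allcr$dcr, 100.0)
  for (e in list(ctrl, res, allcr)) {
    expect_gte(e$dcr, e$orr)
    expect_lte(e$dcr, 100)
    expect_identical(sum(e$counts), e$n)
  }
  expect_error(efficacy_rates(0, 0, 0, 0), "zero")
})

test_that("Kaplan-Meier estimates have the product-limit properties", {
  k <- km_curve(data.frame(time = 1:4, event = 1))
  expect_equal(k$median, 2)                 # S(2) = 0.5, earliest crossing
  expect_equal(k$surv, c(0.75, 0.5, 0.25, 0))

  cens <- km_curve(data.frame(time = c(3, 5, 8), event = 0))
  expect_false(cens$median_defined)

  # with no censoring the estimate equals the empirical survival function
  set.seed(88)
  tt <- rexp(300, 0.2)
  k2 <- km_curve(data.frame(time = tt, event = 1))
  emp <- vapply(k2$time, function(s) mean(tt > s), 0)
  expect_equal(k2$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(k2$surv) <= 0))
  expect_lte(max(k2$surv), 1)

  expect_error(km_curve(data.frame(time = -1, event = 1)), "negative")
})

test_that("the exponential PFS median is recovered at n = 2000", {
  sp <- followup_spec(hazards = c(arm = log(2) / 7.1), censor_time = Inf,
                      arm_sizes = c(arm = 2000), seed = 9)
  fu <- simulate_followup(sp)
  k <- km_curve(fu[, c("time", "event")])
  expect_lt(abs(k$median - 7.1), 0.3)
})

test_that("the group chi-square equals the direct cell sum and is symmetric", {
  flat <- chi2_compare(10, 20, 10, 20)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  got <- chi2_compare(15, 20, 18, 20)
  tab <- rbind(c(15, 5), c(18, 2))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_identical(got$df, 1L)

  swapped <- chi2_compare(18, 20, 15, 20)
  expect_equal(swapped$statistic, got$statistic)
  expect_error(chi2_compare(0, 5, 0, 5), "degenerate")
})
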