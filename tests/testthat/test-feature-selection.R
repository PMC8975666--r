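test_that("chi-square screen keeps signal and drops noise", {
  # variable identical to the outcome: p ~ 0, kept
  d <- data.frame(y = factor(rep(c("a", "d"), 50)))
  d$same <- d$y
  res <- chi_square_screen(d, "y")
  expect_lt(res$p, 1e-15)
  expect_true(res$kept)

  # perfectly balanced 2x2 table: statistic 0, p = 1, dropped
  d2 <- data.frame(x = factor(rep(c(0, 1), each = 20)),
                   y = factor(rep(c("a", "d"), 20)))
  res2 <- chi_square_screen(d2, "y")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  expect_false(res2$kept)

  # constant variable: degenerate table skipped with a warning
  d3 <- data.frame(x = factor(rep("only", 40)),
                   y = factor(rep(c("a", "d"), 20)))
  expect_warning(res3 <- chi_square_screen(d3, "y"), "degenerate")
  expect_true(is.na(res3$statistic))
  expect_false(res3$kept)
})

test_that("screen statistic equals the direct cell-sum computation", {
  chisq_oracle <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  # simulated independent variable, fixed seed
  set.seed(200)
  d <- data.frame(x = factor(sample(1:3, 200, TRUE)),
                  y = factor(sample(c("a", "d"), 200, TRUE)))
  res <- chi_square_screen(d, "y")
  expect_equal(res$statistic, chisq_oracle(table(d$x, d$y)), tolerance = 1e-12)

  # property: random tables up to 5x5 via sampled data
  for (seed in 1:8) {
    set.seed(seed)
    r <- sample(2:5, 1)
    d <- data.frame(x = factor(sample(seq_len(r), 300, TRUE)),
                    y = factor(sample(c("a", "d"), 300, TRUE,
                                      prob = c(0.4, 0.6))))
    res <- chi_square_screen(d, "y")
    expect_equal(res$statistic, chisq_oracle(table(d$x, d$y)),
                 tolerance = 1e-12)
    expect_identical(res$df, (r - 1L) * 1L)
  }
})

test_that("screen on the synthetic cohort separates truth from nuisance", {
  net <- make_ground_truth()
  co <- add_nuisance_variables(sample_cohort(net, 3000, seed = 77), seed = 78)
  res <- chi_square_screen(co, "survival_status", specs = net$continuous)
  kept <- res$variable[res$kept]
  expect_true(all(net$parents$survival_status %in% kept))
})

test_that("logistic filter reports exp(B) consistently with B", {
  net <- make_ground_truth()
  co <- sample_cohort(net, 1500, seed = 31)
  lf <- logistic_filter(co, setdiff(names(co), "survival_status"),
                        "survival_status")
  expect_true(lf$converged)
  expect_equal(lf$table$exp_b, exp(lf$table$B), tolerance = 1e-12)
  expect_true(all(lf$table$ci_lo <= lf$table$exp_b + 1e-12))
  expect_true(all(lf$table$exp_b <= lf$table$ci_hi + 1e-12))
  # strong generating effects: every true predictor retained
  expect_true(all(net$parents$survival_status %in% lf$retained))
})

test_that("logistic filter recovers generating coefficients within 2 SE", {
  set.seed(55)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  p <- plogis(0.2 + 0.8 * x1 - 0.5 * x2)
  d <- data.frame(x1 = x1, x2 = x2,
                  y = factor(ifelse(runif(n) < p, "event", "none"),
                             levels = c("none", "event")))
  lf <- logistic_filter(d, c("x1", "x2"), "y")
  b <- lf$table
  expect_lt(abs(b$B[b$term == "x1"] - 0.8), 2 * b$se[b$term == "x1"])
  expect_lt(abs(b$B[b$term == "x2"] + 0.5), 2 * b$se[b$term == "x2"])
})

test_that("logistic filter is invariant to row order and flags separation", {
  net <- make_ground_truth()
  co <- sample_cohort(net, 800, seed = 13)
  lf1 <- logistic_filter(co, names(net$continuous), "survival_status")
  set.seed(1)
  lf2 <- logistic_filter(co[sample(nrow(co)), ], names(net$continuous),
                         "survival_status")
  expect_equal(lf1$table$B, lf2$table$B, tolerance = 1e-8)
  expect_identical(lf1$retained, lf2$retained)

  sep <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)),
                    y = factor(rep(c("a", "d"), each = 30)))
  expect_error(logistic_filter(sep, "x", "y"), "separation.*x")
})
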