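test_that("false-discovery behaviour under the null stays near nominal", {
  # three mutually independent binaries: any non-empty CPC is a false
  # discovery; the per-target rate must stay within binomial noise of the
  # worst-case nominal level 1 - (1 - alpha)^2
  hits <- 0L; total <- 0L
  for (seed in 1:30) {
    set.seed(seed)
    d <- data.frame(a = factor(rbinom(2000, 1, 0.5)),
                    b = factor(rbinom(2000, 1, 0.4)),
                    c = factor(rbinom(2000, 1, 0.6)))
    for (v in names(d)) {
      total <- total + 1L
      if (length(mmpc(d, v, alpha = 0.05)$cpc) > 0) hits <- hits + 1L
    }
  }
  p0 <- 1 - 0.95^2
  expect_lt(hits / total, p0 + 3 * sqrt(p0 * (1 - p0) / total))
})

test_that("the collider's parents are recovered and singletons are empty", {
  set.seed(500)
  n <- 5000
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  t_ <- rbinom(n, 1, plogis(-1.5 + 1.8 * a + 1.8 * b))
  d <- data.frame(a = factor(a), b = factor(b), t = factor(t_),
                  c = factor(rbinom(n, 1, 0.5)))
  cpc <- mmpc(d, "t", alpha = 0.05, maxk = 3)
  expect_setequal(cpc$cpc, c("a", "b"))

  single <- data.frame(t = factor(rbinom(100, 1, 0.5)))
  expect_length(mmpc(single, "t")$cpc, 0L)
})

test_that("hill climbing improves monotonically from the empty graph", {
  set.seed(7)
  n <- 5000
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  t_ <- rbinom(n, 1, plogis(-1.5 + 2 * a + 2 * b))
  d <- data.frame(a = factor(a), b = factor(b), t = factor(t_))

  # empty skeleton: no additions possible, score is the no-parent total
  empty_skel <- matrix(0L, 3, 3, dimnames = list(names(d), names(d)))
  g0 <- hill_climb(d, empty_skel)
  expect_identical(sum(lengths(g0$parents)), 0L)
  expect_equal(attr(g0, "score"),
               sum(vapply(names(d), function(v)
                 prognet:::node_score(d, v, character(0)), 0)))

  # correct skeleton: the learned graph is equivalent to the collider
  skel <- matrix(0L, 3, 3, dimnames = list(names(d), names(d)))
  skel["a", "t"] <- skel["t", "a"] <- 1L
  skel["b", "t"] <- skel["t", "b"] <- 1L
  g <- hill_climb(d, skel)
  truth <- list(t = c("a", "b"))
  expect_lte(structural_hamming_distance(cpdag(g), cpdag(truth)), 1)

  # accepted moves strictly increase the score; final beats the empty graph
  tr <- attr(g, "trace")
  expect_true(all(diff(tr) > 0))
  expect_gte(attr(g, "score"), attr(g0, "score"))
  expect_false(is.null(prognet:::topo_sort(g$nodes, g$parents)))
})

test_that("mmpc output is invariant to candidate column order", {
  net <- make_ground_truth()
  co <- attr(sample_cohort(net, 2000, seed = 15), "levels")
  c1 <- mmpc(co, "survival_status")
  c2 <- mmpc(co[, rev(names(co))], "survival_status")
  expect_identical(c1$cpc, c2$cpc)
})

test_that("full MMHC recovers the generating structure at n = 5000", {
  truth <- make_ground_truth()
  co <- attr(sample_cohort(truth, 5000, seed = 42), "levels")
  fit <- mmhc(co, outcome = "survival_status", alpha = 0.05, maxk = 3,
              score = "bic")
  expect_setequal(fit$cpc$survival_status$cpc,
                  truth$parents$survival_status)
  shd <- structural_hamming_distance(cpdag(fit), cpdag(truth))
  expect_lte(shd, 2)
})

test_that("prediction beats the majority-class baseline on held-out data", {
  truth <- make_ground_truth()
  co <- attr(sample_cohort(truth, 5000, seed = 42), "levels")
  fit <- mmhc(co, outcome = "survival_status")
  test <- attr(sample_cohort(truth, 1000, seed = 4242), "levels")
  pred <- predict(fit, test, type = "class")
  acc <- mean(as.character(pred) == as.character(test$survival_status))
  baseline <- max(table(test$survival_status)) / nrow(test)
  expect_gt(acc, baseline)
})

test_that("BDeu scoring also yields a close structure", {
  truth <- make_ground_truth()
  co <- attr(sample_cohort(truth, 5000, seed = 8), "levels")
  fit <- mmhc(co, outcome = "survival_status", score = "bdeu")
  expect_lte(structural_hamming_distance(cpdag(fit), cpdag(truth)), 3)
})
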