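test_that("CPT estimation matches counts and smoothing limits", {
  # single binary node, 30 ones / 70 zeros, no smoothing
  d <- data.frame(v = factor(c(rep(0, 70), rep(1, 30))))
  f0 <- fit_parameters(list(v = character(0)), d, pseudocount = 0)
  expect_equal(unname(f0$cpts$v[1, ]), c(0.7, 0.3))

  # pseudocount 1: an unobserved parent configuration yields a uniform row
  d2 <- data.frame(p = factor(rep("a", 50), levels = c("a", "b")),
                   v = factor(rbinom(50, 1, 0.4)))
  f1 <- fit_parameters(list(v = "p"), d2, pseudocount = 1)
  expect_equal(unname(f1$cpts$v[2, ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(f1$cpts$v) - 1) < 1e-9))

  expect_error(fit_parameters(list(v = "missing_node"), d2), "absent")
})

test_that("fitted CPTs converge to the generating tables at large n", {
  # a known 4-node net whose parent configurations are all well populated
  truth <- random_small_bn(4, seed = 9)
  co <- sample_cohort(truth, 10000, seed = 60)
  fit <- fit_parameters(truth, co, pseudocount = 1)
  worst <- 0
  for (v in truth$nodes)
    worst <- max(worst, max(abs(fit$cpts[[v]] - truth$cpts[[v]])))
  expect_lt(worst, 0.05)
})

test_that("posterior inference has the Markov-condition special cases", {
  # single node, no evidence: the marginal CPT
  one <- bn(list(v = c("x", "y")), list(),
            list(v = matrix(c(0.3, 0.7), 1)))
  post <- predict_outcome(one, node = "v")
  expect_equal(unname(as.numeric(post)), c(0.3, 0.7))

  # full evidence on the outcome's parents: exactly the CPT row
  truth <- make_ground_truth()
  ev <- list(histological_grade = "high", tumor_stage = "IV",
             diagnosis_age = "2", tumor_size = "2",
             examined_lymph_nodes = "1", positive_lymph_nodes = "2")
  post2 <- predict_outcome(truth, ev)
  sizes <- vapply(truth$parents$survival_status,
                  function(p) length(truth$levels[[p]]), 1L)
  idx <- vapply(truth$parents$survival_status, function(p)
    match(ev[[p]], truth$levels[[p]]), 1L)
  row <- prognet:::config_index(idx, sizes)
  expect_equal(unname(as.numeric(post2)),
               unname(truth$cpts$survival_status[row, ]), tolerance = 1e-12)

  expect_error(predict_outcome(truth, list(tumor_stage = "IIIC")),
               "not a level")
  expect_error(predict_outcome(truth, list(survival_status = "dead")),
               "queried node")
})

test_that("enumeration inference matches the full-joint oracle", {
  for (seed in 1:8) {
    net <- random_small_bn(5, seed = seed)
    set.seed(seed + 100)
    ev_nodes <- sample(net$nodes, sample(0:3, 1))
    node <- sample(setdiff(net$nodes, ev_nodes), 1)
    evidence <- lapply(stats::setNames(ev_nodes, ev_nodes), function(v)
      sample(net$levels[[v]], 1))
    got <- as.numeric(predict_outcome(net, evidence, node = node))
    want <- posterior_oracle(net, evidence, node)
    expect_equal(got, want, tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("row-wise prediction returns normalized posteriors and classes", {
  truth <- make_ground_truth()
  co <- attr(sample_cohort(truth, 25, seed = 3), "levels")
  post <- predict(truth, co, type = "posterior")
  expect_identical(dim(post), c(25L, 2L))
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  cls <- predict(truth, co, type = "class")
  expect_identical(levels(cls), truth$levels$survival_status)
})
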