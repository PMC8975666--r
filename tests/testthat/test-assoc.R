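test_that("association statistic has its closed-form and degenerate values", {
  # X identical to T, two balanced levels: 2 n ln 2
  d <- data.frame(a = factor(rep(0:1, 50)), b = factor(rep(0:1, 50)))
  a <- assoc(d, "a", "b")
  expect_equal(a$statistic, 2 * 100 * log(2), tolerance = 1e-12)
  expect_identical(a$df, 1L)
  expect_lt(a$p, 1e-20)

  # exact factorization (all four cells equal): statistic 0
  d0 <- expand.grid(a = factor(0:1), b = factor(0:1))
  d0 <- d0[rep(1:4, 25), ]
  expect_equal(assoc(d0, "a", "b")$statistic, 0, tolerance = 1e-12)

  expect_error(assoc(d[0, ], "a", "b"), "empty")
  expect_error(assoc(d, "a", "a"), "disjoint")
})

test_that("association statistic equals the brute-force cell-sum oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(50:300, 1)
    d <- data.frame(
      x = factor(sample(seq_len(sample(2:4, 1)), n, TRUE)),
      t = factor(sample(seq_len(sample(2:4, 1)), n, TRUE)),
      z1 = factor(sample(1:2, n, TRUE)),
      z2 = factor(sample(1:3, n, TRUE)))
    z <- list(character(0), "z1", c("z1", "z2"))[[sample(3, 1)]]
    got <- assoc(d, "x", "t", z)$statistic
    want <- g2_oracle(d, "x", "t", z)
    expect_equal(got, want, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("association is symmetric and non-negative", {
  for (seed in 1:6) {
    set.seed(seed)
    d <- data.frame(x = factor(sample(1:3, 150, TRUE)),
                    t = factor(sample(1:2, 150, TRUE)),
                    z = factor(sample(1:2, 150, TRUE)))
    a1 <- assoc(d, "x", "t", "z")
    a2 <- assoc(d, "t", "x", "z")
    expect_gte(a1$statistic, 0)
    expect_equal(a1$statistic, a2$statistic, tolerance = 1e-12)
  }
})

test_that("minimum association finds the separating subset", {
  # empty Z reduces to the unconditional test
  d <- data.frame(a = factor(rep(0:1, 50)), b = factor(rep(0:1, 50)))
  m <- min_assoc(d, "a", "b", character(0))
  expect_identical(m$subset, character(0))
  expect_equal(m$assoc$statistic, assoc(d, "a", "b")$statistic)

  # chain x -> w -> t: conditioning on w separates x from t
  set.seed(99)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  w <- ifelse(runif(n) < 0.9, x, 1 - x)
  t_ <- ifelse(runif(n) < 0.9, w, 1 - w)
  d2 <- data.frame(x = factor(x), w = factor(w), t = factor(t_))
  m2 <- min_assoc(d2, "x", "t", "w")
  expect_identical(m2$subset, "w")
  expect_gt(m2$p, 0.05)
})

test_that("minimum association equals the exhaustive subset oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 400
    d <- data.frame(x = factor(sample(1:2, n, TRUE)),
                    t = factor(sample(1:2, n, TRUE)),
                    z1 = factor(sample(1:2, n, TRUE)),
                    z2 = factor(sample(1:2, n, TRUE)),
                    z3 = factor(sample(1:2, n, TRUE)))
    got <- min_assoc(d, "x", "t", c("z1", "z2", "z3"), maxk = 3)
    want <- min_assoc_oracle(d, "x", "t", c("z1", "z2", "z3"), maxk = 3)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_identical(got$subset, want$subset)
  }
})
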