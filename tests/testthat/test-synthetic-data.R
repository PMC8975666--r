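test_that("ground-truth construction covers the boundary cases", {
  # two independent variables, no edges
  lv <- list(a = c("0", "1"), b = c("0", "1"))
  net <- make_ground_truth(list(levels = lv, parents = list(),
                                cpts = list(a = matrix(c(0.3, 0.7), 1),
                                            b = matrix(c(0.5, 0.5), 1))))
  expect_identical(sum(lengths(net$parents)), 0L)

  # default: seven nodes, survival status with in-degree six and no children
  def <- make_ground_truth()
  expect_length(def$nodes, 7L)
  expect_length(def$parents$survival_status, 6L)
  expect_identical(def$outcome, "survival_status")

  # random CPTs are reproducible under a fixed seed
  cfg <- list(levels = lv, parents = list(b = "a"), cpts = "random",
              seed = 11L)
  expect_identical(make_ground_truth(cfg)$cpts, make_ground_truth(cfg)$cpts)
  expect_error(make_ground_truth(list(levels = lv, parents = list(b = "a"),
                                      cpts = "random")), "seed")
})

test_that("forward sampling is deterministic and respects forced CPTs", {
  lv <- list(a = c("x", "y"), b = c("0", "1"))
  forced <- make_ground_truth(list(
    levels = lv, parents = list(b = "a"),
    cpts = list(a = matrix(c(0, 1), 1),
                b = rbind(c(1, 0), c(0, 1)))))
  row <- sample_cohort(forced, 1, seed = 3)
  expect_identical(as.character(row$a), "y")
  expect_identical(as.character(row$b), "1")

  net <- make_ground_truth()
  expect_identical(sample_cohort(net, 50, seed = 9),
                   sample_cohort(net, 50, seed = 9))
})

test_that("sampled marginals converge to the exact CPT enumeration", {
  net <- make_ground_truth()
  n <- 5000
  co <- attr(sample_cohort(net, n, seed = 101), "levels")
  truth <- exact_marginals(net)
  for (v in net$nodes) {
    freq <- as.numeric(table(co[[v]])) / n
    p <- as.numeric(truth[[v]])
    bound <- 4 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(freq - p) < bound),
                info = paste("marginal drift for", v))
  }
})

test_that("the generator's discretization spec inverts continuous synthesis", {
  net <- make_ground_truth()
  co <- sample_cohort(net, 2000, seed = 5)
  lev <- attr(co, "levels")
  for (v in names(net$continuous)) {
    rec <- equidistant_discretize(co[[v]], net$continuous[[v]]) + 1L
    expect_identical(rec, as.integer(lev[[v]]),
                     info = paste("level recovery for", v))
  }
})

test_that("phantoms have the analytic geometry and exact masks", {
  sph <- make_phantom(phantom_spec(shape = c(21, 64, 64),
                                   semiaxes = c(10, 10, 10)))
  expect_equal(sph$truth$volume_cm3, 4 / 3 * pi, tolerance = 1e-9)  # 4.18879
  expect_equal(sph$truth$diameter_mm, 20)
  # voxel-count volume within 5% of the analytic ellipsoid at 1 mm spacing
  expect_lt(abs(sum(sph$mask) / 1000 - sph$truth$volume_cm3) /
              sph$truth$volume_cm3, 0.05)

  ell <- make_phantom(phantom_spec(shape = c(40, 64, 64),
                                   semiaxes = c(8, 15, 10)))
  expect_equal(ell$truth$diameter_mm, 30)   # 2 x max in-plane semi-axis

  noiseless <- make_phantom(phantom_spec(noise_sd = 0))
  expect_identical(sort(unique(as.vector(noiseless$image))), c(60, 160))

  expect_error(phantom_spec(shape = c(1, 32, 32), semiaxes = c(10, 40, 10)),
               "outside")
})

test_that("follow-up simulation matches the exponential model", {
  sp <- followup_spec(hazards = c(arm = log(2) / 7.1), censor_time = Inf,
                      arm_sizes = c(arm = 4000), seed = 21)
  fu <- simulate_followup(sp)
  expect_equal(median(fu$time), 7.1, tolerance = 0.1)
  expect_true(all(fu$event == 1))

  all_censored <- simulate_followup(
    followup_spec(hazards = c(a = 0.1), censor_time = 0,
                  arm_sizes = c(a = 10), seed = 1))
  expect_true(all(all_censored$time == 0))
  expect_true(all(all_censored$event == 0))

  expect_identical(simulate_followup(sp), simulate_followup(sp))
  expect_error(followup_spec(hazards = c(a = -1), arm_sizes = c(a = 5)),
               "positive")
})

test_that("nuisance variables complete the 16-variable catalog", {
  net <- make_ground_truth()
  co <- add_nuisance_variables(sample_cohort(net, 100, seed = 2), seed = 3)
  cat <- variable_catalog()
  expect_true(all(cat$name %in% names(co)))
  expect_identical(ncol(co), 17L)   # 16 candidates + survival status
})
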