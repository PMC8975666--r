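test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    set.seed(seed + 40)
    n_in <- sample(2:4, 1); n_h <- sample(2:5, 1)
    net <- prognet:::nn_init(n_in, n_h, 1, seed = seed)
    x <- matrix(rnorm(2 * n_in), 2)
    tgt <- matrix(rbinom(2, 1, 0.5), 2)
    g <- prognet:::nn_gradient(net, x, tgt)
    eps <- 1e-6
    for (w in c("w1", "w2")) {
      fd <- net[[w]]
      for (i in seq_along(net[[w]])) {
        up <- net; up[[w]][i] <- up[[w]][i] + eps
        dn <- net; dn[[w]][i] <- dn[[w]][i] - eps
        fd[i] <- (prognet:::nn_gradient(up, x, tgt)$error -
                    prognet:::nn_gradient(dn, x, tgt)$error) / (2 * eps)
      }
      rel <- abs(fd - g[[sub("w", "g", w)]]) / pmax(abs(fd), 1e-4)
      expect_lt(max(rel), 1e-5)
    }
  }
})

test_that("zero learning rate leaves the weights untouched", {
  fx <- two_blob_fixture()
  clf <- train_pixel_classifier(fx$x, fx$y, hidden = 2, rate = 0,
                                epochs = 5, seed = 1)
  init <- prognet:::nn_init(2, 2, 1, seed = 1)
  expect_identical(clf$w1, init$w1)
  expect_identical(clf$w2, init$w2)
})

test_that("a separable two-blob fixture is learned almost perfectly", {
  fx <- two_blob_fixture()
  clf <- train_pixel_classifier(fx$x, fx$y, hidden = 2, rate = 0.3,
                                epochs = 200, seed = 4)
  acc <- mean(predict(clf, fx$x, type = "class") == fx$y)
  expect_gte(acc, 0.99)
  # squared error is non-increasing across epochs on this fixture
  expect_true(all(diff(clf$epoch_error) <= 1e-9))
})

test_that("the hidden-layer bound is enforced", {
  fx <- two_blob_fixture()
  # upper bound: N_s / (alpha (N_i + N_o)) = 240 / (5 * 3) = 16
  expect_error(train_pixel_classifier(fx$x, fx$y, hidden = 17, seed = 1),
               "bound")
  expect_error(train_pixel_classifier(fx$x, fx$y, hidden = 0, seed = 1),
               "bound")
  clf <- train_pixel_classifier(fx$x, fx$y, hidden = 16, rate = 0.3,
                                epochs = 3, seed = 1)
  expect_identical(clf$sizes[2], 16L)
})

test_that("degenerate classifiers produce the expected masks", {
  ph <- make_phantom(phantom_spec(shape = c(1, 20, 20), spacing = c(1, 1, 1),
                                  center = c(0.5, 10, 10),
                                  semiaxes = c(0.4, 5, 5), noise_sd = 0))
  img <- ph$image[1, , ]
  # force the output unit to saturate at 1 regardless of input
  always1 <- prognet:::nn_init(5, 2, 1, seed = 1)
  always1$w2[] <- 0; always1$w2[3, 1] <- 50
  m1 <- segment(img, always1)
  expect_true(all(m1))
  expect_identical(max(prognet:::label_components(m1)), 1L)

  always0 <- always1; always0$w2[3, 1] <- -50
  expect_warning(m0 <- segment(img, always0), "empty mask")
  expect_false(any(m0))
})

test_that("a trained classifier segments the noiseless phantom accurately", {
  ph <- make_phantom(phantom_spec(shape = c(1, 48, 48), spacing = c(1, 1, 1),
                                  center = c(0.5, 24, 24),
                                  semiaxes = c(0.4, 12, 12), noise_sd = 0))
  img <- ph$image[1, , ]
  truth <- ph$mask[1, , ]
  feats <- pixel_features(img)
  lab <- as.integer(as.vector(truth))
  set.seed(2)
  sel <- c(which(lab == 1), sample(which(lab == 0), 2 * sum(lab)))
  clf <- train_pixel_classifier(feats[sel, ], lab[sel], rate = 0.5,
                                epochs = 30, seed = 3)
  got <- segment(img, clf)
  expect_gte(dice_coef(got, truth), 0.95)
})
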