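# k-means labeling, the Takagi-Sugeno forward pass against a closed-form
# oracle, hybrid training, and error statistics.

test_that("k-means recovers well-separated blobs and orders labels", {
  set.seed(1)
  n <- 15
  # impairment shifts every feature, severity most visible in FH2/FH3
  blob <- function(shift, spread = 0.5) {
    m <- matrix(rnorm(n * 13, shift, spread), n)
    colnames(m) <- c("FL1", "FL2", "FL3", "FL4", "FM1", "FM2", "FM3",
                     "FM4", "FM5", "FH1", "FH2", "FH3", "FH4")
    m
  }
  x <- rbind(blob(0), blob(5), blob(10))
  truth <- rep(1:3, each = n)
  ds <- kmeans_label(x, seed = 7)
  expect_equal(ari(ds$cluster, truth), 1.0)
  # labels ascend with the generating severity
  expect_equal(as.numeric(tapply(ds$y, truth, unique)), c(0, 0.5, 1))
  # determinism
  ds2 <- kmeans_label(x, seed = 7)
  expect_identical(ds$y, ds2$y)
  expect_identical(ds$cluster, ds2$cluster)
})

test_that("three distinct points with k = 3 each get their own cluster", {
  x <- matrix(c(0, 0, 5, 5, 10, 10), 3, byrow = TRUE)
  colnames(x) <- c("FH2", "FH3")
  ds <- kmeans_label(x, k = 3, seed = 1)
  expect_equal(sort(unique(ds$cluster)), 1:3)
  expect_equal(sort(ds$y), c(0, 0.5, 1))
  expect_error(kmeans_label(x[c(1, 1, 1), ], k = 3, seed = 1), "distinct")
})

test_that("initialization reproduces cluster statistics", {
  set.seed(2)
  x <- matrix(rnorm(40 * 4), 40)
  colnames(x) <- c("FH1", "FH2", "FH3", "FH4")
  cl <- rep(1:2, each = 20)
  ds <- labeled_dataset(x, y = ifelse(cl == 1, 0, 1), cluster = cl)
  m <- anfis_init(ds)
  expect_equal(m$centers[1, ], unname(colMeans(ds$xs[1:20, ])),
               tolerance = 1e-12)
  expect_equal(m$sigmas[2, ],
               unname(pmax(apply(ds$xs[21:40, ], 2, sd), 0.1)),
               tolerance = 1e-12)
  # consequents start at zero weights with the label as intercept
  expect_equal(m$coef[, 1:4], matrix(0, 2, 4))
  expect_equal(m$coef[, 5], c(0, 1))
  # sigma floor engages for a zero-variance feature
  x0 <- x
  x0[, 2] <- 7
  ds0 <- labeled_dataset(x0, y = ifelse(cl == 1, 0, 1), cluster = cl)
  expect_equal(anfis_init(ds0)$sigmas[, 2], c(0.1, 0.1))
})

test_that("the forward pass matches the closed-form oracle", {
  set.seed(3)
  for (i in 1:60) {
    m <- random_anfis(p = 13, k = 3)
    x <- rnorm(13)
    expect_equal(anfis_forward(m, x),
                 ts_forward_oracle(m$centers, m$sigmas, m$coef, x),
                 tolerance = 1e-12)
  }
  # normalized strengths sum to one
  m <- random_anfis()
  xs <- matrix(rnorm(20 * 13), 20)
  wn <- etmt:::anfis_norm_strengths(m, xs)
  expect_equal(rowSums(wn), rep(1, 20), tolerance = 1e-12)
  expect_error(anfis_forward(m, rnorm(5)), "length")
})

test_that("a single-rule model is exactly its linear consequent", {
  m <- random_anfis(p = 3, k = 1)
  x <- c(0.5, -1, 2)
  expect_equal(anfis_forward(m, x),
               sum(m$coef[1, 1:3] * x) + m$coef[1, 4], tolerance = 1e-12)
})

test_that("far-from-support inputs fall back to the nearest rule", {
  m <- random_anfis(p = 2, k = 2)
  m$centers <- rbind(c(0, 0), c(10, 10))
  m$sigmas <- matrix(0.1, 2, 2)
  x <- c(1e4, 1e4) # strengths underflow to zero
  got <- anfis_forward(m, x)
  expect_equal(got, sum(m$coef[2, 1:2] * x) + m$coef[2, 3],
               tolerance = 1e-9)
})

test_that("error statistics follow their definitions", {
  expect_equal(unlist(error_stats(c(1, 2), c(1, 2))[1:3]),
               c(rmse = 0, error_mean = 0, error_std = 0))
  s <- error_stats(rep(0, 4), rep(0.5, 4))
  expect_equal(s$rmse, 0.5)
  expect_equal(s$error_mean, 0.5)
  expect_equal(s$error_std, 0)
  s2 <- error_stats(c(1, -1), c(0, 0))
  expect_equal(s2$rmse, 1)
  expect_equal(s2$error_mean, 0)
  expect_equal(s2$error_std, sqrt(2))
  expect_error(error_stats(1:3, 1:2), "length")
})

test_that("zero epochs leave the model untouched", {
  b <- ts2_benchmark(n = 60, seed = 2)
  ds <- labeled_dataset(b$x, b$y, cluster = b$cl)
  m0 <- anfis_init(ds)
  fit <- anfis_train(m0, ds, epochs = 0, seed = 5)
  expect_identical(fit$model$centers, m0$centers)
  expect_identical(fit$model$sigmas, m0$sigmas)
  expect_identical(fit$model$coef, m0$coef)
  expect_false(fit$model$trained)
})

test_that("one least-squares step never increases training error", {
  b <- ts2_benchmark(n = 100, seed = 3)
  ds <- labeled_dataset(b$x, b$y, cluster = b$cl)
  m0 <- anfis_init(ds)
  fit1 <- anfis_train(m0, ds, epochs = 1, seed = 5, learn_rate = 0)
  pre <- sqrt(mean((anfis_forward(m0, ds$xs[fit1$split$train, ]) -
                      ds$y[fit1$split$train])^2))
  expect_lte(fit1$train_stats$rmse, pre + 1e-12)
})

test_that("hybrid training recovers a known Takagi-Sugeno system", {
  b <- ts2_benchmark(n = 200, seed = 1, noise_sd = 0.01)
  ds <- labeled_dataset(b$x, b$y, cluster = b$cl)
  m0 <- anfis_init(ds)
  init_rmse <- sqrt(mean((anfis_forward(m0, ds$xs) - ds$y)^2))
  fit <- anfis_train(m0, ds, epochs = 30, seed = 9)
  expect_lt(fit$test_stats$rmse, 0.05)
  # at least a 5-fold improvement over the initialized model
  expect_lt(fit$test_stats$rmse, init_rmse / 5)
  # identical seeds give bit-identical trained parameters
  fit2 <- anfis_train(m0, ds, epochs = 30, seed = 9)
  expect_identical(fit$model, fit2$model)
  expect_identical(fit$split, fit2$split)
})

test_that("training rejects degenerate datasets and splits", {
  b <- ts2_benchmark(n = 6, seed = 4)
  ds <- labeled_dataset(b$x, b$y, cluster = b$cl)
  expect_error(anfis_train(anfis_init(ds), ds, seed = 1), "too small")
  x <- matrix(rnorm(20 * 2), 20)
  ds1 <- labeled_dataset(x, y = rep(0.5, 20))
  expect_error(anfis_train(anfis_init(ds1), ds1, seed = 1),
               "single-label")
})

test_that("participant scoring clips, bands, and demands training", {
  b <- ts2_benchmark(n = 100, seed = 5)
  ds <- labeled_dataset(b$x, b$y, cluster = b$cl)
  m0 <- anfis_init(ds)
  expect_error(score_participant(m0, b$x[1, ]), "not trained")
  fit <- anfis_train(m0, ds, epochs = 10, seed = 2)
  # scoring at a cluster center in raw space lands near the local label
  center_raw <- colMeans(b$x[b$cl == 2, ])
  sc <- score_participant(fit$model, center_raw)
  expect_true(sc$score >= 0 && sc$score <= 1)
  expect_equal(sc$score, min(max(sc$raw, 0), 1))
  # clipping
  m <- fit$model
  m$coef[, 3] <- 100
  raw <- anfis_predict(m, b$x[1, ])
  expect_gt(raw, 1)
  m$trained <- TRUE
  expect_equal(score_participant(m, b$x[1, ])$score, 1)
})

test_that("models round-trip exactly through JSON", {
  b <- ts2_benchmark(n = 100, seed = 6)
  ds <- labeled_dataset(b$x, b$y, cluster = b$cl)
  fit <- anfis_train(anfis_init(ds), ds, epochs = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_anfis_model(fit$model, path)
  back <- read_anfis_model(path)
  expect_identical(back$centers, fit$model$centers)
  expect_identical(back$sigmas, fit$model$sigmas)
  expect_identical(back$coef, fit$model$coef)
  expect_identical(back$center_x, fit$model$center_x)
  expect_identical(back$scale_x, fit$model$scale_x)
  # predictions are bit-identical after reload
  expect_identical(anfis_predict(back, b$x[1:5, ]),
                   anfis_predict(fit$model, b$x[1:5, ]))
})
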