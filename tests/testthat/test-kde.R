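test_that("Silverman bandwidths follow the stated rule with a floor", {
  # one point per class: sd = IQR = 0, so every bandwidth hits the floor
  clf <- fit_kde(list("0" = matrix(c(1, 2), 1), "1" = matrix(c(3, 4), 1)))
  expect_equal(clf$models[["0"]]$bandwidths, c(1e-3, 1e-3))

  # two points {0, 10}: population sd = 5, IQR(type 2) = 10
  clf2 <- fit_kde(list("0" = matrix(c(0, 10), ncol = 1)))
  expect_equal(clf2$models[["0"]]$bandwidths,
               0.9 * min(5, 10 / 1.34) * 2^(-1 / 5), tolerance = 1e-12)

  set.seed(2)
  pts <- list("0" = matrix(rnorm(40), 10), "1" = matrix(rnorm(40), 10))
  expect_identical(fit_kde(pts)$models[["1"]]$bandwidths,
                   fit_kde(pts)$models[["1"]]$bandwidths)

  expect_error(fit_kde(list("0" = matrix(numeric(0), 0, 2))),
               class = "ieegsift_empty_class")
})

test_that("log density matches the closed form and integrates to one", {
  kde <- list(class_code = "0", points = matrix(c(0.3, -0.2), 1),
              bandwidths = c(1, 1))
  expect_equal(kde_log_density(kde, c(0.3, -0.2)), log(1 / (2 * pi)),
               tolerance = 1e-12)

  kde1 <- list(class_code = "0", points = matrix(c(-1, 0.5, 2), ncol = 1),
               bandwidths = 0.7)
  grid <- seq(-15, 15, length.out = 20001)
  dens <- exp(kde_log_density(kde1, matrix(grid, ncol = 1)))
  expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 1e-4)

  expect_error(kde_log_density(kde, c(1, 2, 3)), class = "ieegsift_shape_mismatch")
})

test_that("log-domain density matches the brute-force oracle", {
  set.seed(42)
  for (trial in 1:20) {
    D <- sample(1:3, 1); N <- sample(1:5, 1)
    pts <- matrix(rnorm(N * D, sd = 2), N, D)
    bw <- runif(D, 0.2, 1.5)
    kde <- list(class_code = "0", points = pts, bandwidths = bw)
    x <- rnorm(D, sd = 3)
    expect_equal(kde_log_density(kde, x), log(brute_kde_density(pts, bw, x)),
                 tolerance = 1e-9)
  }
})

test_that("classification picks the nearest class density and normalizes posteriors", {
  pts <- lapply(c(0, 10, 20, 30), function(m) matrix(c(m, m), 1))
  names(pts) <- as.character(0:3)
  clf <- fit_kde(pts, eps_bw = 1)
  out <- kde_classify(clf, c(20, 20))
  expect_identical(out$class, 2L)

  set.seed(3)
  q <- matrix(rnorm(20, sd = 10), 10, 2)
  out2 <- kde_classify(clf, q)
  expect_equal(rowSums(out2$posterior), rep(1, 10), tolerance = 1e-9)
  expect_true(all(out2$posterior >= 0))
})

test_that("posteriors match a brute-force Bayes oracle over 200 random instances", {
  set.seed(7)
  for (trial in 1:200) {
    D <- sample(1:3, 1)
    n_classes <- sample(2:4, 1)
    pts <- lapply(seq_len(n_classes), function(i) {
      matrix(rnorm(sample(1:5, 1) * D, mean = rnorm(1, sd = 2)), ncol = D)
    })
    names(pts) <- as.character(seq_len(n_classes) - 1)
    priors <- runif(n_classes); priors <- priors / sum(priors)
    clf <- fit_kde(pts, eps_bw = 0.1, priors = priors)
    # query near a training point so the non-log-domain oracle cannot underflow
    anchor <- pts[[sample(n_classes, 1)]]
    x <- anchor[sample(nrow(anchor), 1), ] + rnorm(D, sd = 0.5)
    got <- kde_classify(clf, x)
    bw <- lapply(clf$models, `[[`, "bandwidths")
    ref <- brute_posterior(lapply(clf$models, `[[`, "points"), bw, priors, x)
    expect_equal(as.numeric(got$posterior), as.numeric(ref), tolerance = 1e-9)
    expect_identical(got$class, as.integer(names(pts)[which.max(ref)]))
  }
})

test_that("well-separated Gaussian classes are classified almost perfectly", {
  set.seed(15)
  train <- list("0" = matrix(rnorm(200), 100, 2),
                "1" = matrix(rnorm(200, mean = 6), 100, 2))
  clf <- fit_kde(train)
  test_x <- rbind(matrix(rnorm(400), 200, 2), matrix(rnorm(400, mean = 6), 200, 2))
  truth <- rep(0:1, each = 200)
  acc <- mean(kde_classify(clf, test_x)$class == truth)
  expect_gte(acc, 0.99)
})
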