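test_that("descriptor has the configured structure", {
  img <- makeScene(sceneSpec("coast", 0.5, width = 64L, height = 64L,
                             seed = 1L))
  g <- gistDescriptor(toLab(img), scales = 4, orientations = 8, grid = 4)
  expect_length(g, 3 * 4 * 8 * 16 + 1)
  expect_equal(unname(g[length(g)]), 1)
  # constant image: all features (numerically) zero, intercept 1
  flat <- methods::new("HorizonImage", id = "f",
                       pixels = array(128, c(64, 64, 3)),
                       sceneClass = "other", trueHorizon = 0.5)
  gf <- gistDescriptor(toLab(flat), scales = 2, orientations = 4,
                       grid = 2)
  expect_lt(max(abs(gf[-length(gf)])), 1e-9)
  expect_error(gistDescriptor(toLab(makeScene(
    sceneSpec("coast", 0.5, width = 24L, height = 24L)))), "32 x 32")
})

test_that("horizontal gratings drive the horizontal-orientation features", {
  # grating with vertical modulation (horizontal stripes) at a bank
  # wavelength; orientation index for pi/2 is o = O/2 + 1
  n <- 64; wl <- 8
  stripe <- 128 + 100 * sin(2 * pi * (0:(n - 1)) / wl)
  px <- array(rep(matrix(stripe, n, n), 3), c(n, n, 3))
  px <- pmin(pmax(px, 0), 255)
  img <- methods::new("HorizonImage", id = "g", pixels = px,
                      sceneClass = "other", trueHorizon = 0.5)
  g <- gistDescriptor(toLab(img), scales = 4, orientations = 8, grid = 2)
  o <- rep(rep(1:8, each = 4), 3 * 4)       # orientation index per feature
  horiz <- g[-length(g)][o == 5]            # theta = pi/2
  other <- g[-length(g)][o != 5]
  expect_gt(mean(horiz), 5 * mean(other))
})

test_that("grid-cell permutation permutes feature blocks identically", {
  img <- makeScene(sceneSpec("city", 0.4, width = 64L, height = 64L,
                             seed = 3L))
  g <- gistDescriptor(toLab(img), scales = 2, orientations = 2, grid = 2)
  # flipping the image horizontally swaps the left/right cell columns
  px <- pixels(img)[, 64:1, , drop = FALSE]
  gf <- gistDescriptor(toLab(methods::new("HorizonImage", id = "m",
    pixels = px, sceneClass = "city", trueHorizon = 0.4)),
    scales = 2, orientations = 2, grid = 2)
  # cell ids are column-major: 1,2 = left cells, 3,4 = right cells
  cells <- rep(1:4, 3 * 2 * 2)
  reord <- c(3, 4, 1, 2)
  a <- g[-length(g)]
  b <- gf[-length(gf)]
  for (blk in seq_len(3 * 2 * 2)) {
    ia <- which(rep(seq_len(12), each = 4) == blk)
    expect_equal(unname(b[ia]), unname(a[ia][reord]), tolerance = 0.05)
  }
})

test_that("K = 1 mixture equals closed-form ridge regression", {
  set.seed(11)
  n <- 60; d <- 10
  X <- cbind(matrix(rnorm(n * (d - 1)), n), 1)
  w <- runif(d, -0.1, 0.1)
  y <- pmin(pmax(as.numeric(X %*% w) + 0.5 + rnorm(n, 0, 0.02), 0), 1)
  fit <- fitMixture(X, y, K = 1, nRestarts = 1, seed = 1, gateDim = 4)
  expect_lt(max(abs(fit@coef[, 1] - oracleRidge(X, y, 1e-6))), 1e-6)
  # the dual-form solver agrees with the normal equations when d > n
  Xw <- cbind(matrix(rnorm(20 * 39), 20), 1)
  yw <- runif(20)
  fitw <- fitMixture(Xw, yw, K = 1, nRestarts = 1, seed = 2, gateDim = 4)
  expect_lt(max(abs(fitw@coef[, 1] - oracleRidge(Xw, yw, 1e-6))), 1e-5)
})

test_that("EM log-likelihood is monotone and restarts keep the best", {
  set.seed(12)
  n <- 90
  z <- rep(c(0, 1, 2), each = n / 3)
  X <- cbind(rnorm(n) + 6 * z, rnorm(n), 1)
  y <- pmin(pmax(0.3 + 0.15 * z + rnorm(n, 0, 0.03), 0), 1)
  fit <- fitMixture(X, y, K = 3, nRestarts = 5, seed = 3, gateDim = 2)
  expect_true(all(diff(fit@trace) > -1e-8))
  expect_true(all(is.finite(fit@trace)))
  # selected restart dominates each single restart
  singles <- vapply(1:5, function(r)
    fitMixture(X, y, K = 3, nRestarts = 1,
               seed = skyline:::childSeed(3, "em", r),
               gateDim = 2)@logLik, numeric(1))
  expect_gte(fit@logLik + 1e-8, max(singles))
})

test_that("two disjoint linear regimes are fit to numerical precision", {
  set.seed(13)
  n <- 80
  z <- rep(c(0, 1), each = n / 2)
  X <- cbind(rnorm(n) + 10 * z, rnorm(n), 1)
  y <- ifelse(z == 0, 0.3 + 0.01 * X[, 2], 0.7 + 0.01 * X[, 2])
  fit <- fitMixture(X, y, K = 2, nRestarts = 3, seed = 4, gateDim = 2)
  pred <- predictHorizon(fit, X)
  expect_lt(sqrt(mean((pred - y)^2)), 1e-3)
})

test_that("single-regressor parameter recovery reaches the noise floor", {
  set.seed(14)
  n <- 500; d <- 50; sigma <- 0.02
  X <- cbind(matrix(rnorm(n * (d - 1), 0, 0.5), n), 1)
  w <- c(runif(d - 1, -0.02, 0.02), 0.5)
  y <- pmin(pmax(as.numeric(X %*% w) + rnorm(n, 0, sigma), 0), 1)
  tr <- sample(n, 400)
  fit <- fitMixture(X[tr, ], y[tr], K = 1, nRestarts = 1, seed = 5,
                    gateDim = 8)
  pred <- predictHorizon(fit, X[-tr, ])
  expect_lt(sqrt(mean((pred - y[-tr])^2)), 2 * sigma)
})

test_that("prediction is a clamped responsibility-weighted blend", {
  # zero weights with intercept 0.55 predict 0.55 everywhere
  mix <- methods::new("RegressorMixture", K = 1L,
    coef = matrix(c(0, 0, 0.55), 3, 1), noiseSd = 0.1, prior = 1,
    gateMean = matrix(0, 2, 1), gateSd = matrix(1, 2, 1),
    pca = list(center = c(0, 0), rotation = diag(2)), logLik = 0,
    trace = 0)
  expect_equal(as.numeric(predictHorizon(mix, c(3, -2, 1))), 0.55)
  # clamping flags out-of-range raw predictions
  mix2 <- methods::new("RegressorMixture", K = 1L,
    coef = matrix(c(0, 0, -0.1), 3, 1), noiseSd = 0.1, prior = 1,
    gateMean = matrix(0, 2, 1), gateSd = matrix(1, 2, 1),
    pca = list(center = c(0, 0), rotation = diag(2)), logLik = 0,
    trace = 0)
  p <- predictHorizon(mix2, c(1, 1, 1))
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "clamped"))
  expect_error(predictHorizon(mix, c(1, 2)), "dims")
  # blend matches a brute-force responsibility computation
  set.seed(15)
  n <- 40
  z <- rep(c(0, 1), each = n / 2)
  X <- cbind(rnorm(n) + 8 * z, 1)
  y <- ifelse(z == 0, 0.35, 0.65)
  fit <- fitMixture(X, y, K = 2, nRestarts = 2, seed = 6, gateDim = 1)
  pred <- predictHorizon(fit, X)
  Z <- sweep(X[, 1, drop = FALSE], 2, fit@pca$center) %*% fit@pca$rotation
  manual <- vapply(seq_len(n), function(i) {
    lw <- vapply(1:2, function(k)
      log(fit@prior[k]) + sum(dnorm(Z[i, ], fit@gateMean[, k],
                                    fit@gateSd[, k], log = TRUE)),
      numeric(1))
    wgt <- exp(lw - max(lw)); wgt <- wgt / sum(wgt)
    min(max(sum(wgt * (X[i, ] %*% fit@coef)), 0), 1)
  }, numeric(1))
  expect_lt(max(abs(as.numeric(pred) - manual)), 1e-9)
})

test_that("degenerate mixture inputs are rejected", {
  X <- cbind(matrix(1, 10, 3), 1)
  expect_error(fitMixture(X, runif(10), K = 2), "degenerate")
  X2 <- cbind(matrix(rnorm(10 * 3), 10), 1)
  expect_error(fitMixture(X2, runif(10), K = 0), "K")
  expect_error(fitMixture(X2, runif(10) + 1, K = 1), "0, 1")
  expect_error(fitMixture(X2, runif(10), K = 6), "per component")
})
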