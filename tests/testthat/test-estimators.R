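test_that("division profile finds a constructed light/dark split", {
  ch <- stepChannel(100, 40, boundary = 50)
  p <- profileValues(profileDiv(ch, divParams(localWeight = 0)))
  expect_equal(which.max(p) - 1L, 50L)       # 0-based boundary
  # exchanged polarity: the boundary is the worst split
  pd <- profileValues(profileDiv(ch, divParams(localWeight = 0),
                                 "dark_above"))
  expect_lte(pd[51], min(p[-1]))
  expect_gt(abs((which.max(pd) - 1L) - 50L), 10L)
  # constant image: all-zero profile, readout falls back to the tie-break
  pc <- profileDiv(matrix(7, 20, 20), divParams())
  expect_true(all(profileValues(pc) == 0))
  expect_equal(winnerTakesAll(pc), 0.475)    # center row of H = 20
})

test_that("division profile matches the two-loop oracle", {
  for (seed in 1:6) {
    ch <- randomChannel(40, 30, seed)
    p <- profileValues(profileDiv(ch, divParams(1.2, 0.7)))
    expect_lt(max(abs(p - oracleDiv(ch, 1.2, 0.7))), 1e-9)
    pn <- profileValues(profileDiv(ch, divParams(0.8, 0.3), "dark_above"))
    expect_lt(max(abs(pn - oracleDiv(ch, 0.8, 0.3, darkAbove = TRUE))),
              1e-9)
  }
})

test_that("gradient profile localizes steps and matches its oracle", {
  ch <- stepChannel(100, 40, boundary = 50)
  p0 <- profileValues(profileLin(ch, smoothingSigma = 0))
  expect_equal(which(p0 != 0), 50L)          # single nonzero at boundary
  expect_true(all(profileValues(profileLin(matrix(3, 10, 10), 0)) == 0))
  for (seed in 1:6) {
    ch <- randomChannel(25, 25, seed + 100)
    p <- profileValues(profileLin(ch, 1.5))
    expect_lt(max(abs(p - oracleLin(ch, 1.5))), 1e-9)
  }
})

test_that("Gabor profile responds to horizontal structure", {
  # zero-mean kernel: constant image gives (numerically) zero profile
  pc <- profileValues(profileGab(matrix(11, 40, 40),
                                 gaborParams(6, 1, 0.8)))
  expect_lt(max(abs(pc)), 1e-9)
  # step edge: argmax within ceiling(wavelength / 2) of the boundary
  ch <- stepChannel(60, 40, boundary = 30)
  p <- profileValues(profileGab(ch, gaborParams(8, 1, 0.8)))
  expect_lte(abs((which.max(p) - 0.5) - 30), ceiling(8 / 2))
  # square-wave grating at the wavelength: interior rows within 5%
  wl <- 8
  grating <- matrix(rep(ifelse((0:(63)) %/% (wl / 2) %% 2 == 0, 80, 20),
                        40), 64, 40)
  pg <- profileValues(profileGab(grating, gaborParams(wl, 1, 0.8)))
  interior <- pg[20:45]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.05)
  expect_error(profileGab(matrix(0, 10, 10), gaborParams(12)),
               "wavelength")
})

test_that("Gabor profile matches the naive convolution oracle", {
  for (seed in 1:4) {
    ch <- randomChannel(30, 24, seed + 200)
    p <- profileValues(profileGab(ch, gaborParams(5, 1, 0.8)))
    expect_lt(max(abs(p - oracleGab(ch, 5, 1, 0.8))), 1e-9)
  }
})

test_that("vanishing-point profile peaks where line bundles meet", {
  # three one-pixel dark lines through (W/2, floor(0.4 H))
  h <- 80; w <- 100
  ch <- matrix(200, h, w)
  vy <- floor(0.4 * h) + 1L; vx <- w %/% 2
  for (x1 in c(5, 50, 95)) {
    ch[skyline:::linePixels(vx, vy, x1, h, h, w)] <- 10
  }
  p <- profileValues(profileVan(ch))
  # Canny localizes a one-pixel-wide line by the ridges on either side,
  # so recovered lines sit within a pixel of the drawn ones and the
  # crossing can shift by a couple of rows
  expect_lte(abs((which.max(p) - 1L) - floor(0.4 * h)), 3L)
  # blank image: all-zero profile is legal
  expect_true(all(profileValues(profileVan(matrix(5, 32, 32))) == 0))
})

test_that("vanishing-point voting matches the brute-force accumulator", {
  # two bundles: 4 strong lines at 0.3 H, 2 faint at 0.7 H
  h <- 64; w <- 80
  ch <- matrix(180, h, w)
  for (x1 in c(4, 30, 55, 78)) {
    ch[skyline:::linePixels(w %/% 2, round(0.3 * h), x1, h, h, w)] <- 10
  }
  for (x1 in c(15, 65)) {
    ch[skyline:::linePixels(w %/% 2, round(0.7 * h), x1, h, h, w)] <- 120
  }
  params <- vanParams()
  p <- profileValues(profileVan(ch, params))
  # the stronger bundle wins; Canny ridges sit one pixel either side of a
  # drawn line, so the crossing is smeared over a few rows
  expect_lt(abs(winnerTakesAll(p) - 0.3), 0.08)
  expect_gt(abs(winnerTakesAll(p) - 0.7), 0.2)
  lines <- vanLineSet(ch, params)
  expect_gt(length(lines), 0)
  oracle <- oracleVanProfile(lines, h, w, params$exponentRho)
  expect_lt(max(abs(p - oracle)), 1e-9)
  # oracle equivalence on random images too
  for (seed in 1:3) {
    chr <- randomChannel(32, 40, seed + 300)
    pr <- profileValues(profileVan(chr, params))
    orr <- oracleVanProfile(vanLineSet(chr, params), 32, 40,
                            params$exponentRho)
    expect_lt(max(abs(pr - orr)), 1e-9)
  }
})

test_that("winner-takes-all reads out the argmax with center tie-breaks", {
  expect_equal(winnerTakesAll(c(0, 0, 5, 0)), 0.625)
  expect_equal(winnerTakesAll(rep(1, 5)), 0.5)
  expect_equal(winnerTakesAll(c(0, 2, 2, 0, 0)), 0.5)  # row 2 nearer center
  expect_error(winnerTakesAll(c(1, NA, 2)), "non-finite")
  expect_error(winnerTakesAll(numeric(0)), "empty")
})

test_that("estimators refuse multi-channel input", {
  arr <- array(1, c(8, 8, 3))
  expect_error(profileLin(arr), "one channel")
  expect_error(profileDiv(arr), "one channel")
})

test_that("flip equivariance holds for the symmetric estimators", {
  for (seed in 1:10) {
    img <- makeScene(sceneSpec(sample(c("coast", "city", "open_country"),
                                      1), runif(1, 0.35, 0.65),
                               seed = seed + 40L))
    ch <- labChannel(toLab(img), "L")
    chf <- ch[nrow(ch):1, ]
    h <- nrow(ch)
    for (fn in list(function(x) profileLin(x, 1),
                    function(x) profileGab(x, gaborParams(6, 1, 0.5)))) {
      y <- winnerTakesAll(fn(ch))
      yf <- winnerTakesAll(fn(chf))
      expect_lte(abs(yf - (1 - y)), 1 / h + 1e-12)
    }
  }
})

test_that("division global term obeys polarity duality", {
  for (seed in 1:5) {
    ch <- randomChannel(24, 18, seed + 400)
    neg <- max(ch) - ch                     # negated, shifted to valid range
    a <- profileValues(profileDiv(ch, divParams(localWeight = 0),
                                  "dark_above"))
    b <- profileValues(profileDiv(neg, divParams(localWeight = 0),
                                  "light_above"))
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("dummy estimators have the declared distributions", {
  expect_equal(dummyEstimate(dummyParams("uniform", center = 0.4,
                                         halfWidth = 0), seed = 1), 0.4)
  expect_equal(dummyEstimate(dummyParams("normal", mean = 0.6, sd = 0),
                             seed = 1), 0.6)
  d <- dummyEstimate(dummyParams("uniform", center = 0.5,
                                 halfWidth = 0.2), seed = 2, n = 1e5)
  ks <- suppressWarnings(stats::ks.test(d, "punif", 0.3, 0.7))
  expect_gt(ks$p.value, 0.01)
})
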