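test_that("PNG round trips are lossless and failures are named", {
  set.seed(10)
  px <- array(as.double(sample(0:255, 64 * 48 * 3, replace = TRUE)),
              c(48, 64, 3))
  img <- methods::new("HorizonImage", id = "rt", pixels = px,
                      sceneClass = "other", trueHorizon = 0.5)
  path <- tempfile(fileext = ".png")
  writeImagePNG(img, path)
  back <- readImagePNG(path)
  expect_identical(pixels(back), px)
  # grayscale promotion to three identical channels
  gpath <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(20 * 30), 20, 30), gpath)
  g <- readImagePNG(gpath)
  expect_identical(pixels(g)[, , 1], pixels(g)[, , 3])
  # empty and missing files error with the path in the message
  zpath <- tempfile(fileext = ".png")
  file.create(zpath)
  expect_error(readImagePNG(zpath), basename(zpath), fixed = TRUE)
  expect_error(readImagePNG("no/such/file.png"), "no/such/file.png")
})

test_that("Lab conversion matches the published sRGB formulas", {
  mk <- function(r, g, b) {
    px <- array(0, c(2, 2, 3))
    px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
    methods::new("HorizonImage", id = "c", pixels = px,
                 sceneClass = "other", trueHorizon = 0.5)
  }
  white <- toLab(mk(255, 255, 255))
  expect_equal(white@L[1, 1], 100, tolerance = 1e-6)
  expect_lt(abs(white@a[1, 1]), 0.5)
  expect_lt(abs(white@b[1, 1]), 0.5)
  black <- toLab(mk(0, 0, 0))
  expect_equal(black@L[1, 1], 0, tolerance = 1e-9)
  # frozen reference values from an independent implementation of the
  # published sRGB (D65) -> L*a*b* formulas (scikit-image color.rgb2lab)
  refs <- list(
    list(rgb = c(128, 128, 128), lab = c(53.585013, -0.001473, 0.002791)),
    list(rgb = c(200, 30, 60), lab = c(43.563032, 64.057043, 28.472346)),
    list(rgb = c(10, 120, 250), lab = c(52.281909, 22.102152,
                                        -72.089333)))
  for (r in refs) {
    got <- toLab(mk(r$rgb[1], r$rgb[2], r$rgb[3]))
    expect_lt(abs(got@L[1, 1] - r$lab[1]), 0.1)
    expect_lt(abs(got@a[1, 1] - r$lab[2]), 0.1)
    expect_lt(abs(got@b[1, 1] - r$lab[3]), 0.1)
    # grDevices' pipeline (chromaticity-derived matrix) as a coarser
    # cross-check
    cc <- grDevices::convertColor(matrix(r$rgb / 255, 1), from = "sRGB",
                                  to = "Lab", to.ref.white = "D65")
    expect_lt(max(abs(c(got@L[1, 1], got@a[1, 1], got@b[1, 1]) - cc)),
              0.5)
  }
})

test_that("condition transforms keep the stated geometry", {
  img <- makeScene(sceneSpec("coast", 0.5, width = 160L, height = 120L,
                             seed = 2L))
  # inversion is an involution
  inv <- applyCondition(img, "inverted")
  invinv <- applyCondition(methods::new("HorizonImage", id = "i",
    pixels = pixels(inv), sceneClass = "other", trueHorizon = 0.5),
    "inverted")
  expect_identical(pixels(invinv), pixels(img))
  # middle on a 600-row image keeps rows 100..499 (0-based); columns are
  # trimmed from the borders, so rows match a contiguous column window
  tall <- makeScene(sceneSpec("coast", 0.5, width = 64L, height = 600L,
                              seed = 3L))
  mid <- applyCondition(tall, "middle")
  wMid <- dim(pixels(mid))[2]
  expect_equal(dim(pixels(mid))[1], 400)
  offsets <- which(vapply(0:(64 - wMid), function(o)
    identical(pixels(mid)[1, , 1],
              pixels(tall)[101, (o + 1):(o + wMid), 1]), logical(1))) - 1L
  expect_length(offsets, 1L)
  expect_identical(pixels(mid)[400, , ],
                   pixels(tall)[500, (offsets + 1):(offsets + wMid), ])
  expect_false(identical(pixels(mid)[1, , ],
                         pixels(tall)[100, (offsets + 1):(offsets + wMid),
                                      ]))
  # lower on a 4:3 image restores the aspect ratio within one column
  four3 <- makeScene(sceneSpec("coast", 0.5, width = 160L, height = 120L,
                               seed = 4L))
  low <- applyCondition(four3, "lower")
  d <- dim(pixels(low))
  expect_lte(abs(d[2] / d[1] - 160 / 120), 1 / d[1])
  # blur preserves the mean within 0.5%
  bl <- applyCondition(img, "blurred", blurSigmaFraction = 0.02)
  expect_lt(abs(mean(pixels(bl)) - mean(pixels(img))) / mean(pixels(img)),
            0.005)
  expect_error(applyCondition(img, "sideways"), "unknown condition")
})

test_that("coordinate maps are exact inverses and match the window spans", {
  img <- makeScene(sceneSpec("coast", 0.5, width = 96L, height = 96L,
                             seed = 5L))
  for (cond in conditionNames()) {
    ci <- applyCondition(img, cond)
    m <- coordinateMap(ci)
    yw <- seq(0, 1, length.out = 100)          # window coordinates
    expect_lt(max(abs(as.numeric(toWindowCoords(
      as.numeric(toFullCoords(yw, m)), m)) - yw)), 1e-12)
    yf <- as.numeric(toFullCoords(yw, m))      # full coords in the span
    expect_lt(max(abs(as.numeric(toFullCoords(
      as.numeric(toWindowCoords(yf, m)), m)) - yf)), 1e-12)
  }
  # identity, window span and mirror examples
  expect_equal(as.numeric(toFullCoords(0.37,
    coordinateMap(applyCondition(img, "norm")))), 0.37)
  lowMap <- coordinateMap(applyCondition(img, "lower"))
  expect_equal(as.numeric(toFullCoords(c(0, 1), lowMap)), c(1 / 3, 1))
  invMap <- coordinateMap(applyCondition(img, "inverted"))
  expect_equal(as.numeric(toFullCoords(0.2, invMap)), 0.8)
  # out-of-range results are clamped and flagged
  up <- toFullCoords(1.6, lowMap)
  expect_equal(as.numeric(up), 1)
  expect_true(attr(up, "clamped"))
})
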