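# Independent brute-force oracles. Everything here is deliberately naive
# (explicit loops, closed forms, raw sums of squares) and shares no code
# path with the package internals it checks.

# Symmetric-reflection index (edge pixel included); valid for |offsets|
# up to the dimension size.
refIdx <- function(q, n) {
  ifelse(q < 1, 1 - q, ifelse(q > n, 2 * n + 1 - q, q))
}

# Naive separable Gaussian smoothing: vertical pass then horizontal pass,
# each with per-pixel loops and reflected indices.
oracleSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(x); w <- ncol(x)
  tmp <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      tmp[i, j] <- sum(k * x[refIdx(i + (-r):r, h), j])
    }
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- sum(k * tmp[i, refIdx(j + (-r):r, w)])
    }
  }
  out
}

oracleMinmax <- function(x) {
  if (max(x) == min(x)) return(rep(0, length(x)))
  (x - min(x)) / (max(x) - min(x))
}

# Two-loop implementation of the division profile.
oracleDiv <- function(ch, sigma, localWeight, darkAbove = FALSE) {
  h <- nrow(ch)
  g <- numeric(h - 1)
  for (r in 1:(h - 1)) {
    g[r] <- mean(ch[1:r, ]) - mean(ch[(r + 1):h, ])
  }
  if (darkAbove) g <- -g
  s <- oracleSmooth(ch, sigma)
  l <- numeric(h - 1)
  for (r in 1:(h - 1)) {
    l[r] <- mean(abs(s[r + 1, ] - s[r, ]))
  }
  c(0, (1 - localWeight) * oracleMinmax(g) + localWeight * oracleMinmax(l))
}

oracleLin <- function(ch, sigma) {
  s <- oracleSmooth(ch, sigma)
  h <- nrow(s)
  p <- numeric(h)
  for (r in 1:(h - 1)) {
    p[r] <- sum(abs(s[r + 1, ] - s[r, ]))
  }
  p
}

# Naive Gabor profile: kernels rebuilt from the closed formulas with an
# explicit grid loop, convolution as per-pixel sums over the kernel.
oracleGab <- function(ch, wavelength, bw, gamma) {
  slr <- (1 / pi) * sqrt(log(2) / 2) * (2^bw + 1) / (2^bw - 1)
  sigma <- slr * wavelength
  r <- ceiling(2.5 * sigma / min(1, gamma))
  ke <- matrix(0, 2 * r + 1, 2 * r + 1)
  ko <- ke
  for (dy in (-r):r) {
    for (dx in (-r):r) {
      u <- dy                                  # vertical carrier
      v <- -dx
      env <- exp(-(u^2 + gamma^2 * v^2) / (2 * sigma^2))
      ke[dy + r + 1, dx + r + 1] <- env * cos(2 * pi * u / wavelength)
      ko[dy + r + 1, dx + r + 1] <- env * sin(2 * pi * u / wavelength)
    }
  }
  ke <- ke - mean(ke)
  h <- nrow(ch); w <- ncol(ch)
  prof <- numeric(h)
  for (i in seq_len(h)) {
    acc <- 0
    for (j in seq_len(w)) {
      block <- ch[refIdx(i + (-r):r, h), refIdx(j + (-r):r, w)]
      acc <- acc + sqrt(sum(ke * block)^2 + sum(ko * block)^2)
    }
    prof[i] <- acc
  }
  prof
}

# Brute-force vote image for a given list of Hough lines: per-column /
# per-row rounding rasterization in plain loops, then exponentiated row
# sums.
oracleVanProfile <- function(lines, h, w, exponent) {
  V <- matrix(0, h, w)
  for (ln in lines) {
    ct <- cos(ln$theta); st <- sin(ln$theta)
    seen <- matrix(FALSE, h, w)
    if (abs(st) >= abs(ct)) {
      for (x in seq_len(w)) {
        y <- round((ln$rho - x * ct) / st)
        if (y >= 1 && y <= h && !seen[y, x]) {
          V[y, x] <- V[y, x] + ln$strength
          seen[y, x] <- TRUE
        }
      }
    } else {
      for (y in seq_len(h)) {
        x <- round((ln$rho - y * st) / ct)
        if (x >= 1 && x <= w && !seen[y, x]) {
          V[y, x] <- V[y, x] + ln$strength
          seen[y, x] <- TRUE
        }
      }
    }
  }
  apply(V, 1, function(row) sum(row^exponent))
}

# Extract the retained line set of profileVan (shared selection; the
# oracle below rebuilds the voting stage from it independently).
vanLineSet <- function(ch, params) {
  ce <- skyline:::cannyEdges(ch, params$cannySigma, params$cannyLow,
                             params$cannyHigh)
  hl <- skyline:::houghLines(ce$edges, ce$magnitude, params$houghRho,
                             params$houghTheta)
  acc <- hl$accumulator
  excl <- params$verticalExclusionDeg * pi / 180
  acc[, abs(hl$theta) < excl] <- 0
  ord <- skyline:::houghPeaks(acc, params$nLines)
  if (!length(ord)) return(list())
  top <- acc[ord[1]]
  lapply(ord, function(cell) {
    ri <- ((cell - 1L) %% nrow(acc)) + 1L
    ti <- ((cell - 1L) %/% nrow(acc)) + 1L
    list(rho = hl$rho[ri], theta = hl$theta[ti],
         strength = acc[cell] / top)
  })
}

# Closed-form Gaussian kernel density sum, one kernel at a time.
oracleKernelSum <- function(y, centers, h) {
  total <- 0
  for (c0 in centers) {
    total <- total + exp(-(y - c0)^2 / (2 * h^2))
  }
  total / (length(centers) * h * sqrt(2 * pi))
}

# Pearson correlation from the textbook formula, loop version.
oraclePearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# ICC(2,1)/ICC(2,k) from raw sums of squares.
oracleICC <- function(m, form) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rm <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((m - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

# Ridge regression by the normal equations.
oracleRidge <- function(X, y, lambda) {
  d <- ncol(X)
  solve(crossprod(X) + lambda * diag(d), crossprod(X, y))
}

# Random test channel with some vertical structure.
randomChannel <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w, 0, 100), h, w)
}

# A two-tone step image (sky value above the boundary row, ground below).
stepChannel <- function(h, w, boundary, top = 200, bottom = 20) {
  ch <- matrix(bottom, h, w)
  ch[seq_len(boundary), ] <- top
  ch
}

# Flat RGB HorizonImage wrapper around a single channel.
grayImage <- function(ch, id = "gray", class = "other", horizon = 0.5) {
  px <- array(rep(pmin(pmax(ch, 0), 255), 3), dim = c(dim(ch), 3))
  methods::new("HorizonImage", id = id, pixels = px, sceneClass = class,
               trueHorizon = horizon)
}

makeEstimateSet <- function(positions, id = "img",
                            dnk = rep(FALSE, length(positions))) {
  methods::new("EstimateSet", imageId = id, positions = positions,
               doNotKnow = dnk)
}

spikeDensity <- function(id, at = 0.55, h = 0.005, n = 12) {
  methods::new("GroundTruthDensity", imageId = id,
               samplePoints = rep(at, n), bandwidth = h)
}
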