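## Internal spatial-filtering primitives.
##
## All convolutions here use symmetric reflection padding (the edge row is
## mirrored, edge pixel included), chosen so that smoothing preserves the
## image mean closely and so the brute-force test oracles can reproduce the
## arithmetic bit-for-bit.

gaussianKernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Reflect-pad a matrix ('symmetric' style: edge row repeated mirrored).
padReflect <- function(x, top, bottom, left, right) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rev(seq_len(min(top, h))), seq_len(h),
          h + 1 - seq_len(min(bottom, h)))
  ## for pads longer than the image, keep reflecting
  while (length(ri) < h + top + bottom) {
    ri <- c(ri[1], ri, ri[length(ri)])
  }
  ci <- c(rev(seq_len(min(left, w))), seq_len(w),
          w + 1 - seq_len(min(right, w)))
  while (length(ci) < w + left + right) {
    ci <- c(ci[1], ci, ci[length(ci)])
  }
  x[ri, ci, drop = FALSE]
}

## 2-D cross-correlation with an odd-sized kernel, reflection boundary.
conv2Reflect <- function(x, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  xp <- padReflect(x, kr, kr, kc, kc)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * xp[i:(i + h - 1L), j:(j + w - 1L)]
    }
  }
  out
}

## Separable Gaussian smoothing; sigma = 0 is the identity.
smoothGaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussianKernel1d(sigma)
  x <- conv2Reflect(x, matrix(k, ncol = 1))     # vertical pass
  conv2Reflect(x, matrix(k, nrow = 1))          # horizontal pass
}

## Gabor quadrature pair. 'orientationDeg' is the direction of the carrier
## modulation: 90 modulates vertically, i.e. responds to horizontal
## structure. 'bandwidth' in octaves sets the envelope SD along the carrier;
## 'gamma' (spatial aspect ratio) shrinks the envelope across it, so small
## gamma gives elongated, orientation-selective kernels. The even kernel is
## recentred to zero mean so constant images yield zero response.
gaborKernel <- function(wavelength, bandwidth = 1, gamma = 0.5,
                        orientationDeg = 90, maxRadius = Inf) {
  stopifnot(wavelength > 0, bandwidth > 0, gamma > 0)
  slratio <- (1 / pi) * sqrt(log(2) / 2) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
  sigma <- slratio * wavelength
  r <- min(ceiling(2.5 * sigma / min(1, gamma)), maxRadius)
  th <- orientationDeg * pi / 180
  g <- expand.grid(dy = (-r):r, dx = (-r):r)
  u <- g$dx * cos(th) + g$dy * sin(th)     # along the carrier
  v <- -g$dx * sin(th) + g$dy * cos(th)    # across the carrier
  env <- exp(-(u^2 + gamma^2 * v^2) / (2 * sigma^2))
  even <- matrix(env * cos(2 * pi * u / wavelength), 2 * r + 1)
  odd <- matrix(env * sin(2 * pi * u / wavelength), 2 * r + 1)
  even <- even - mean(even)
  list(even = even, odd = odd, radius = r, sigma = sigma)
}

## Rasterize the segment (x0,y0)-(x1,y1) (1-based pixel coordinates) and
## return unique integer pixel indices inside an h x w raster. Plain
## single-pixel coverage: each crossed pixel counted once.
linePixels <- function(x0, y0, x1, y1, h, w) {
  n <- max(2L, ceiling(2 * max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- round(x0 + t * (x1 - x0))
  ys <- round(y0 + t * (y1 - y0))
  keep <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  if (!any(keep)) return(integer(0))
  unique((xs[keep] - 1L) * h + ys[keep])   # column-major linear index
}

## Bilinear resize of a matrix to hOut x wOut (pixel-center aligned).
resizeBilinear <- function(x, hOut, wOut) {
  h <- nrow(x); w <- ncol(x)
  sy <- (seq_len(hOut) - 0.5) * h / hOut + 0.5
  sx <- (seq_len(wOut) - 0.5) * w / wOut + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- x[y0, x0, drop = FALSE] * (1 - fy) + x[y1, x0, drop = FALSE] * fy
  b <- x[y0, x1, drop = FALSE] * (1 - fy) + x[y1, x1, drop = FALSE] * fy
  a * (1 - matrix(fx, hOut, wOut, byrow = TRUE)) +
    b * matrix(fx, hOut, wOut, byrow = TRUE)
}
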