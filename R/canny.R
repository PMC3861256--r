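## Canny edge detection and the Hough line transform, the front end of the
## vanishing-point estimator. Implemented here: no installed package
## provides them, and the voting chain is the substance of that estimator.

.sobelX <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
.sobelY <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then double-threshold hysteresis: pixels
#' above `high` seed edges which grow through 8-connected pixels above
#' `low`.
#'
#' @param channel numeric matrix (one L*a*b* channel).
#' @param sigma smoothing SD in pixels.
#' @param low,high gradient-magnitude thresholds, `low < high`.
#' @return list with logical matrix `edges` and numeric matrix `magnitude`.
#' @keywords internal
cannyEdges <- function(channel, sigma = 1.4, low = 2, high = 6) {
  stopifnot(low < high)
  s <- smoothGaussian(channel, sigma)
  gx <- conv2Reflect(s, .sobelX)
  gy <- conv2Reflect(s, .sobelY)
  mag <- sqrt(gx^2 + gy^2)
  h <- nrow(mag); w <- ncol(mag)
  ## quantize direction to 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  dy <- c(0L, 1L, 1L, 1L)[sector + 1L]
  dx <- c(1L, 1L, 0L, -1L)[sector + 1L]
  ri <- matrix(rep(seq_len(h), w), h, w)
  ci <- matrix(rep(seq_len(w), each = h), h, w)
  at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(0, h, w)
    v[ok] <- mag[cbind(r[ok], c[ok])]
    v
  }
  n1 <- at(ri + dy, ci + dx)
  n2 <- at(ri - dy, ci - dx)
  thin <- mag * (mag >= n1 & mag >= n2)
  ## hysteresis by iterated neighbor growth
  strong <- thin >= high
  weak <- thin >= low
  edges <- strong
  repeat {
    grown <- edges
    grown[-1, ] <- grown[-1, ] | edges[-h, ]
    grown[-h, ] <- grown[-h, ] | edges[-1, ]
    grown[, -1] <- grown[, -1] | edges[, -w]
    grown[, -w] <- grown[, -w] | edges[, -1]
    grown[-1, -1] <- grown[-1, -1] | edges[-h, -w]
    grown[-1, -w] <- grown[-1, -w] | edges[-h, -1]
    grown[-h, -1] <- grown[-h, -1] | edges[-1, -w]
    grown[-h, -w] <- grown[-h, -w] | edges[-1, -1]
    grown <- grown & weak
    grown <- grown | edges
    if (identical(grown, edges)) break
    edges <- grown
  }
  list(edges = edges, magnitude = mag)
}

#' Hough line transform with magnitude-weighted votes
#'
#' Lines are parameterized as `rho = x cos(theta) + y sin(theta)` with x the
#' column and y the row (1-based pixel centers), theta in [-90, 90) degrees
#' measured for the line normal. Each edge pixel votes with its gradient
#' magnitude, so a line's strength reflects both edge response and length.
#'
#' @param edges logical matrix of edge pixels.
#' @param weights numeric matrix of vote weights (gradient magnitudes).
#' @param rhoRes accumulator resolution in pixels.
#' @param thetaRes accumulator resolution in radians.
#' @return list with `accumulator` (rho x theta matrix), `rho`, `theta`
#'   (bin centers, radians).
#' @keywords internal
houghLines <- function(edges, weights, rhoRes = 1, thetaRes = pi / 180) {
  h <- nrow(edges); w <- ncol(edges)
  theta <- seq(-pi / 2, pi / 2 - thetaRes / 2, by = thetaRes)
  diag <- sqrt(h^2 + w^2)
  rho <- seq(-diag, diag, by = rhoRes)
  acc <- matrix(0, length(rho), length(theta))
  idx <- which(edges)
  if (!length(idx)) {
    return(list(accumulator = acc, rho = rho, theta = theta))
  }
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  wts <- weights[idx]
  for (j in seq_along(theta)) {
    r <- xs * cos(theta[j]) + ys * sin(theta[j])
    bin <- round((r - rho[1]) / rhoRes) + 1L
    ok <- bin >= 1L & bin <= length(rho)
    tab <- rowsum(wts[ok], bin[ok])
    acc[as.integer(rownames(tab)), j] <-
      acc[as.integer(rownames(tab)), j] + tab[, 1]
  }
  list(accumulator = acc, rho = rho, theta = theta)
}
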