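## Holistic pathway: spatial-envelope descriptor over all three L*a*b*
## channels and a cluster-weighted mixture of linear regressors trained by
## expectation-maximization. Unlike the per-row cues this returns a single
## horizon estimate directly.

#' Spatial-envelope (GIST-style) descriptor
#'
#' Each L*a*b* channel is resized to a square working resolution and passed
#' through a bank of oriented band-pass filters (log-Gabor transfer
#' functions applied in the frequency domain, one-sided so the complex
#' response magnitude is the local amplitude envelope; the DC bin is zeroed
#' so constant images give zero features). Response magnitudes are averaged
#' within each cell of a `grid x grid` partition and concatenated across
#' channels, scales and orientations; a constant 1 is appended for the
#' regression intercept.
#'
#' Orientation angles denote the direction of the carrier modulation:
#' orientation `pi/2` responds to horizontal structure (vertical
#' modulation). Scale s has center wavelength `4 * 2^(s-1)` pixels at the
#' working resolution.
#'
#' @param lab a [LabImage-class] (image at least 32 x 32 pixels).
#' @param scales number of scales S.
#' @param orientations number of orientations O.
#' @param grid cells per side G.
#' @param resizeTo square working resolution (pixels).
#' @return numeric vector of length `3 * S * O * G^2 + 1`, ordered
#'   channel-major (L, a, b), then scale, orientation, grid cell
#'   (row-major); names encode the structure.
#' @examples
#' img <- makeScene(sceneSpec("coast", 0.5, seed = 1))
#' g <- gistDescriptor(toLab(img), scales = 2, orientations = 4, grid = 2)
#' length(g)   # 3 * 2 * 4 * 4 + 1
#' @export
gistDescriptor <- function(lab, scales = 4L, orientations = 8L,
                           grid = 4L, resizeTo = 64L) {
  stopifnot(methods::is(lab, "LabImage"))
  d <- dim(lab@L)
  if (d[1] < 32L || d[2] < 32L) {
    stop("image must be at least 32 x 32 for the spatial envelope",
         call. = FALSE)
  }
  if (grid > min(d)) stop("'grid' larger than the image", call. = FALSE)
  n <- as.integer(resizeTo)
  bank <- gistBank(n, scales, orientations)
  cellId <- gistCells(n, grid)
  feats <- lapply(list(lab@L, lab@a, lab@b), function(ch) {
    x <- resizeBilinear(ch, n, n)
    Fx <- stats::fft(x)
    unlist(lapply(bank, function(G) {
      resp <- Mod(stats::fft(Fx * G, inverse = TRUE)) / (n * n)
      as.numeric(rowsum(as.numeric(resp), cellId) /
                   tabulate(cellId, nbins = grid * grid))
    }), use.names = FALSE)
  })
  v <- c(unlist(feats, use.names = FALSE), 1)
  names(v) <- c(sprintf("ch%d.s%d.o%d.c%d",
                        rep(1:3, each = scales * orientations * grid^2),
                        rep(rep(seq_len(scales),
                                each = orientations * grid^2), 3),
                        rep(rep(seq_len(orientations), each = grid^2),
                            3 * scales),
                        rep(seq_len(grid^2), 3 * scales * orientations)),
                "intercept")
  v
}

## One-sided log-Gabor transfer functions on an n x n frequency grid.
gistBank <- function(n, scales, orientations) {
  k <- c(0:(n %/% 2 - 1), -(n - n %/% 2):-1) / n
  fx <- matrix(rep(k, each = n), n, n)       # column frequency
  fy <- matrix(rep(k, n), n, n)              # row frequency
  fr <- sqrt(fx^2 + fy^2)
  fa <- atan2(fy, fx)
  sigmaOnF <- 0.65
  sigmaTheta <- 0.8 * pi / orientations
  out <- vector("list", scales * orientations)
  i <- 0L
  for (s in seq_len(scales)) {
    f0 <- 1 / (4 * 2^(s - 1))
    radial <- exp(-(log(pmax(fr, 1e-12) / f0))^2 / (2 * log(sigmaOnF)^2))
    radial[1, 1] <- 0                        # zero DC: zero-mean filters
    for (o in seq_len(orientations)) {
      theta <- (o - 1) * pi / orientations
      dth <- atan2(sin(fa - theta), cos(fa - theta))
      angular <- exp(-dth^2 / (2 * sigmaTheta^2))   # one-sided
      i <- i + 1L
      out[[i]] <- radial * angular
    }
  }
  out
}

## Grid-cell id (1..grid^2, row-major blocks) for each pixel of an n x n
## image, as a vector aligned with as.numeric() column-major order.
gistCells <- function(n, grid) {
  rows <- pmin(((seq_len(n) - 1L) * grid) %/% n + 1L, grid)
  cols <- rows
  as.integer(matrix(rows, n, n) + (matrix(cols, n, n, byrow = TRUE) - 1L) *
               grid)
}

#' Descriptors for a list of images
#'
#' @param images list of [HorizonImage-class] / [ConditionedImage-class].
#' @param ... passed to [gistDescriptor()].
#' @return matrix with one descriptor per row, rownames = image ids where
#'   available.
#' @export
gistDescriptors <- function(images, ...) {
  rows <- lapply(images, function(im) gistDescriptor(toLab(im), ...))
  m <- do.call(rbind, rows)
  ids <- vapply(images, function(im)
    if (methods::is(im, "HorizonImage")) imageId(im) else im@sourceId,
    character(1))
  rownames(m) <- ids
  m
}

#' Fit a mixture of linear regressors by EM
#'
#' Cluster-weighted model: each of K components owns a linear regressor
#' from the descriptor to the horizon position plus a diagonal Gaussian
#' "gate" in a PCA-reduced descriptor space. Responsibilities combine the
#' mixing prior, the gate density and the target likelihood under the
#' component's regressor; the M-step solves ridge-stabilized weighted least
#' squares (solved in dual form when descriptors outnumber samples). The
#' best of `nRestarts` seeded restarts by final log-likelihood is kept.
#'
#' @param descriptors matrix, one descriptor per row (intercept as last
#'   column, as produced by [gistDescriptor()]).
#' @param targets normalized horizon positions in [0, 1].
#' @param K component count (>= 1).
#' @param nRestarts number of EM restarts.
#' @param seed integer seed.
#' @param gateDim dimensionality of the PCA gating space (capped by data).
#' @param ridge ridge penalty of the M-step least squares.
#' @param maxIter,tol EM stopping rule.
#' @return a [RegressorMixture-class].
#' @export
fitMixture <- function(descriptors, targets, K = 4L, nRestarts = 3L,
                       seed = 1L, gateDim = 64L, ridge = 1e-6,
                       maxIter = 100L, tol = 1e-8) {
  X <- as.matrix(descriptors)
  y <- as.numeric(targets)
  n <- nrow(X); d <- ncol(X)
  if (K < 1L) stop("'K' must be >= 1", call. = FALSE)
  if (length(y) != n) stop("targets/descriptors length mismatch",
                           call. = FALSE)
  if (any(y < 0 | y > 1)) stop("targets must lie in [0, 1]", call. = FALSE)
  if (n < 2L * K) stop("need at least 2 training items per component",
                       call. = FALSE)
  X0 <- X[, -d, drop = FALSE]                 # descriptor minus intercept
  if (all(apply(X0, 2, function(c) length(unique(c)) == 1L))) {
    stop("degenerate training set: all descriptors identical",
         call. = FALSE)
  }
  ## PCA gating space, fitted on the training descriptors only
  ctr <- colMeans(X0)
  Xc <- sweep(X0, 2, ctr)
  p <- min(gateDim, n - 1L, ncol(X0))
  sv <- svd(Xc, nu = 0, nv = p)
  rot <- sv$v
  Z <- Xc %*% rot
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- tryCatch(
      emOneRun(X, y, Z, K, ridge, maxIter, tol,
               seed = childSeed(seed, "em", r)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("EM failed on every restart", call. = FALSE)
  methods::new("RegressorMixture", K = as.integer(K), coef = best$coef,
               noiseSd = best$noiseSd, prior = best$prior,
               gateMean = best$gateMean, gateSd = best$gateSd,
               pca = list(center = ctr, rotation = rot),
               logLik = best$logLik, trace = best$trace)
}

## One EM run from a seeded k-means initialization.
emOneRun <- function(X, y, Z, K, ridge, maxIter, tol, seed) {
  n <- nrow(X); d <- ncol(X); p <- ncol(Z)
  sdFloorGate <- 1e-4
  sdFloorNoise <- 1e-4
  R <- withSeed(seed, {
    grp <- if (K == 1L) rep(1L, n) else {
      km <- tryCatch(stats::kmeans(Z, centers = K, nstart = 1),
                     error = function(e) NULL)
      if (is.null(km)) sample(rep_len(seq_len(K), n)) else km$cluster
    }
    r0 <- matrix(0.05 / max(K - 1, 1), n, K)
    r0[cbind(seq_len(n), grp)] <- 0.95
    if (K == 1L) r0[] <- 1
    r0
  })
  coef <- matrix(0, d, K)
  gateMean <- matrix(0, p, K); gateSd <- matrix(1, p, K)
  noiseSd <- rep(0.1, K); prior <- rep(1 / K, K)
  trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    ## M-step
    nk <- colSums(R)
    prior <- pmax(nk, 1e-10) / sum(pmax(nk, 1e-10))
    for (k in seq_len(K)) {
      r <- R[, k]
      wk <- sum(r)
      gateMean[, k] <- colSums(Z * r) / wk
      gateSd[, k] <- pmax(sqrt(colSums(sweep(Z, 2, gateMean[, k])^2 * r) /
                                 wk), sdFloorGate)
      coef[, k] <- ridgeWLS(X, y, r, ridge)
      resid <- y - X %*% coef[, k]
      noiseSd[k] <- max(sqrt(sum(r * resid^2) / wk), sdFloorNoise)
    }
    ## E-step
    logR <- matrix(0, n, K)
    for (k in seq_len(K)) {
      gate <- gateLogDensity(Z, gateMean[, k], gateSd[, k])
      pred <- as.numeric(X %*% coef[, k])
      logR[, k] <- log(prior[k]) + gate +
        stats::dnorm(y, pred, noiseSd[k], log = TRUE)
    }
    m <- apply(logR, 1, max)
    lse <- m + log(rowSums(exp(logR - m)))
    R <- exp(logR - lse)
    llNew <- sum(lse)
    trace <- c(trace, llNew)
    if (is.finite(ll) && llNew - ll < tol * (1 + abs(llNew))) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  list(coef = coef, noiseSd = noiseSd, prior = prior, gateMean = gateMean,
       gateSd = gateSd, logLik = ll, trace = trace)
}

## Summed per-dimension log-density of a diagonal Gaussian gate.
gateLogDensity <- function(Z, mu, sd) {
  out <- numeric(nrow(Z))
  for (j in seq_len(ncol(Z))) {
    out <- out + stats::dnorm(Z[, j], mu[j], sd[j], log = TRUE)
  }
  out
}

## Ridge-stabilized weighted least squares; dual (kernel) form when the
## descriptor dimension exceeds the sample count.
ridgeWLS <- function(X, y, r, ridge) {
  n <- nrow(X); d <- ncol(X)
  sr <- sqrt(r)
  Xs <- X * sr
  ys <- y * sr
  if (d <= n) {
    as.numeric(solve(crossprod(Xs) + ridge * diag(d), crossprod(Xs, ys)))
  } else {
    a <- solve(tcrossprod(Xs) + ridge * diag(n), ys)
    as.numeric(crossprod(Xs, a))
  }
}

#' @describeIn predictHorizon responsibility-weighted sum of component
#'   predictions, gated by prior x PCA-space density, clamped to [0, 1]
#'   (attribute `clamped` flags out-of-range raw predictions).
#' @export
setMethod("predictHorizon", signature("RegressorMixture", "numeric"),
  function(object, descriptor) {
    p <- predictHorizon(object, matrix(descriptor, nrow = 1))
    out <- as.numeric(p)
    attr(out, "clamped") <- attr(p, "clamped")
    out
  })

#' @describeIn predictHorizon matrix method: one descriptor per row.
#' @export
setMethod("predictHorizon", signature("RegressorMixture", "matrix"),
  function(object, descriptor) {
    X <- descriptor
    d <- nrow(object@coef)
    if (ncol(X) != d) {
      stop(sprintf("descriptor has %d dims, mixture was trained on %d",
                   ncol(X), d), call. = FALSE)
    }
    Z <- sweep(X[, -d, drop = FALSE], 2, object@pca$center) %*%
      object@pca$rotation
    n <- nrow(X); K <- object@K
    logW <- matrix(0, n, K)
    for (k in seq_len(K)) {
      logW[, k] <- log(object@prior[k]) +
        gateLogDensity(Z, object@gateMean[, k], object@gateSd[, k])
    }
    m <- apply(logW, 1, max)
    W <- exp(logW - m)
    W <- W / rowSums(W)
    raw <- rowSums(W * (X %*% object@coef))
    out <- pmin(pmax(raw, 0), 1)
    attr(out, "clamped") <- raw < 0 | raw > 1
    out
  })
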