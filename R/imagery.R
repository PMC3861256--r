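## Image I/O, CIE L*a*b* decomposition, condition transforms and the
## coordinate algebra that makes estimates comparable between conditions.

#' Read / write a HorizonImage as PNG
#'
#' PNG round trips are lossless for 8-bit RGB. Grayscale files are promoted
#' to three identical channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @param id,sceneClass,trueHorizon metadata attached on read (PNG carries
#'   none); defaults: basename, "other", 0.5.
#' @return [readImagePNG()]: a [HorizonImage-class]; [writeImagePNG()]: the
#'   path, invisibly.
#' @export
readImagePNG <- function(path, id = NULL, sceneClass = "other",
                         trueHorizon = 0.5) {
  if (!file.exists(path) || file.info(path)$size == 0) {
    stop(sprintf("cannot read image file '%s'", path), call. = FALSE)
  }
  raw <- tryCatch(png::readPNG(path),
                  error = function(e) stop(sprintf(
                    "'%s' is not a readable PNG: %s", path,
                    conditionMessage(e)), call. = FALSE))
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))   # grayscale promotion
  } else if (dim(raw)[3] == 4L) {
    raw <- raw[, , 1:3, drop = FALSE]                 # drop alpha
  } else if (dim(raw)[3] == 2L) {
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  }
  if (dim(raw)[3] != 3L) {
    stop(sprintf("'%s' is not an RGB or grayscale image", path),
         call. = FALSE)
  }
  methods::new("HorizonImage", id = if (is.null(id))
    sub("\\.png$", "", basename(path)) else id,
    pixels = round(raw * 255), sceneClass = sceneClass,
    trueHorizon = trueHorizon)
}

#' @rdname readImagePNG
#' @param image a [HorizonImage-class] or [ConditionedImage-class].
#' @export
writeImagePNG <- function(image, path) {
  px <- pixels(image) / 255
  png::writePNG(px, path)
  invisible(path)
}

## sRGB (D65) -> XYZ matrix, IEC 61966-2-1.
.srgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041),
                    3, 3, byrow = TRUE)
.whiteD65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Convert an image to CIE 1976 L*a*b*
#'
#' Standard pipeline: 8-bit sRGB values are linearized (gamma expansion),
#' mapped to XYZ with the D65 primaries matrix, and converted to L*a*b*
#' against the D65 white point. L* spans [0, 100].
#'
#' @param image a [HorizonImage-class] or [ConditionedImage-class].
#' @return a [LabImage-class].
#' @examples
#' img <- makeScene(sceneSpec("coast", 0.5, seed = 1))
#' lab <- toLab(img)
#' range(lab@L)
#' @export
toLab <- function(image) {
  px <- pixels(image)
  d <- dim(px)
  v <- px / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  rgb <- matrix(lin, ncol = 3)                       # pixels x 3
  xyz <- rgb %*% t(.srgb2xyz)
  fx <- labF(xyz[, 1] / .whiteD65[1])
  fy <- labF(xyz[, 2] / .whiteD65[2])
  fz <- labF(xyz[, 3] / .whiteD65[3])
  methods::new("LabImage",
    L = matrix(116 * fy - 16, d[1], d[2]),
    a = matrix(500 * (fx - fy), d[1], d[2]),
    b = matrix(200 * (fy - fz), d[1], d[2]))
}

## CIE f() with the linear segment below (6/29)^3.
labF <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Extract one channel of a LabImage
#'
#' The single-cue estimators operate on exactly one channel at a time; this
#' is the only sanctioned way to hand them pixel data.
#'
#' @param lab a [LabImage-class].
#' @param channel "L", "a" or "b".
#' @return a numeric matrix.
#' @export
labChannel <- function(lab, channel = c("L", "a", "b")) {
  channel <- match.arg(channel)
  switch(channel, L = lab@L, a = lab@a, b = lab@b)
}

#' Apply one of the six stimulus conditions
#'
#' Conditions: `norm` (identity), `inverted` (vertical mirror), `blurred`
#' (Gaussian blur with SD `blurSigmaFraction * height`), and the subwindow
#' conditions `lower` / `middle` / `upper` that keep the lower, middle or
#' upper two thirds of the rows — removing `floor(H/3)` rows from the top,
#' `floor(H/6)` from top and bottom, or `floor(H/3)` from the bottom — and
#' then remove columns alternately from the left and right border (starting
#' side decided by a seeded coin flip) until the aspect ratio matches the
#' original within one column.
#'
#' The returned [ConditionedImage-class] carries the [CoordinateMap-class]
#' back to full-upright-image normalized coordinates.
#'
#' @param image a [HorizonImage-class].
#' @param condition one of [conditionNames()].
#' @param blurSigmaFraction blur SD as a fraction of image height (blurred
#'   condition only; scales with image size).
#' @param seed seed for the column-removal coin flip.
#' @return a [ConditionedImage-class].
#' @examples
#' img <- makeScene(sceneSpec("coast", 0.5, seed = 1))
#' ci <- applyCondition(img, "middle")
#' coordinateMap(ci)
#' @export
applyCondition <- function(image, condition, blurSigmaFraction = 0.01,
                           seed = 1L) {
  stopifnot(methods::is(image, "HorizonImage"))
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% .conditionNames) {
    stop("unknown condition '", paste(condition, collapse = ","),
         "'; must be one of: ", paste(.conditionNames, collapse = ", "),
         call. = FALSE)
  }
  px <- pixels(image)
  H <- dim(px)[1]; W <- dim(px)[2]
  idMap <- methods::new("CoordinateMap")
  if (condition == "norm") {
    out <- px; map <- idMap
  } else if (condition == "inverted") {
    out <- px[H:1, , , drop = FALSE]
    map <- methods::new("CoordinateMap", scale = 1, offset = 0, flip = TRUE)
  } else if (condition == "blurred") {
    sigma <- blurSigmaFraction * H
    out <- px
    for (k in 1:3) out[, , k] <- smoothGaussian(px[, , k], sigma)
    out <- pmin(pmax(out, 0), 255)
    map <- idMap
  } else {
    keep <- switch(condition,
      lower = (floor(H / 3) + 1):H,
      upper = 1:(H - floor(H / 3)),
      middle = (floor(H / 6) + 1):(H - floor(H / 6)))
    out <- px[keep, , , drop = FALSE]
    hKeep <- length(keep)
    targetW <- max(1L, round(W * hKeep / H))
    nRemove <- W - targetW
    colsKeep <- seq_len(W)
    if (nRemove > 0) {
      side <- withSeed(seed, stats::runif(1) < 0.5)   # TRUE: start right
      nRight <- if (side) ceiling(nRemove / 2) else floor(nRemove / 2)
      nLeft <- nRemove - nRight
      colsKeep <- (nLeft + 1L):(W - nRight)
    }
    out <- out[, colsKeep, , drop = FALSE]
    map <- methods::new("CoordinateMap", scale = hKeep / H,
                        offset = (keep[1] - 1) / H, flip = FALSE)
  }
  methods::new("ConditionedImage", pixels = out, condition = condition,
               map = map, sourceId = imageId(image))
}

#' Map window coordinates to full-image coordinates and back
#'
#' `toFullCoords` converts a normalized vertical position inside a
#' conditioned image window to the normalized coordinate system of the full
#' upright image (`offset + scale * y`, after mirroring when the map flips);
#' `toWindowCoords` is its inverse on the window's span. Outputs falling
#' outside [0, 1] are clamped and flagged via the `clamped` attribute.
#'
#' @param y normalized position(s) in [0, 1].
#' @param map a [CoordinateMap-class].
#' @return numeric position(s) with logical attribute `clamped`.
#' @examples
#' m <- methods::new("CoordinateMap", scale = 2 / 3, offset = 1 / 3,
#'                   flip = FALSE)
#' toFullCoords(c(0, 1), m)
#' @export
toFullCoords <- function(y, map) {
  stopifnot(methods::is(map, "CoordinateMap"))
  yw <- if (map@flip) 1 - y else y
  out <- map@offset + map@scale * yw
  clamped <- out < 0 | out > 1
  out <- pmin(pmax(out, 0), 1)
  attr(out, "clamped") <- clamped
  out
}

#' @rdname toFullCoords
#' @export
toWindowCoords <- function(y, map) {
  stopifnot(methods::is(map, "CoordinateMap"))
  out <- (y - map@offset) / map@scale
  if (map@flip) out <- 1 - out
  clamped <- out < 0 | out > 1
  out <- pmin(pmax(out, 0), 1)
  attr(out, "clamped") <- clamped
  out
}
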