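## Synthetic outdoor-scene generator.
##
## Scenes are rendered with an exactly known astronomical horizon so that
## every downstream component can be validated against construction: the
## sky/ground luminance split, occluder baselines and the intersection row
## of perspective line bundles all encode the same horizon. Recipes follow
## the per-class difficulty ordering seen in human raters: coastal scenes
## are clean two-tone splits (easiest), closed natural scenes bury the
## split under occluders, street/city scenes add converging line bundles.

.classDefaults <- data.frame(
  sceneClass = .sceneClasses,
  skyGroundContrast = c(1.0, 0.8, 0.5, 0.55, 0.75, 0.7, 0.7),
  occluderDensity   = c(0.0, 0.05, 0.75, 0.55, 0.10, 0.15, 0.2),
  nPerspectiveLines = c(0L, 0L, 0L, 0L, 4L, 8L, 2L),
  estimateSd        = c(0.01, 0.04, 0.04, 0.04, 0.02, 0.025, 0.03),
  stringsAsFactors = FALSE)

#' Default per-class spread of simulated human estimates
#'
#' Normalized-units standard deviations of the simulated raters per scene
#' class. The values are generator parameters chosen to reproduce the
#' ordering observed in human data — much tighter agreement on open coastal
#' scenes than on closed natural scene types, streets in between — not any
#' particular magnitudes.
#'
#' @return named numeric vector over [sceneClasses()].
#' @export
defaultEstimateSd <- function() {
  stats::setNames(.classDefaults$estimateSd, .classDefaults$sceneClass)
}

#' Specification of one synthetic scene
#'
#' @slot sceneClass one of [sceneClasses()].
#' @slot trueHorizon normalized position in [1/3, 2/3]; the corpus keeps
#'   horizons in the middle third of the image, mirroring the
#'   stimulus-selection rule.
#' @slot width,height image size in pixels.
#' @slot skyGroundContrast luminance contrast of the sky/ground split, [0,1].
#' @slot occluderDensity density of dark vertical occluders, [0,1].
#' @slot nPerspectiveLines count of lines converging on the horizon.
#' @slot textureNoiseSd pixel-noise SD in 8-bit intensity units.
#' @slot seed integer rendering seed.
#' @export
setClass("SceneSpec",
  representation(sceneClass = "character", trueHorizon = "numeric",
                 width = "integer", height = "integer",
                 skyGroundContrast = "numeric", occluderDensity = "numeric",
                 nPerspectiveLines = "integer", textureNoiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (!object@sceneClass %in% .sceneClasses)
      return(sprintf("unknown sceneClass '%s'", object@sceneClass))
    if (object@trueHorizon < 1 / 3 || object@trueHorizon > 2 / 3)
      return("'trueHorizon' must lie in [1/3, 2/3]")
    if (object@width < 16L || object@height < 16L)
      return("'width' and 'height' must be >= 16 pixels")
    if (object@skyGroundContrast < 0 || object@skyGroundContrast > 1)
      return("'skyGroundContrast' must lie in [0, 1]")
    if (object@occluderDensity < 0 || object@occluderDensity > 1)
      return("'occluderDensity' must lie in [0, 1]")
    if (object@nPerspectiveLines < 0L)
      return("'nPerspectiveLines' must be >= 0")
    TRUE
  })

#' Create a scene specification
#'
#' Unspecified rendering parameters default to the recipe of the scene
#' class (see package vignette for the recipes).
#'
#' @param sceneClass one of [sceneClasses()].
#' @param trueHorizon normalized vertical horizon position in [1/3, 2/3].
#' @param width,height image size in pixels (default 128 x 96, landscape).
#' @param skyGroundContrast,occluderDensity,nPerspectiveLines,textureNoiseSd
#'   recipe overrides; `NULL` takes the class default.
#' @param seed integer rendering seed.
#' @return a [SceneSpec-class].
#' @examples
#' sp <- sceneSpec("coast", trueHorizon = 0.5, seed = 1)
#' img <- makeScene(sp)
#' img
#' @export
sceneSpec <- function(sceneClass, trueHorizon = 0.5, width = 128L,
                      height = 96L, skyGroundContrast = NULL,
                      occluderDensity = NULL, nPerspectiveLines = NULL,
                      textureNoiseSd = 2, seed = 1L) {
  if (!is.character(sceneClass) || length(sceneClass) != 1L ||
      !sceneClass %in% .sceneClasses) {
    stop("'sceneClass' must be one of: ",
         paste(.sceneClasses, collapse = ", "), call. = FALSE)
  }
  assertScalarIn(width, "width", 1, Inf, integer = TRUE)
  assertScalarIn(height, "height", 1, Inf, integer = TRUE)
  d <- .classDefaults[.classDefaults$sceneClass == sceneClass, ]
  methods::new("SceneSpec",
    sceneClass = sceneClass, trueHorizon = trueHorizon,
    width = as.integer(width), height = as.integer(height),
    skyGroundContrast = if (is.null(skyGroundContrast))
      d$skyGroundContrast else skyGroundContrast,
    occluderDensity = if (is.null(occluderDensity))
      d$occluderDensity else occluderDensity,
    nPerspectiveLines = as.integer(if (is.null(nPerspectiveLines))
      d$nPerspectiveLines else nPerspectiveLines),
    textureNoiseSd = textureNoiseSd, seed = as.integer(seed))
}

#' Render a synthetic outdoor scene
#'
#' Deterministic for a fixed spec (including its seed). The first ground
#' row is row `floor(trueHorizon * height)` (0-based), so the sky-to-ground
#' luminance transition sits exactly at the specified horizon; perspective
#' lines are drawn through a vanishing point on that row; occluders are
#' darker strips crossing it.
#'
#' @param spec a [SceneSpec-class].
#' @param id image identifier (default derived from class and seed).
#' @return a [HorizonImage-class].
#' @export
makeScene <- function(spec, id = NULL) {
  stopifnot(methods::is(spec, "SceneSpec"))
  methods::validObject(spec)
  if (is.null(id)) id <- sprintf("%s_%06d", spec@sceneClass, spec@seed)
  H <- spec@height; W <- spec@width
  hr <- floor(spec@trueHorizon * H)       # 0-based first ground row
  ctr <- spec@skyGroundContrast
  withSeed(spec@seed, {
    lum <- matrix(0, H, W)
    skyRows <- seq_len(hr)                # 1-based rows above horizon
    gndRows <- (hr + 1):H
    ## sky: bright with a mild top-to-horizon gradient
    if (hr > 0) {
      grad <- if (hr > 1) (skyRows - 1) / (hr - 1) else 0
      lum[skyRows, ] <- 140 + ctr * (100 - 25 * grad)
    }
    ## ground: dark, with class texture
    gl <- 140 - ctr * 95
    lum[gndRows, ] <- gl
    if (spec@sceneClass == "open_country") {
      ## low-amplitude luminance undulation on the ground
      und <- 6 * sin(2 * pi * 3 * (seq_len(W) - 1) / W)
      lum[gndRows, ] <- lum[gndRows, ] +
        matrix(und, length(gndRows), W, byrow = TRUE)
    }
    ## pixel noise
    lum <- lum + matrix(stats::rnorm(H * W, 0, spec@textureNoiseSd), H, W)
    ## occluders: dark vertical strips crossing the horizon
    nOcc <- round(spec@occluderDensity * W / 6)
    if (nOcc > 0) {
      xs <- sample.int(W, nOcc, replace = TRUE)
      for (x in xs) {
        wOcc <- sample(2:4, 1)
        cols <- intersect(x:(x + wOcc - 1L), seq_len(W))
        top <- max(1L, hr - sample(seq_len(max(1L, floor(H / 5))), 1))
        lum[top:H, cols] <- 35 + stats::rnorm(length(top:H) * length(cols),
                                              0, spec@textureNoiseSd)
      }
    }
    ## perspective bundle: segments through the vanishing point on the
    ## horizon row, fanning to the bottom border
    if (spec@nPerspectiveLines > 0) {
      vx <- floor(W / 2) + 1L              # 1-based vanishing-point column
      vy <- hr + 1L                        # 1-based horizon row
      bx <- round(seq(1, W, length.out = spec@nPerspectiveLines))
      strength <- if (spec@sceneClass == "city") 25 else 45
      for (x1 in bx) {
        px <- linePixels(vx, vy, x1, H, H, W)
        lum[px] <- strength
      }
    }
    lum <- pmin(pmax(lum, 0), 255)
    ## colour: bluish sky, class-tinted ground
    r <- lum; g <- lum; b <- lum
    if (hr > 0) {
      r[skyRows, ] <- lum[skyRows, ] * 0.82
      g[skyRows, ] <- lum[skyRows, ] * 0.90
    }
    gtint <- switch(spec@sceneClass,
      coast = c(1.00, 0.92, 0.70),        # sandy
      city = c(0.95, 0.95, 0.95),         # grey
      non_urban_street = c(0.95, 0.92, 0.85),
      c(0.80, 1.00, 0.70))                # vegetated
    r[gndRows, ] <- lum[gndRows, ] * gtint[1]
    g[gndRows, ] <- lum[gndRows, ] * gtint[2]
    b[gndRows, ] <- lum[gndRows, ] * gtint[3]
    px <- array(0, dim = c(H, W, 3))
    px[, , 1] <- pmin(pmax(r, 0), 255)
    px[, , 2] <- pmin(pmax(g, 0), 255)
    px[, , 3] <- pmin(pmax(b, 0), 255)
    px <- round(px)                        # 8-bit quantization
    methods::new("HorizonImage", id = id, pixels = px,
                 sceneClass = spec@sceneClass,
                 trueHorizon = spec@trueHorizon)
  })
}

#' Simulate a set of human horizon estimates
#'
#' Each response is, with probability `1 - contamination`, a draw from a
#' Normal centred on the true horizon truncated (by rejection) to [0, 1];
#' otherwise a Uniform[0, 1] contaminant — a rater guessing blindly.
#'
#' @param trueHorizon normalized true horizon position.
#' @param sd normalized-units rater spread (>= 0).
#' @param n number of raters (>= 1; typically 12).
#' @param contamination per-draw contamination probability in [0, 1].
#' @param seed integer seed.
#' @param imageId id of the rated image (bookkeeping only).
#' @return an [EstimateSet-class] with all do-not-know flags FALSE.
#' @examples
#' es <- simulateEstimates(0.5, sd = 0.02, n = 12, seed = 7)
#' estimates(es)
#' @export
simulateEstimates <- function(trueHorizon, sd, n = 12L, contamination = 0,
                              seed = 1L, imageId = "") {
  assertScalarIn(trueHorizon, "trueHorizon", 0, 1)
  assertScalarIn(sd, "sd", 0, Inf)
  assertScalarIn(contamination, "contamination", 0, 1)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be >= 1: a density cannot be fitted to an empty set",
         call. = FALSE)
  }
  n <- as.integer(n)
  pos <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      if (stats::runif(1) < contamination) return(stats::runif(1))
      if (sd == 0) return(trueHorizon)
      repeat {
        y <- stats::rnorm(1, trueHorizon, sd)
        if (y >= 0 && y <= 1) return(y)
      }
    }, numeric(1))
  })
  methods::new("EstimateSet", imageId = imageId, positions = pos,
               doNotKnow = rep(FALSE, n))
}

#' Generate a synthetic corpus of scenes with simulated estimate sets
#'
#' Class counts follow `classMix` by largest-remainder rounding; the default
#' mix is proportional to the stimulus-set class counts
#' 32/29/18/46/16/47/12 over coast, open country, forest, enclosed nature,
#' non-urban street, city and other. Every image carries a simulated
#' estimate set whose spread is the class default ([defaultEstimateSd()]).
#'
#' @param nImages corpus size.
#' @param classMix named (or ordered as [sceneClasses()]) non-negative
#'   proportions summing to 1.
#' @param width,height image size in pixels.
#' @param seed integer master seed; all per-image seeds derive from it.
#' @param nEstimates raters per image (default 12).
#' @param contamination per-draw contamination probability of the simulated
#'   raters (default 0.02, a rare attentional lapse).
#' @param estimateSd named per-class rater spreads; default
#'   [defaultEstimateSd()].
#' @return a list with one element per image: `list(image = HorizonImage,
#'   estimates = EstimateSet)`, named by image id.
#' @examples
#' corpus <- makeCorpus(7, classMix = rep(1 / 7, 7), seed = 1)
#' vapply(corpus, function(x) sceneClass(x$image), character(1))
#' @export
makeCorpus <- function(nImages, classMix = NULL, width = 128L,
                       height = 96L, seed = 1L, nEstimates = 12L,
                       contamination = 0.02, estimateSd = NULL) {
  assertScalarIn(nImages, "nImages", 1, Inf, integer = TRUE)
  if (is.null(classMix)) {
    classMix <- c(32, 29, 18, 46, 16, 47, 12) / 200
  }
  if (length(classMix) != length(.sceneClasses)) {
    stop("'classMix' must give one proportion per scene class",
         call. = FALSE)
  }
  if (!is.null(names(classMix))) classMix <- classMix[.sceneClasses]
  if (any(classMix < 0) || abs(sum(classMix) - 1) > 1e-9) {
    stop("'classMix' proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (nImages < sum(classMix > 0)) {
    stop("'nImages' is smaller than the number of classes with nonzero ",
         "proportion", call. = FALSE)
  }
  if (is.null(estimateSd)) estimateSd <- defaultEstimateSd()
  counts <- largestRemainder(nImages, classMix)
  classes <- rep(.sceneClasses, counts)
  horizons <- withSeed(childSeed(seed, "horizons"),
                       stats::runif(nImages, 1 / 3, 2 / 3))
  out <- vector("list", nImages)
  ids <- character(nImages)
  for (i in seq_len(nImages)) {
    cl <- classes[i]
    sp <- sceneSpec(cl, trueHorizon = horizons[i], width = width,
                    height = height, seed = childSeed(seed, "scene", i))
    id <- sprintf("img%04d_%s", i, cl)
    img <- makeScene(sp, id = id)
    es <- simulateEstimates(horizons[i], sd = estimateSd[[cl]],
                            n = nEstimates, contamination = contamination,
                            seed = childSeed(seed, "est", i), imageId = id)
    ids[i] <- id
    out[[i]] <- list(image = img, estimates = es)
  }
  names(out) <- ids
  out
}

#' Write a corpus to disk as PNGs plus CSV manifests
#'
#' Emits one PNG per image, `manifest.csv` (id, path, scene_class,
#' true_horizon) and `estimates.csv` (image_id, rater_index, position,
#' do_not_know).
#'
#' @param corpus output of [makeCorpus()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
writeCorpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- do.call(rbind, lapply(corpus, function(x) {
    img <- x$image
    path <- file.path(dir, paste0(imageId(img), ".png"))
    writeImagePNG(img, path)
    data.frame(id = imageId(img), path = path,
               scene_class = sceneClass(img),
               true_horizon = trueHorizon(img),
               stringsAsFactors = FALSE)
  }))
  est <- do.call(rbind, lapply(corpus, function(x) {
    es <- x$estimates
    data.frame(image_id = imageId(es),
               rater_index = seq_along(es@positions),
               position = es@positions, do_not_know = es@doNotKnow,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(est, file.path(dir, "estimates.csv"), row.names = FALSE)
  invisible(man)
}
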