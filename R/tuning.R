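## Stratified fold construction and per-fold hyperparameter search.
##
## The training objective is the one the evaluation uses: the value of the
## image's ground-truth density at the estimated position ("confidence"),
## averaged over the training images. Search is an extensive seeded random
## search followed by Nelder-Mead refinement from the best points; for the
## holistic regressor every parameter evaluation wraps an inner 3-fold
## cross-validation (evaluating it requires training); the dummy baselines
## are averaged over 10 seeded runs.

#' FoldPartition: stratified assignment of images to folds
#'
#' @slot assignments named integer vector, image id -> fold (1..k).
#' @slot k fold count.
#' @slot report data.frame with per-fold class proportions and mean peak
#'   density.
#' @slot objective final value of the stratification objective.
#' @export
setClass("FoldPartition",
  representation(assignments = "integer", k = "integer",
                 report = "data.frame", objective = "numeric"),
  validity = function(object) {
    sizes <- tabulate(object@assignments, nbins = object@k)
    if (max(sizes) - min(sizes) > 1L)
      return("fold sizes must differ by at most 1")
    TRUE
  })

setMethod("show", "FoldPartition", function(object) {
  cat(sprintf("FoldPartition: %d images in %d folds (J = %.4f)\n",
              length(object@assignments), object@k, object@objective))
})

#' TuneResult: per-fold optimal parameters
#'
#' @slot algorithm,channel what was tuned.
#' @slot perFold list of length k: each `list(params, objective, nEval,
#'   trainingIds, seed)`.
#' @export
setClass("TuneResult",
  representation(algorithm = "character", channel = "character",
                 perFold = "list"))

setMethod("show", "TuneResult", function(object) {
  objs <- vapply(object@perFold, `[[`, numeric(1), "objective")
  cat(sprintf("TuneResult [%s/%s]: %d folds, objectives %.3f..%.3f\n",
              object@algorithm, object@channel, length(object@perFold),
              min(objs), max(objs)))
})

## Peak ground-truth density per image, evaluated on a fine grid.
peakDensity <- function(density, gridN = 401L) {
  g <- seq(0, 1, length.out = gridN)
  max(confidence(density, g))
}

#' Stratified k-fold partition of a corpus
#'
#' Starts from a seeded random equal-size split and hill-climbs by pairwise
#' swaps, minimizing the sum over folds of (a) the L1 deviation of the
#' fold's class proportions from the global proportions and (b) the
#' absolute deviation of the fold's mean peak ground-truth density from the
#' global mean, the latter standardized by the global SD of peak densities
#' so both terms are unitless and equally weighted. Swaps that do not
#' decrease the objective are rejected, so the objective is monotone
#' non-increasing.
#'
#' @param corpus output of [makeCorpus()] (or any list of
#'   `list(image=, estimates=)`).
#' @param densities named list of [GroundTruthDensity-class], one per
#'   image id.
#' @param k fold count (>= 2).
#' @param seed integer seed.
#' @param nIterations number of candidate swaps.
#' @return a [FoldPartition-class].
#' @export
stratifiedFolds <- function(corpus, densities, k = 10L, seed = 1L,
                            nIterations = 5000L) {
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  n <- length(corpus)
  if (n < k) stop("corpus smaller than the fold count", call. = FALSE)
  ids <- names(corpus)
  cls <- vapply(corpus, function(x) sceneClass(x$image), character(1))
  peaks <- vapply(ids, function(id) peakDensity(densities[[id]]),
                  numeric(1))
  pGlobal <- table(factor(cls, levels = .sceneClasses)) / n
  mGlobal <- mean(peaks)
  sGlobal <- stats::sd(peaks)
  if (!is.finite(sGlobal) || sGlobal == 0) sGlobal <- 1
  Jof <- function(assign) {
    J <- 0
    for (f in seq_len(k)) {
      in_f <- assign == f
      pf <- table(factor(cls[in_f], levels = .sceneClasses)) / sum(in_f)
      J <- J + sum(abs(pf - pGlobal)) +
        abs(mean(peaks[in_f]) - mGlobal) / sGlobal
    }
    J
  }
  withSeed(seed, {
    assign <- sample(rep_len(seq_len(k), n))
    J <- Jof(assign)
    for (it in seq_len(nIterations)) {
      pair <- sample.int(n, 2L)
      if (assign[pair[1]] == assign[pair[2]]) next
      cand <- assign
      cand[pair[1]] <- assign[pair[2]]
      cand[pair[2]] <- assign[pair[1]]
      Jc <- Jof(cand)
      if (Jc < J) {
        assign <- cand
        J <- Jc
      }
    }
    rep_list <- lapply(seq_len(k), function(f) {
      in_f <- assign == f
      data.frame(fold = f, n = sum(in_f),
                 meanPeakDensity = mean(peaks[in_f]),
                 t(as.numeric(table(factor(cls[in_f],
                                           levels = .sceneClasses)) /
                                sum(in_f))))
    })
    report <- do.call(rbind, rep_list)
    names(report)[4:10] <- .sceneClasses
    methods::new("FoldPartition",
                 assignments = stats::setNames(as.integer(assign), ids),
                 k = as.integer(k), report = report, objective = J)
  })
}

#' Searchable parameter space
#'
#' @param ... one or more `list(name=, lower=, upper=, log=, integer=)`
#'   entries (log and integer default FALSE).
#' @return a data.frame with class "ParamSpace".
#' @export
paramSpace <- function(...) {
  rows <- lapply(list(...), function(p) {
    stopifnot(!is.null(p$name), p$lower < p$upper)
    data.frame(name = p$name, lower = p$lower, upper = p$upper,
               log = isTRUE(p$log), integer = isTRUE(p$integer),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ParamSpace", "data.frame")
  out
}

#' Default search space per algorithm
#'
#' @param algorithm one of [algorithmNames()].
#' @return a ParamSpace data.frame.
#' @export
defaultParamSpace <- function(algorithm) {
  if (identical(algorithm, "-div")) algorithm <- "ndiv"
  switch(algorithm,
    div = ,
    ndiv = paramSpace(
      list(name = "smoothingSigma", lower = 0.3, upper = 5, log = TRUE),
      list(name = "localWeight", lower = 0, upper = 1)),
    lin = paramSpace(
      list(name = "smoothingSigma", lower = 0.3, upper = 5, log = TRUE)),
    gab = paramSpace(
      list(name = "wavelength", lower = 4, upper = 24, log = TRUE),
      list(name = "bandwidth", lower = 0.5, upper = 2),
      list(name = "selectivity", lower = 0.2, upper = 1)),
    van = paramSpace(
      list(name = "cannySigma", lower = 0.8, upper = 2.5),
      list(name = "cannyLow", lower = 0.5, upper = 4, log = TRUE),
      list(name = "cannyRatio", lower = 1.5, upper = 4),
      list(name = "nLines", lower = 5, upper = 40, integer = TRUE),
      list(name = "exponentRho", lower = 1, upper = 4)),
    gst = paramSpace(
      list(name = "K", lower = 1, upper = 6, integer = TRUE),
      list(name = "gateDim", lower = 2, upper = 32, integer = TRUE,
           log = TRUE)),
    dum1 = paramSpace(
      list(name = "center", lower = 0, upper = 1),
      list(name = "halfWidth", lower = 0.01, upper = 0.5)),
    dum2 = paramSpace(
      list(name = "mean", lower = 0, upper = 1),
      list(name = "sd", lower = 0.005, upper = 0.3, log = TRUE)),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
}

## Uniform / log-uniform seeded draws from a ParamSpace.
sampleParams <- function(space, n, seed) {
  withSeed(seed, {
    draws <- lapply(seq_len(nrow(space)), function(i) {
      s <- space[i, ]
      v <- if (s$log) {
        exp(stats::runif(n, log(s$lower), log(s$upper)))
      } else {
        stats::runif(n, s$lower, s$upper)
      }
      if (s$integer) round(v) else v
    })
    m <- do.call(cbind, draws)
    colnames(m) <- space$name
    m
  })
}

## Translate a named numeric vector from the search space into the
## parameter list the estimator expects.
vectorToParams <- function(algorithm, v) {
  v <- as.list(v)
  switch(algorithm,
    div = ,
    ndiv = divParams(v$smoothingSigma, min(max(v$localWeight, 0), 1)),
    lin = list(smoothingSigma = max(v$smoothingSigma, 0)),
    gab = gaborParams(v$wavelength, v$bandwidth, v$selectivity),
    van = vanParams(cannySigma = v$cannySigma, cannyLow = v$cannyLow,
                    cannyHigh = v$cannyLow * v$cannyRatio,
                    nLines = max(1, round(v$nLines)),
                    exponentRho = max(1, v$exponentRho)),
    gst = list(K = max(1L, as.integer(round(v$K))),
               gateDim = max(2L, as.integer(round(v$gateDim)))),
    dum1 = dummyParams("uniform", center = min(max(v$center, 0), 1),
                       halfWidth = max(v$halfWidth, 0)),
    dum2 = dummyParams("normal", mean = min(max(v$mean, 0), 1),
                       sd = max(v$sd, 1e-4)),
    stop("unknown algorithm", call. = FALSE))
}

## Precompute one channel matrix per image (norm condition pixels).
corpusChannels <- function(corpus, channel) {
  lapply(corpus, function(x) labChannel(toLab(x$image), channel))
}

#' Training objective: mean confidence at the estimated position
#'
#' Mean over images of the ground-truth density evaluated at the
#' winner-takes-all readout of the algorithm's profile (for the holistic
#' regressor, at its prediction under an inner 3-fold cross-validation; for
#' the dummies, at the random guess). An estimator failure on an image
#' contributes 0 and is logged as a warning.
#'
#' @param algorithm one of [algorithmNames()].
#' @param channel "L", "a" or "b" (ignored by "gst" and the dummies).
#' @param params parameter list (see [estimatorParams] /
#'   [vectorToParams()] internals); for "gst", `list(K=, gateDim=)`.
#' @param images list of [HorizonImage-class] (or corpus entries).
#' @param densities named list of [GroundTruthDensity-class] keyed by
#'   image id.
#' @param channels optional precomputed list of channel matrices (same
#'   order as `images`), avoiding repeated L*a*b* conversion during search.
#' @param descriptors optional precomputed descriptor matrix for "gst"
#'   (rows named by image id).
#' @param seed seed for the stochastic algorithms.
#' @param innerFolds inner CV folds for "gst".
#' @return mean confidence (a density value).
#' @export
objectiveConfidence <- function(algorithm, channel, params, images,
                                densities, channels = NULL,
                                descriptors = NULL, seed = 1L,
                                innerFolds = 3L) {
  images <- lapply(images, function(x) if (is.list(x)) x$image else x)
  ids <- vapply(images, imageId, character(1))
  if (algorithm %in% c("dum1", "dum2")) {
    est <- dummyEstimate(params, seed = seed, n = length(images))
    confs <- vapply(seq_along(images), function(i)
      confidence(densities[[ids[i]]], est[i]), numeric(1))
    return(mean(confs))
  }
  if (algorithm == "gst") {
    return(gstInnerCV(params, images, densities, descriptors, seed,
                      innerFolds))
  }
  if (is.null(channels)) {
    channels <- lapply(images, function(im) labChannel(toLab(im), channel))
  }
  confs <- vapply(seq_along(images), function(i) {
    est <- tryCatch(
      winnerTakesAll(confidenceProfile(algorithm, channels[[i]], params)),
      error = function(e) {
        warning(sprintf("estimator failed on '%s': %s", ids[i],
                        conditionMessage(e)))
        NA_real_
      })
    if (is.na(est)) 0 else confidence(densities[[ids[i]]], est)
  }, numeric(1))
  mean(confs)
}

## Inner cross-validation for the holistic regressor: train on
## (innerFolds-1)/innerFolds of the images, score confidences on the rest.
gstInnerCV <- function(params, images, densities, descriptors, seed,
                       innerFolds = 3L) {
  ids <- vapply(images, imageId, character(1))
  if (is.null(descriptors)) descriptors <- gistDescriptors(images)
  X <- descriptors[ids, , drop = FALSE]
  y <- vapply(ids, function(id) mean(samplePoints(densities[[id]])),
              numeric(1))
  n <- length(ids)
  fold <- withSeed(childSeed(seed, "gstcv"),
                   sample(rep_len(seq_len(innerFolds), n)))
  confs <- numeric(n)
  for (f in seq_len(innerFolds)) {
    tr <- fold != f
    fit <- tryCatch(
      fitMixture(X[tr, , drop = FALSE], y[tr], K = params$K,
                 nRestarts = 2L, gateDim = params$gateDim,
                 seed = childSeed(seed, "gstfit", f)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pred <- predictHorizon(fit, X[!tr, , drop = FALSE])
    confs[!tr] <- vapply(seq_along(pred), function(j)
      confidence(densities[[ids[!tr][j]]], pred[j]), numeric(1))
  }
  mean(confs)
}

#' Tune an algorithm per fold by random search + Nelder-Mead
#'
#' For each fold f, the objective is evaluated on the union of the other
#' folds (fold f's training set, in the normal condition): `nRandom` seeded
#' uniform / log-uniform draws from the space, then Nelder-Mead refinement
#' from the `nRefineStarts` best draws (integer parameters are relaxed
#' during refinement and rounded at evaluation). Dummy objectives are
#' averaged over 10 seeded runs. The recorded best never falls below the
#' best random draw.
#'
#' @param algorithm,channel what to tune.
#' @param corpus output of [makeCorpus()].
#' @param densities named list of ground-truth densities.
#' @param folds a [FoldPartition-class] over the corpus.
#' @param space a ParamSpace; default [defaultParamSpace()].
#' @param budget list with `nRandom`, `nRefineStarts`, `refineMaxIter`.
#' @param seed integer seed.
#' @return a [TuneResult-class].
#' @export
tuneAlgorithm <- function(algorithm, channel, corpus, densities, folds,
                          space = defaultParamSpace(algorithm),
                          budget = list(nRandom = 500, nRefineStarts = 3,
                                        refineMaxIter = 200),
                          seed = 1L) {
  if (identical(algorithm, "-div")) algorithm <- "ndiv"
  stopifnot(algorithm %in% .algorithmNames)
  if (is.null(space) || nrow(space) == 0) {
    stop("empty parameter space", call. = FALSE)
  }
  if (is.null(budget$nRandom) || budget$nRandom < 1) {
    stop("budget$nRandom must be >= 1", call. = FALSE)
  }
  ids <- names(corpus)
  images <- lapply(corpus, `[[`, "image")
  perRow <- algorithm %in% c("div", "ndiv", "lin", "gab", "van")
  channels <- if (perRow) corpusChannels(corpus, channel) else NULL
  descr <- if (algorithm == "gst") gistDescriptors(images) else NULL
  evalObjective <- function(v, trainIdx, evalSeed) {
    params <- tryCatch(vectorToParams(algorithm, v),
                       error = function(e) NULL)
    if (is.null(params)) return(-Inf)
    run1 <- function(s) {
      tryCatch(suppressWarnings(objectiveConfidence(
        algorithm, channel, params, images[trainIdx], densities,
        channels = channels[trainIdx],
        descriptors = descr, seed = s)),
        error = function(e) -Inf)
    }
    if (algorithm %in% c("dum1", "dum2")) {
      mean(vapply(1:10, function(r) run1(childSeed(evalSeed, "rep", r)),
                  numeric(1)))
    } else {
      run1(evalSeed)
    }
  }
  perFold <- lapply(seq_len(folds@k), function(f) {
    trainIdx <- which(folds@assignments != f)
    foldSeed <- childSeed(seed, "fold", f)
    cand <- sampleParams(space, budget$nRandom, foldSeed)
    objs <- vapply(seq_len(nrow(cand)), function(i)
      evalObjective(cand[i, ], trainIdx, childSeed(foldSeed, "eval", i)),
      numeric(1))
    nEval <- nrow(cand)
    bestI <- which.max(objs)
    best <- list(v = cand[bestI, ], objective = objs[bestI])
    nStarts <- min(budget$nRefineStarts %||% 0,
                   sum(is.finite(objs) & objs > -Inf))
    if (nStarts > 0) {
      starts <- order(objs, decreasing = TRUE)[seq_len(nStarts)]
      refineSeed <- childSeed(foldSeed, "refine")
      for (sI in starts) {
        res <- tryCatch(suppressWarnings(stats::optim(
          par = cand[sI, ],
          fn = function(v) {
            v <- pmin(pmax(v, space$lower), space$upper)
            -evalObjective(v, trainIdx, refineSeed)
          },
          method = "Nelder-Mead",
          control = list(maxit = budget$refineMaxIter %||% 200))),
          error = function(e) NULL)
        if (!is.null(res)) {
          nEval <- nEval + res$counts[1]
          v <- pmin(pmax(res$par, space$lower), space$upper)
          obj <- evalObjective(v, trainIdx, childSeed(foldSeed, "final",
                                                      sI))
          if (obj > best$objective) best <- list(v = v, objective = obj)
        }
      }
    }
    vBest <- best$v
    vBest[space$integer] <- round(vBest[space$integer])
    list(params = vectorToParams(algorithm, vBest),
         paramVector = stats::setNames(as.numeric(vBest), space$name),
         objective = best$objective, nEval = as.integer(nEval),
         trainingIds = ids[trainIdx], seed = foldSeed)
  })
  methods::new("TuneResult", algorithm = algorithm, channel = channel,
               perFold = perFold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated test confidences
#'
#' Scores every image exactly once, using the parameter set tuned without
#' its fold. The `condition` transform is applied before estimation and the
#' estimate is mapped back to full-image normalized coordinates before the
#' full-image ground-truth density is evaluated at it.
#'
#' @param algorithm,channel what to evaluate.
#' @param corpus,densities the corpus and its ground-truth densities.
#' @param folds the [FoldPartition-class] used for tuning.
#' @param tuneResult the matching [TuneResult-class].
#' @param condition one of [conditionNames()] (default "norm").
#' @param blurSigmaFraction blur SD fraction for the blurred condition.
#' @param seed seed for stochastic algorithms and column removal.
#' @return data.frame (image_id, algorithm, channel, condition, fold,
#'   position, confidence).
#' @export
crossValidate <- function(algorithm, channel, corpus, densities, folds,
                          tuneResult, condition = "norm",
                          blurSigmaFraction = 0.01, seed = 1L) {
  if (identical(algorithm, "-div")) algorithm <- "ndiv"
  if (length(tuneResult@perFold) != folds@k) {
    stop("tune result does not cover all folds", call. = FALSE)
  }
  ids <- names(corpus)
  perRow <- algorithm %in% c("div", "ndiv", "lin", "gab", "van")
  descr <- NULL
  gstFits <- NULL
  if (algorithm == "gst") {
    images <- lapply(corpus, `[[`, "image")
    descr <- gistDescriptors(images)
    gstFits <- lapply(seq_len(folds@k), function(f)
      gstFoldFit(tuneResult@perFold[[f]], descr, densities,
                 seed = childSeed(seed, "gstfold", f)))
  }
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    f <- folds@assignments[[id]]
    pf <- tuneResult@perFold[[f]]
    ci <- applyCondition(corpus[[i]]$image, condition,
                         blurSigmaFraction = blurSigmaFraction,
                         seed = childSeed(seed, "cols", i))
    pos <- if (perRow) {
      ch <- labChannel(toLab(ci), channel)
      winnerTakesAll(confidenceProfile(algorithm, ch, pf$params))
    } else if (algorithm %in% c("dum1", "dum2")) {
      dummyEstimate(pf$params, seed = childSeed(seed, "dummy", i))
    } else {
      dsc <- gistDescriptor(toLab(ci))
      as.numeric(predictHorizon(gstFits[[f]], dsc))
    }
    posFull <- as.numeric(toFullCoords(pos, coordinateMap(ci)))
    data.frame(image_id = id, algorithm = algorithm, channel = channel,
               condition = condition, fold = f, position = posFull,
               confidence = confidence(densities[[id]], posFull),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Final per-fold regressor: trained on the full training set of the fold
## with the tuned parameters.
gstFoldFit <- function(pf, descriptors, densities, seed) {
  trIds <- pf$trainingIds
  y <- vapply(trIds, function(id) mean(samplePoints(densities[[id]])),
              numeric(1))
  fitMixture(descriptors[trIds, , drop = FALSE], y, K = pf$params$K,
             gateDim = pf$params$gateDim, nRestarts = 2L, seed = seed)
}
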