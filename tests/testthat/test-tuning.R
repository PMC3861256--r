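twoClassCorpus <- function(n, seed) {
  makeCorpus(n, classMix = c(0.5, 0, 0, 0, 0, 0.5, 0), seed = seed,
             width = 32L, height = 32L, nEstimates = 4L)
}

equalDensities <- function(corpus, at = 0.5) {
  dens <- lapply(names(corpus), spikeDensity, at = at)
  names(dens) <- names(corpus)
  dens
}

test_that("stratified folds balance sizes and classes", {
  corpus <- twoClassCorpus(20, seed = 50)
  dens <- equalDensities(corpus)
  folds <- stratifiedFolds(corpus, dens, k = 2, seed = 1,
                           nIterations = 500)
  sizes <- table(folds@assignments)
  expect_identical(as.integer(sizes), c(10L, 10L))
  # exhaustively optimal split: 5 of each class per fold (J = 0, since the
  # density term vanishes for identical densities)
  cls <- vapply(corpus, function(x) sceneClass(x$image), character(1))
  for (f in 1:2) {
    expect_identical(as.integer(table(cls[folds@assignments == f])),
                     c(5L, 5L))
  }
  expect_equal(folds@objective, 0, tolerance = 1e-12)
  expect_error(stratifiedFolds(corpus, dens, k = 1), "k")
  # determinism
  folds2 <- stratifiedFolds(corpus, dens, k = 2, seed = 1,
                            nIterations = 500)
  expect_identical(folds@assignments, folds2@assignments)
})

test_that("the objective is the mean density at the estimate", {
  corpus <- twoClassCorpus(2, seed = 51)
  ids <- names(corpus)
  # forced estimate at the spike: objective equals the spike height
  dens <- equalDensities(corpus[1], at = 0.5)
  obj <- objectiveConfidence("dum2", "L",
                             dummyParams("normal", mean = 0.5, sd = 0),
                             corpus[1], dens)
  expect_equal(obj, 1 / (0.005 * sqrt(2 * pi)), tolerance = 1e-9)
  # estimates many bandwidths from every kernel score essentially zero
  densFar <- equalDensities(corpus, at = 0.3)
  objFar <- objectiveConfidence("dum2", "L",
                                dummyParams("normal", mean = 1, sd = 0),
                                corpus, densFar)
  expect_lt(objFar, 1e-10)
  # two hand-set densities: objective is the arithmetic mean of the two
  d1 <- spikeDensity(ids[1], at = 0.4, h = 0.01)
  d2 <- spikeDensity(ids[2], at = 0.6, h = 0.02)
  dens2 <- list(d1, d2); names(dens2) <- ids
  objMean <- objectiveConfidence("dum2", "L",
                                 dummyParams("normal", mean = 0.5, sd = 0),
                                 corpus, dens2)
  expect_equal(objMean, mean(c(confidence(d1, 0.5), confidence(d2, 0.5))),
               tolerance = 1e-12)
})

test_that("tuning the normal dummy recovers a planted density peak", {
  corpus <- twoClassCorpus(16, seed = 52)
  dens <- equalDensities(corpus, at = 0.55)
  folds <- stratifiedFolds(corpus, dens, k = 2, seed = 2,
                           nIterations = 200)
  tr <- tuneAlgorithm("dum2", "L", corpus, dens, folds,
                      budget = list(nRandom = 60, nRefineStarts = 2,
                                    refineMaxIter = 80), seed = 3)
  # grid-search oracle: the objective's unique maximizer over the mean
  grid <- seq(0, 1, by = 0.005)
  gridObj <- vapply(grid, function(m)
    confidence(dens[[1]], m), numeric(1))
  oracleMean <- grid[which.max(gridObj)]
  expect_equal(oracleMean, 0.55)
  for (p in tr@perFold) {
    expect_lt(abs(p$params$mean - oracleMean), 0.01)
    expect_equal(p$params$sd, 0.005)    # lower bound of the search space
  }
})

test_that("tuning budgets are accounted and refinement never hurts", {
  corpus <- twoClassCorpus(8, seed = 53)
  dens <- equalDensities(corpus, at = 0.5)
  folds <- stratifiedFolds(corpus, dens, k = 2, seed = 4,
                           nIterations = 50)
  tiny <- tuneAlgorithm("dum2", "L", corpus, dens, folds,
                        budget = list(nRandom = 1, nRefineStarts = 0),
                        seed = 5)
  expect_length(tiny@perFold, 2L)
  for (p in tiny@perFold) expect_identical(p$nEval, 1L)
  # same random draws, with refinement on top: never worse
  base <- tuneAlgorithm("lin", "L", corpus, dens, folds,
                        budget = list(nRandom = 4, nRefineStarts = 0),
                        seed = 6)
  refined <- tuneAlgorithm("lin", "L", corpus, dens, folds,
                           budget = list(nRandom = 4, nRefineStarts = 1,
                                         refineMaxIter = 30), seed = 6)
  for (f in 1:2) {
    expect_gte(refined@perFold[[f]]$objective,
               base@perFold[[f]]$objective - 1e-12)
  }
  expect_error(tuneAlgorithm("lin", "L", corpus, dens, folds,
                             space = NULL), "empty parameter space")
  # reproducibility of the full trace
  again <- tuneAlgorithm("lin", "L", corpus, dens, folds,
                         budget = list(nRandom = 4, nRefineStarts = 0),
                         seed = 6)
  expect_identical(lapply(base@perFold, `[[`, "paramVector"),
                   lapply(again@perFold, `[[`, "paramVector"))
})

test_that("cross-validation scores each image once without leakage", {
  corpus <- twoClassCorpus(12, seed = 54)
  dens <- lapply(corpus, function(x)
    fitDensity(suppressWarnings(removeOutliers(x$estimates))))
  names(dens) <- names(corpus)
  folds <- stratifiedFolds(corpus, dens, k = 3, seed = 7,
                           nIterations = 100)
  tr <- tuneAlgorithm("lin", "L", corpus, dens, folds,
                      budget = list(nRandom = 3, nRefineStarts = 0),
                      seed = 8)
  cv <- crossValidate("lin", "L", corpus, dens, folds, tr)
  expect_identical(sort(cv$image_id), sort(names(corpus)))
  expect_identical(anyDuplicated(cv$image_id), 0L)
  # provenance: the parameters applied to an image were tuned without it
  for (i in seq_len(nrow(cv))) {
    trainIds <- tr@perFold[[cv$fold[i]]]$trainingIds
    expect_false(cv$image_id[i] %in% trainIds)
  }
  # the norm condition is the identity: same result as the default
  cvNorm <- crossValidate("lin", "L", corpus, dens, folds, tr,
                          condition = "norm")
  expect_equal(cv$confidence, cvNorm$confidence)
  # an estimator pinned to the true horizon beats uniform guessing on a
  # tight-density corpus
  tight <- lapply(corpus, function(x)
    spikeDensity(imageId(x$image), at = trueHorizon(x$image), h = 0.01))
  names(tight) <- names(corpus)
  oracleConf <- mean(vapply(corpus, function(x)
    confidence(tight[[imageId(x$image)]], trueHorizon(x$image)),
    numeric(1)))
  trD <- tuneAlgorithm("dum1", "L", corpus, tight, folds,
                       budget = list(nRandom = 10, nRefineStarts = 0),
                       seed = 9)
  cvD <- crossValidate("dum1", "L", corpus, tight, folds, trD, seed = 10)
  expect_gt(oracleConf, mean(cvD$confidence))
  expect_error(crossValidate("lin", "L", corpus, dens,
                             stratifiedFolds(corpus, dens, k = 2,
                                             seed = 1, nIterations = 10),
                             tr), "cover")
})
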