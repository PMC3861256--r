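## Aggregation of confidences by condition and scene type, human-machine
## behavior correlation, and inter-rater reliability (intraclass
## correlations, Shrout-Fleiss two-way random-effects form).

#' Group means and standard errors of confidences
#'
#' Arithmetic means with standard error `sd / sqrt(n)` per group. Groups
#' present in the grouping levels but empty in the data are reported as
#' missing (NA), never as zero.
#'
#' @param confidences data.frame with a `confidence` column and the
#'   grouping column(s).
#' @param grouping `"condition"`, `"scene_type"` or
#'   `"condition_x_scene_type"` (crossed cells).
#' @return data.frame with grouping columns plus `mean`, `se`, `n`.
#' @export
meanConfidenceBy <- function(confidences,
                             grouping = c("condition", "scene_type",
                                          "condition_x_scene_type")) {
  grouping <- match.arg(grouping)
  if (!nrow(confidences)) stop("empty confidence table", call. = FALSE)
  cols <- switch(grouping,
    condition = "condition",
    scene_type = "scene_type",
    condition_x_scene_type = c("condition", "scene_type"))
  if (!all(cols %in% names(confidences))) {
    stop("confidence table lacks column(s): ",
         paste(setdiff(cols, names(confidences)), collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(confidences[cols], drop = FALSE, sep = ":")
  means <- tapply(confidences$confidence, key, mean)
  sds <- tapply(confidences$confidence, key, stats::sd)
  ns <- tapply(confidences$confidence, key, length)
  ns[is.na(ns)] <- 0
  labs <- do.call(rbind, strsplit(names(means), ":", fixed = TRUE))
  out <- data.frame(labs, mean = as.numeric(means),
                    se = as.numeric(sds) / sqrt(as.numeric(ns)),
                    n = as.integer(ns), stringsAsFactors = FALSE)
  names(out)[seq_along(cols)] <- cols
  rownames(out) <- NULL
  out
}

#' Build a 13-cell behavior pattern
#'
#' The "behavior" of a source (an algorithm/channel, or the simulated human
#' reference) is its vector of mean confidences: the 6 condition means
#' followed by the 7 scene-type means. A crossed 6 x 7 = 42-cell variant is
#' available via `crossed = TRUE`.
#'
#' @param confidences data.frame with columns `condition`, `scene_type`,
#'   `confidence`.
#' @param source label stored in the attribute `source`.
#' @param crossed use the 42 crossed cells instead of the 13 marginals.
#' @return named numeric vector of cell means.
#' @export
behaviorPattern <- function(confidences, source = "", crossed = FALSE) {
  if (crossed) {
    m <- meanConfidenceBy(confidences, "condition_x_scene_type")
    v <- stats::setNames(m$mean, paste(m$condition, m$scene_type,
                                       sep = ":"))
  } else {
    mc <- meanConfidenceBy(confidences, "condition")
    ms <- meanConfidenceBy(confidences, "scene_type")
    v <- c(stats::setNames(mc$mean, paste0("cond:", mc$condition)),
           stats::setNames(ms$mean, paste0("scene:", ms$scene_type)))
  }
  attr(v, "source") <- source
  v
}

#' Pearson correlation between two behavior patterns
#'
#' Cells are matched by label; with zero variance in either pattern the
#' correlation is undefined and NA is returned.
#'
#' @param patternA,patternB named numeric vectors (see
#'   [behaviorPattern()]).
#' @return Pearson correlation coefficient, or NA.
#' @export
behaviorCorrelation <- function(patternA, patternB) {
  if (is.null(names(patternA)) || is.null(names(patternB)) ||
      !setequal(names(patternA), names(patternB))) {
    stop("patterns must share cell labels", call. = FALSE)
  }
  b <- patternB[names(patternA)]
  keep <- is.finite(patternA) & is.finite(b)
  a <- patternA[keep]; b <- b[keep]
  if (length(a) < 3L) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  as.numeric(stats::cor(a, b))
}

#' Intraclass correlation, Shrout-Fleiss form 2
#'
#' Two-way random-effects reliability of k raters judging n items.
#' Items with any missing rating are dropped (a do-not-know response
#' invalidates the whole row). With the row (item), column (rater) and
#' error mean squares MSR, MSC, MSE from the two-way decomposition:
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)}
#' \deqn{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#'
#' @param ratings numeric items x raters matrix (NA = missing).
#' @param form `"single"` for ICC(2,1) (reliability of one rater) or
#'   `"average"` for ICC(2,k) (reliability of the rater mean).
#' @return the coefficient, with attributes `nItems` and `nDropped`.
#' @examples
#' set.seed(1)
#' item <- rnorm(20)
#' m <- outer(item, rnorm(4, sd = 0.1), `+`) + rnorm(80, sd = 0.2)
#' iccRating(m, "single")
#' @export
iccRating <- function(ratings, form = c("single", "average")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  complete <- stats::complete.cases(ratings)
  dropped <- sum(!complete)
  m <- ratings[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 complete items and 2 raters", call. = FALSE)
  }
  df <- data.frame(y = as.numeric(m),
                   item = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ## F statistics are unused (and warn on perfect fits); only the mean
  ## squares of the two-way decomposition are read off
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ item + rater, data = df))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  out <- if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  attr(out, "nItems") <- n
  attr(out, "nDropped") <- dropped
  out
}

#' Simulated quick-viewing human reference confidences
#'
#' A synthetic stand-in for human raters estimating under brief masked
#' presentation: for every image and condition one simulated estimate is
#' drawn around the true horizon with the scene-class rater spread inflated
#' by a condition-dependent factor (manipulated images are harder), then
#' scored against the image's ground-truth density. Clearly a synthetic
#' construct: it reproduces the qualitative structure (per-class difficulty
#' ordering, condition effects), not measured human magnitudes.
#'
#' @param corpus output of [makeCorpus()].
#' @param densities named list of ground-truth densities.
#' @param conditions conditions to simulate (default all six).
#' @param inflation named per-condition SD inflation factors.
#' @param nRaters simulated raters per image and condition.
#' @param seed integer seed.
#' @return data.frame (image_id, scene_type, condition, position,
#'   confidence), source tag "human_synthetic" in attribute `source`.
#' @export
simulateHumanPattern <- function(corpus, densities,
                                 conditions = conditionNames(),
                                 inflation = c(norm = 1, inverted = 2,
                                               blurred = 1.8, lower = 1.2,
                                               middle = 1.1, upper = 1.4),
                                 nRaters = 3L, seed = 1L) {
  sdByClass <- defaultEstimateSd()
  rows <- list()
  for (cond in conditions) {
    infl <- inflation[[cond]]
    for (i in seq_along(corpus)) {
      img <- corpus[[i]]$image
      id <- imageId(img)
      es <- simulateEstimates(trueHorizon(img),
                              sd = sdByClass[[sceneClass(img)]] * infl,
                              n = nRaters,
                              seed = childSeed(seed, cond, i),
                              imageId = id)
      pos <- estimates(es)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, scene_type = sceneClass(img), condition = cond,
        position = pos,
        confidence = confidence(densities[[id]], pos),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "source") <- "human_synthetic"
  out
}
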