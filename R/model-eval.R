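## Metrics, classifier comparison and variability reporting.  The preterm
## class is the positive class throughout: F1, sensitivity and PPV refer
## to preterm detection.

#' Confusion-matrix metrics and AUC
#'
#' Accuracy, F1, sensitivity, specificity, PPV, NPV from the confusion
#' matrix (positive = preterm) and the area under the ROC curve by
#' trapezoidal integration, computed in its rank (Mann-Whitney) form with
#' ties counted one half.
#'
#' @param truth factor of true labels (both classes must occur).
#' @param predicted factor of predicted labels.
#' @param scores numeric preterm scores for the ROC.
#' @return Named numeric vector with \code{accuracy}, \code{f1},
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv},
#'   \code{auc}, all fractions in \code{[0, 1]}.
#' @export
computeMetrics <- function(truth, predicted, scores) {
  truth <- factor(truth, c("term", "preterm"))
  predicted <- factor(predicted, c("term", "preterm"))
  if (length(truth) != length(predicted) ||
      length(truth) != length(scores))
    stop("truth, predicted and scores must be aligned")
  if (nlevels(droplevels(truth)) < 2L)
    stop("true labels contain a single class; metrics undefined")
  tp <- sum(truth == "preterm" & predicted == "preterm")
  fn <- sum(truth == "preterm" & predicted == "term")
  fp <- sum(truth == "term" & predicted == "preterm")
  tn <- sum(truth == "term" & predicted == "term")
  pos <- truth == "preterm"
  r <- rank(scores)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  c(accuracy = (tp + tn) / length(truth),
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp == 0) 0 else tp / (tp + fp),
    npv = if (tn + fn == 0) 0 else tn / (tn + fn),
    auc = auc)
}

#' Friedman test with Nemenyi post-hoc classifier comparison
#'
#' Friedman rank test across partitions (rows) and classifiers (columns),
#' followed by Nemenyi pairwise comparisons: classifiers i and j differ at
#' level alpha when their mean ranks differ by at least the critical
#' difference \eqn{q_\alpha \sqrt{k(k+1)/(6n)}}, with \eqn{q_\alpha} the
#' Studentized-range quantile divided by \eqn{\sqrt 2}.
#'
#' @param scoreMatrix numeric matrix, partitions x classifiers (e.g. the
#'   per-partition validation F1 of each classifier).
#' @param alpha significance level (default 0.05).
#' @return List with \code{friedmanStatistic}, \code{friedmanP},
#'   \code{meanRanks}, \code{criticalDifference}, \code{pMatrix}
#'   (symmetric pairwise Nemenyi p-values) and \code{significant}
#'   (symmetric logical matrix).
#' @export
compareClassifiers <- function(scoreMatrix, alpha = 0.05) {
  m <- as.matrix(scoreMatrix)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("clf", seq_len(ncol(m)))
  n <- nrow(m); k <- ncol(m)
  if (k < 2L || n < 5L)
    stop("need >= 2 classifiers and >= 5 partitions")
  rk <- t(apply(m, 1L, rank))
  meanRanks <- colMeans(rk)
  if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) {
    ## every row completely tied: no evidence of any difference
    fr <- list(statistic = 0, p.value = 1)
  } else {
    ft <- friedman.test(m)
    fr <- list(statistic = unname(ft$statistic), p.value = ft$p.value)
  }
  se <- sqrt(k * (k + 1) / (6 * n))
  cd <- qtukey(1 - alpha, k, Inf) / sqrt(2) * se
  dif <- abs(outer(meanRanks, meanRanks, "-"))
  pMat <- ptukey(dif / se * sqrt(2), k, Inf, lower.tail = FALSE)
  diag(pMat) <- 1
  dimnames(pMat) <- list(colnames(m), colnames(m))
  sig <- dif >= cd
  diag(sig) <- FALSE
  dimnames(sig) <- dimnames(pMat)
  list(friedmanStatistic = fr$statistic, friedmanP = fr$p.value,
       meanRanks = meanRanks, criticalDifference = cd,
       pMatrix = pMat, significant = sig)
}

#' Coefficient-of-variation report
#'
#' Between-partition variability (CV = SD/mean) of every metric for every
#' classifier, plus the min/mean/max CV across the base classifiers for
#' each metric (the layout used to compare an ensemble against the spread
#' of its bases).
#'
#' @param metrics data.frame in long layout with columns
#'   \code{classifier}, \code{partition} and one column per metric (as
#'   produced by [runPipeline()]).
#' @param baseClassifiers names counted as base classifiers (default all
#'   except \code{"ensemble"}).
#' @return List with \code{cv} (data.frame classifier x metric; \code{NA}
#'   where a metric's mean is zero) and \code{baseRange} (data.frame with
#'   rows min/mean/max across base classifiers).
#' @export
variabilityReport <- function(metrics,
    baseClassifiers = setdiff(unique(metrics$classifier), "ensemble")) {
  metricCols <- setdiff(names(metrics),
                        c("classifier", "partition", "split"))
  cls <- unique(metrics$classifier)
  cv <- do.call(rbind, lapply(cls, function(cl) {
    sub <- metrics[metrics$classifier == cl, metricCols, drop = FALSE]
    if (nrow(sub) < 2L) stop("need >= 2 partitions per classifier")
    vals <- vapply(metricCols, function(mc) {
      mu <- mean(sub[[mc]])
      if (mu == 0) NA_real_ else sd(sub[[mc]]) / mu
    }, numeric(1))
    data.frame(classifier = cl, t(vals))
  }))
  base <- cv[cv$classifier %in% baseClassifiers, metricCols, drop = FALSE]
  baseRange <- data.frame(
    stat = c("min", "mean", "max"),
    rbind(vapply(base, min, numeric(1)),
          vapply(base, mean, numeric(1)),
          vapply(base, max, numeric(1))))
  list(cv = cv, baseRange = baseRange)
}
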