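## The three base classifiers.  Features are standardised with statistics
## fitted on the training rows only; scores are continuous (KNN:
## preterm-neighbour fraction; LDA/LR: posterior probability of preterm)
## and labels use the 0.5 threshold.

#' Base classifier specification
#'
#' @param kind \code{"KNN"}, \code{"LDA"} or \code{"LR"}.
#' @param knnK neighbour count for KNN (odd, to avoid vote ties;
#'   default 5).
#' @param standardize z-score features on training statistics
#'   (default TRUE).
#' @return List of class \code{ClassifierSpec}.
#' @export
classifierSpec <- function(kind = c("KNN", "LDA", "LR"), knnK = 5,
                           standardize = TRUE) {
  kind <- match.arg(kind)
  if (kind == "KNN" && knnK %% 2 == 0)
    stop("knnK must be odd to avoid vote ties")
  structure(list(kind = kind, knnK = as.integer(knnK),
                 standardize = standardize), class = "ClassifierSpec")
}

## Gaussian LDA with ridge-regularised pooled covariance; fallback when
## MASS::lda refuses (e.g. a feature constant within a group)
.ridgeLDA <- function(trainX, trainY, evalX) {
  classes <- levels(trainY)
  p <- ncol(trainX)
  mus <- lapply(classes, function(cl)
    colMeans(trainX[trainY == cl, , drop = FALSE]))
  S <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    xc <- sweep(trainX[trainY == classes[i], , drop = FALSE], 2L,
                mus[[i]])
    S <- S + crossprod(xc)
  }
  S <- S / max(1L, nrow(trainX) - length(classes))
  lambda <- 1e-6 * mean(diag(S))
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-8
  Sinv <- solve(S + diag(lambda, p))
  priors <- as.numeric(table(trainY)[classes]) / nrow(trainX)
  disc <- vapply(seq_along(classes), function(i) {
    w <- Sinv %*% mus[[i]]
    as.numeric(evalX %*% w) - 0.5 * sum(mus[[i]] * w) + log(priors[i])
  }, numeric(nrow(evalX)))
  disc <- matrix(disc, nrow = nrow(evalX))
  post <- exp(disc - apply(disc, 1L, max))
  post <- post / rowSums(post)
  post[, match("preterm", classes)]
}

#' Fit a base classifier and predict labels and scores
#'
#' @param spec a [classifierSpec()].
#' @param trainX,trainY training feature matrix (rows = subjects) and
#'   label factor with levels \code{term}, \code{preterm}.
#' @param evalX feature matrix to predict.
#' @return List with \code{labels} (factor) and \code{scores} (numeric
#'   probability-like score for the preterm class; thresholded at 0.5,
#'   ties to preterm).
#' @export
fitPredict <- function(spec, trainX, trainY, evalX) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  trainX <- as.matrix(trainX)
  evalX <- as.matrix(evalX)
  if (ncol(trainX) != ncol(evalX)) stop("feature dimension mismatch")
  trainY <- factor(trainY, c("term", "preterm"))
  if (spec$standardize) {
    mu <- colMeans(trainX)
    sg <- apply(trainX, 2L, sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    trainX <- sweep(sweep(trainX, 2L, mu), 2L, sg, "/")
    evalX <- sweep(sweep(evalX, 2L, mu), 2L, sg, "/")
  }
  scores <- switch(spec$kind,
    KNN = {
      pr <- class::knn(trainX, evalX, trainY, k = spec$knnK,
                       prob = TRUE, use.all = TRUE)
      frac <- attr(pr, "prob")
      ifelse(pr == "preterm", frac, 1 - frac)
    },
    LDA = {
      fit <- tryCatch(
        suppressWarnings(MASS::lda(trainX, grouping = trainY)),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("singular within-class covariance; ",
                "using ridge-regularized LDA")
        .ridgeLDA(trainX, trainY, evalX)
      } else {
        as.numeric(predict(fit, evalX)$posterior[, "preterm"])
      }
    },
    LR = {
      y01 <- as.integer(trainY == "preterm")
      fit <- suppressWarnings(
        glm.fit(cbind(1, trainX), y01, family = binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      as.numeric(plogis(cbind(1, evalX) %*% beta))
    })
  list(labels = factor(ifelse(scores >= 0.5, "preterm", "term"),
                       c("term", "preterm")),
       scores = scores)
}

#' Majority-vote ensemble of the three base classifiers
#'
#' Per row, the label predicted by at least two of the three base
#' classifiers; the ensemble score (for ROC analysis) is the mean of the
#' base scores.
#'
#' @param labelsList list of three aligned label factors.
#' @param scoresList optional list of three aligned score vectors.
#' @return List with \code{labels} and (if scores given) \code{scores}.
#' @export
majorityVote <- function(labelsList, scoresList = NULL) {
  n <- unique(vapply(labelsList, length, integer(1)))
  if (length(n) != 1L) stop("label vectors have mismatched lengths")
  votes <- rowSums(do.call(cbind,
    lapply(labelsList, function(l) l == "preterm")))
  out <- list(labels = factor(ifelse(votes >= 2, "preterm", "term"),
                              c("term", "preterm")))
  if (!is.null(scoresList)) {
    if (any(vapply(scoresList, length, integer(1)) != n))
      stop("score vectors have mismatched lengths")
    out$scores <- rowMeans(do.call(cbind, scoresList))
  }
  out
}
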