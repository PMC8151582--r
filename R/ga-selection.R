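## Genetic-algorithm wrapper feature selection.
##
## Chromosomes are binary inclusion masks over the feature columns.  The
## fitness of a mask is mean validation F1 (preterm positive) across the
## partitions, multiplied by the feature-reduction term
## (NFeat - NCFeat), so equal-performing smaller subsets always win.
## Generational loop: elites copied unchanged; of the remaining children,
## a crossover fraction (0.8) come from arithmetic crossover of tournament
## parents and the rest are mutation-only copies of tournament parents.

#' Genetic-algorithm configuration
#'
#' Defaults follow the emulated protocol: population size equal to the
#' genome length, arithmetic crossover with probability 0.8, uniform
#' mutation at 0.01, tournament size 2, elite count 2, and termination
#' when the best fitness improves by less than 1e-6 over 150 consecutive
#' generations.
#'
#' @param genomeLength number of features (genes).
#' @param populationSize chromosomes per generation (default =
#'   \code{genomeLength}; >= 4).
#' @param crossoverProb fraction of non-elite children produced by
#'   crossover (default 0.8).
#' @param mutationRate per-gene probability of redrawing the gene
#'   uniformly from \{0, 1\} (default 0.01).
#' @param tournamentSize candidates per tournament (default 2).
#' @param eliteCount chromosomes copied unchanged (default 2).
#' @param stallGenerations,fitnessTolerance terminate when the best
#'   fitness has improved by less than \code{fitnessTolerance} over this
#'   many consecutive generations.
#' @param maxGenerations hard generation cap (default 1000).
#' @param seed integer seed.
#' @return List of class \code{GAConfig}.
#' @export
gaConfig <- function(genomeLength = 203, populationSize = genomeLength,
                     crossoverProb = 0.8, mutationRate = 0.01,
                     tournamentSize = 2, eliteCount = 2,
                     stallGenerations = 150, fitnessTolerance = 1e-6,
                     maxGenerations = 1000, seed = 1) {
  if (populationSize < 4) stop("populationSize must be >= 4")
  if (crossoverProb < 0 || crossoverProb > 1)
    stop("crossoverProb must be in [0, 1]")
  if (mutationRate < 0 || mutationRate > 1)
    stop("mutationRate must be in [0, 1]")
  if (eliteCount >= populationSize)
    stop("eliteCount must be smaller than populationSize")
  structure(list(genomeLength = as.integer(genomeLength),
                 populationSize = as.integer(populationSize),
                 crossoverProb = crossoverProb,
                 mutationRate = mutationRate,
                 tournamentSize = as.integer(tournamentSize),
                 eliteCount = as.integer(eliteCount),
                 stallGenerations = as.integer(stallGenerations),
                 fitnessTolerance = fitnessTolerance,
                 maxGenerations = as.integer(maxGenerations),
                 seed = seed),
            class = "GAConfig")
}

## the fitness functional: mean validation F1 times the reduction term
.gaFitness <- function(meanValF1, nFeat, nSelected) {
  meanValF1 * (nFeat - nSelected)
}

.f1 <- function(truth, predicted) {
  tp <- sum(truth == "preterm" & predicted == "preterm")
  fp <- sum(truth == "term" & predicted == "preterm")
  fn <- sum(truth == "preterm" & predicted == "term")
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

## per-partition train/validation/test data, optionally SMOTE-augmenting
## each training fold only (leakage-free mode)
.preparePartitions <- function(x, y, partitions, smoteMode = "none",
                               smoteK = 5, seed = 1) {
  lapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    trainX <- x[p$train, , drop = FALSE]
    trainY <- y[p$train]
    if (smoteMode == "trainOnly") {
      se <- SummarizedExperiment(
        assays = list(features = t(trainX)),
        colData = DataFrame(subject_id = paste0("r", p$train),
                            label = trainY, is_synthetic = FALSE))
      bal <- smoteBalance(se, k = smoteK, seed = seed + i)
      xy <- .tableXY(bal)
      trainX <- xy$x
      trainY <- xy$y
    }
    list(trainX = trainX, trainY = trainY,
         valX = x[p$validation, , drop = FALSE], valY = y[p$validation],
         testX = x[p$test, , drop = FALSE], testY = y[p$test])
  })
}

.evalFitnessPrepared <- function(mask, spec, prep, nFeat) {
  sel <- which(mask == 1L)
  f1s <- vapply(prep, function(pp) {
    pred <- fitPredict(spec, pp$trainX[, sel, drop = FALSE], pp$trainY,
                       pp$valX[, sel, drop = FALSE])
    .f1(pp$valY, pred$labels)
  }, numeric(1))
  meanF1 <- mean(f1s)
  list(meanValF1 = meanF1, nFeat = nFeat, nSelected = length(sel),
       fitness = .gaFitness(meanF1, nFeat, length(sel)),
       perPartitionF1 = f1s)
}

#' Evaluate the fitness of a feature mask
#'
#' For each partition the classifier is fitted on the masked training rows
#' and scored by F1 (preterm positive) on the masked validation rows; the
#' fitness is the mean validation F1 times \code{(NFeat - NCFeat)}.  Test
#' rows are never touched.  An all-zero mask receives fitness
#' \code{-Inf} (never selected) with a message.
#'
#' @param mask binary vector over the feature columns.
#' @param spec a [classifierSpec()].
#' @param x feature matrix (rows = subjects) or a feature
#'   \code{SummarizedExperiment} (then \code{y} is taken from its
#'   \code{colData}).
#' @param y label factor (ignored when \code{x} is a
#'   \code{SummarizedExperiment}).
#' @param partitions partition list from [makePartitions()].
#' @return List with \code{meanValF1}, \code{nFeat}, \code{nSelected},
#'   \code{fitness} and \code{perPartitionF1}.
#' @export
evaluateFitness <- function(mask, spec, x, y = NULL, partitions) {
  if (is(x, "SummarizedExperiment")) {
    xy <- .tableXY(x)
    x <- xy$x; y <- xy$y
  }
  if (length(mask) != ncol(x))
    stop("mask length must equal the number of feature columns")
  if (sum(mask) == 0L) {
    message("all-zero mask: assigning minimal fitness")
    return(list(meanValF1 = 0, nFeat = ncol(x), nSelected = 0L,
                fitness = -Inf, perPartitionF1 = NA_real_))
  }
  prep <- .preparePartitions(x, y, partitions)
  .evalFitnessPrepared(as.integer(mask), spec, prep, ncol(x))
}

#' Tournament selection
#'
#' Draws \code{size} chromosomes uniformly with replacement and returns
#' the index of the fittest; exact fitness ties are resolved uniformly.
#'
#' @param fitness numeric vector of evaluated fitness values.
#' @param size tournament size (default 2).
#' @return Integer index of the selected chromosome.
#' @export
tournamentSelect <- function(fitness, size = 2) {
  if (length(fitness) == 0L || anyNA(fitness))
    stop("population must be fully evaluated")
  cand <- sample.int(length(fitness), size, replace = TRUE)
  best <- cand[fitness[cand] == max(fitness[cand])]
  if (length(best) > 1L) best <- sample(best, 1L)
  best
}

#' Arithmetic crossover for binary genomes
#'
#' One convex weight u ~ U(0, 1) per child: the child is
#' \code{round(u p1 + (1 - u) p2)} gene-wise, i.e. the shared value where
#' the parents agree and a u-dependent value where they differ; an exact
#' 0.5 rounds by fair coin.
#'
#' @param p1,p2 equal-length binary parent vectors.
#' @return Binary child vector.
#' @export
arithmeticCrossover <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("parents have different lengths")
  u <- runif(1)
  raw <- u * p1 + (1 - u) * p2
  child <- as.integer(round(raw))
  half <- abs(raw - 0.5) < 1e-12
  if (any(half)) child[half] <- rbinom(sum(half), 1L, 0.5)
  child
}

#' Uniform mutation
#'
#' Each gene is independently redrawn uniformly from \{0, 1\} with
#' probability \code{rate} (so on average only half the redrawn genes
#' actually change).
#'
#' @param mask binary vector.
#' @param rate per-gene redraw probability (default 0.01).
#' @return Mutated binary vector.
#' @export
uniformMutation <- function(mask, rate = 0.01) {
  hit <- runif(length(mask)) < rate
  mask[hit] <- rbinom(sum(hit), 1L, 0.5)
  as.integer(mask)
}

#' Run the genetic-algorithm wrapper selection
#'
#' @param x feature matrix (rows = subjects) or feature
#'   \code{SummarizedExperiment}.
#' @param y label factor (ignored for a \code{SummarizedExperiment}).
#' @param spec a [classifierSpec()] used inside the fitness wrapper.
#' @param partitions partition list from [makePartitions()]; only the
#'   train and validation sets are ever used.
#' @param config a [gaConfig()]; \code{genomeLength} must equal the
#'   feature count.
#' @param smoteMode \code{"none"} (default; the table is typically already
#'   balanced) or \code{"trainOnly"} to SMOTE-augment each training fold
#'   inside the fitness wrapper.
#' @param smoteK SMOTE neighbour count for \code{smoteMode = "trainOnly"}.
#' @return List with \code{bestMask} (binary vector, named by features
#'   when available), \code{bestFitness}, \code{bestEvaluation} (the
#'   [evaluateFitness()] record of the best mask), \code{history}
#'   (data.frame generation/best/mean), \code{generations} and
#'   \code{converged}.
#' @export
runGA <- function(x, y = NULL, spec, partitions, config = gaConfig(),
                  smoteMode = c("none", "trainOnly"), smoteK = 5) {
  smoteMode <- match.arg(smoteMode)
  if (is(x, "SummarizedExperiment")) {
    xy <- .tableXY(x)
    x <- xy$x; y <- xy$y
  }
  L <- config$genomeLength
  if (L != ncol(x))
    stop("config genomeLength must equal the number of feature columns")
  prep <- .preparePartitions(x, y, partitions, smoteMode = smoteMode,
                             smoteK = smoteK, seed = config$seed)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  evalMask <- function(mask) {
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ev <- if (sum(mask) == 0L)
      list(meanValF1 = 0, nFeat = L, nSelected = 0L, fitness = -Inf)
    else .evalFitnessPrepared(mask, spec, prep, L)
    cache[[key]] <- ev
    ev
  }
  .guard <- function(mask) {      # keep at least one gene switched on
    if (sum(mask) == 0L) mask[sample.int(L, 1L)] <- 1L
    mask
  }
  .withSeed(config$seed, {
    pop <- lapply(seq_len(config$populationSize), function(i)
      .guard(as.integer(rbinom(L, 1L, 0.5))))
    history <- data.frame(generation = integer(0), best = numeric(0),
                          mean = numeric(0))
    bestEver <- -Inf
    bestMask <- NULL
    stall <- 0L
    gen <- 0L
    converged <- FALSE
    while (gen < config$maxGenerations) {
      gen <- gen + 1L
      evals <- lapply(pop, evalMask)
      fit <- vapply(evals, function(e) e$fitness, numeric(1))
      genBest <- max(fit)
      history <- rbind(history,
                       data.frame(generation = gen, best = genBest,
                                  mean = mean(fit[is.finite(fit)])))
      if (genBest > bestEver + config$fitnessTolerance) {
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (genBest > bestEver) {
        bestEver <- genBest
        bestMask <- pop[[which.max(fit)]]
      }
      if (stall >= config$stallGenerations) {
        converged <- TRUE
        break
      }
      ord <- order(fit, decreasing = TRUE)
      nChild <- config$populationSize - config$eliteCount
      nCross <- round(config$crossoverProb * nChild)
      newPop <- pop[ord[seq_len(config$eliteCount)]]
      for (i in seq_len(nCross)) {
        p1 <- pop[[tournamentSelect(fit, config$tournamentSize)]]
        p2 <- pop[[tournamentSelect(fit, config$tournamentSize)]]
        newPop[[length(newPop) + 1L]] <- .guard(arithmeticCrossover(p1, p2))
      }
      for (i in seq_len(nChild - nCross)) {
        p <- pop[[tournamentSelect(fit, config$tournamentSize)]]
        newPop[[length(newPop) + 1L]] <-
          .guard(uniformMutation(p, config$mutationRate))
      }
      pop <- newPop
    }
    if (!converged)
      message(sprintf(
        "GA reached the %d-generation cap before stalling; %s",
        config$maxGenerations, "returning best mask so far"))
    if (!is.null(colnames(x))) names(bestMask) <- colnames(x)
    list(bestMask = bestMask, bestFitness = bestEver,
         bestEvaluation = evalMask(as.integer(bestMask)),
         history = history, generations = gen, converged = converged)
  })
}
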