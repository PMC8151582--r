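## End-to-end orchestration: simulate (or ingest) -> extract -> screen ->
## balance -> partition -> GA per classifier -> final train/validation/
## test evaluation of the base classifiers and the majority-vote ensemble,
## each base classifier using its own optimised mask.  Test rows are never
## seen by the GA fitness wrapper.

#' Pipeline configuration
#'
#' @param cohort a [synthCohortConfig()] describing the synthetic cohort
#'   (ignored when a cohort or feature table is supplied to
#'   [runPipeline()]).
#' @param windowS,overlap analysis windowing parameters.
#' @param entropy an [entropyConfig()].
#' @param smoteK SMOTE neighbour count (default 5).
#' @param smoteMode \code{"whole"} (faithful: balance the whole table
#'   before partitioning; leaks synthetic-parent information across
#'   splits, see vignette) or \code{"trainOnly"} (leakage-free).
#' @param nPartitions stratified holdout partitions (default 30).
#' @param ga a [gaConfig()]; its \code{genomeLength} is set to 203 by the
#'   pipeline.
#' @param classifiers named list of [classifierSpec()]s (default KNN,
#'   LDA, LR).
#' @param selectFeatures run the GA wrapper (default TRUE); when FALSE
#'   all features are used (full mask), e.g. for null-effect checks.
#' @param seed master seed for balancing and partitioning.
#' @return List of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(cohort = synthCohortConfig(30, 10),
                           windowS = 120, overlap = 0.5,
                           entropy = entropyConfig(),
                           smoteK = 5, smoteMode = c("whole", "trainOnly"),
                           nPartitions = 30, ga = gaConfig(),
                           classifiers = list(
                             KNN = classifierSpec("KNN"),
                             LDA = classifierSpec("LDA"),
                             LR = classifierSpec("LR")),
                           selectFeatures = TRUE, seed = 1) {
  smoteMode <- match.arg(smoteMode)
  if (nPartitions < 2L) stop("nPartitions must be >= 2")
  structure(list(cohort = cohort, windowS = windowS, overlap = overlap,
                 entropy = entropy, smoteK = smoteK, smoteMode = smoteMode,
                 nPartitions = nPartitions, ga = ga,
                 classifiers = classifiers,
                 selectFeatures = selectFeatures, seed = seed),
            class = "PipelineConfig")
}

#' Run the full prediction pipeline
#'
#' Executes: cohort simulation (unless one is supplied), feature
#' extraction, rank-sum screening (always on the original unbalanced
#' rows), SMOTE balancing, stratified partitioning, GA wrapper selection
#' per base classifier, and final train/validation/test evaluation of the
#' three base classifiers plus the majority-vote ensemble, each base
#' using its own optimised mask.  Stage results are returned so any stage
#' can be resumed from its serialized output.
#'
#' @param config a [pipelineConfig()].
#' @param cohort optional pre-built [EHGCohort-class] (skips simulation).
#' @param featureTable optional pre-built feature
#'   \code{SummarizedExperiment} (skips extraction).
#' @param verbose print per-stage progress and wall time.
#' @return List of class \code{PipelineResult} with elements
#'   \code{featureTable}, \code{screening}, \code{balancedTable},
#'   \code{partitions}, \code{ga} (per classifier), \code{masks} (per
#'   classifier), \code{metrics} (long data.frame: partition, split,
#'   classifier, seven metrics), \code{comparison} (Friedman/Nemenyi on
#'   validation F1), \code{variability} and \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL,
                        featureTable = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  .stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.1f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  if (is.null(featureTable)) {
    if (is.null(cohort))
      cohort <- .stage("simulate", generateCohort(config$cohort))
    featureTable <- .stage("extract",
      buildFeatureTable(cohort, windowS = config$windowS,
                        overlap = config$overlap, config = config$entropy,
                        verbose = verbose))
  }
  screening <- .stage("screen", ranksumScreen(featureTable))

  faithful <- config$smoteMode == "whole"
  analysisTable <- if (faithful)
    .stage("balance", smoteBalance(featureTable, k = config$smoteK,
                                   seed = config$seed))
  else featureTable
  xy <- .tableXY(analysisTable)
  partitions <- .stage("partition",
    makePartitions(xy$y, nPartitions = config$nPartitions,
                   seed = config$seed + 1L))
  gaSmoteMode <- if (faithful) "none" else "trainOnly"

  gaRes <- list()
  masks <- list()
  for (ci in seq_along(config$classifiers)) {
    cname <- names(config$classifiers)[ci]
    if (config$selectFeatures) {
      cfg <- config$ga
      cfg$genomeLength <- ncol(xy$x)
      if (cfg$populationSize < 4L) cfg$populationSize <- cfg$genomeLength
      cfg$seed <- config$seed + 100L * ci
      gaRes[[cname]] <- .stage(paste0("select:", cname),
        runGA(xy$x, xy$y, config$classifiers[[ci]], partitions, cfg,
              smoteMode = gaSmoteMode, smoteK = config$smoteK))
      masks[[cname]] <- gaRes[[cname]]$bestMask
    } else {
      masks[[cname]] <- setNames(rep(1L, ncol(xy$x)), colnames(xy$x))
    }
  }

  prep <- .preparePartitions(xy$x, xy$y, partitions,
                             smoteMode = gaSmoteMode,
                             smoteK = config$smoteK, seed = config$seed)
  metrics <- .stage("evaluate", {
    rows <- list()
    for (pi in seq_along(prep)) {
      pp <- prep[[pi]]
      base <- lapply(names(config$classifiers), function(cname) {
        sel <- which(masks[[cname]] == 1L)
        fit <- list(
          train = fitPredict(config$classifiers[[cname]],
                             pp$trainX[, sel, drop = FALSE], pp$trainY,
                             pp$trainX[, sel, drop = FALSE]),
          validation = fitPredict(config$classifiers[[cname]],
                                  pp$trainX[, sel, drop = FALSE],
                                  pp$trainY,
                                  pp$valX[, sel, drop = FALSE]),
          test = fitPredict(config$classifiers[[cname]],
                            pp$trainX[, sel, drop = FALSE], pp$trainY,
                            pp$testX[, sel, drop = FALSE]))
        fit
      })
      names(base) <- names(config$classifiers)
      truth <- list(train = pp$trainY, validation = pp$valY,
                    test = pp$testY)
      for (split in names(truth)) {
        for (cname in names(base)) {
          m <- computeMetrics(truth[[split]],
                              base[[cname]][[split]]$labels,
                              base[[cname]][[split]]$scores)
          rows[[length(rows) + 1L]] <-
            data.frame(partition = pi, split = split, classifier = cname,
                       t(m))
        }
        ens <- majorityVote(
          lapply(base, function(b) b[[split]]$labels),
          lapply(base, function(b) b[[split]]$scores))
        m <- computeMetrics(truth[[split]], ens$labels, ens$scores)
        rows[[length(rows) + 1L]] <-
          data.frame(partition = pi, split = split,
                     classifier = "ensemble", t(m))
      }
    }
    do.call(rbind, rows)
  })

  val <- metrics[metrics$split == "validation", ]
  f1Mat <- do.call(cbind, lapply(split(val$f1, val$classifier),
                                 as.numeric))
  f1Mat <- f1Mat[, c(names(config$classifiers), "ensemble")]
  comparison <- if (config$nPartitions >= 5L) {
    .stage("compare", compareClassifiers(f1Mat))
  } else {
    if (verbose)
      message("[compare] skipped: fewer than 5 partitions")
    NULL
  }
  variability <- .stage("variability",
    variabilityReport(val[, setdiff(names(val), "split")]))

  structure(list(featureTable = featureTable, screening = screening,
                 balancedTable = if (faithful) analysisTable else NULL,
                 partitions = partitions, ga = gaRes, masks = masks,
                 metrics = metrics, comparison = comparison,
                 variability = variability, config = config),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  val <- x$metrics[x$metrics$split == "validation", ]
  agg <- vapply(split(val, val$classifier), function(d)
    c(mean(d$f1), sd(d$f1)), numeric(2))
  cat("Preterm-labor prediction pipeline result\n")
  cat(sprintf("  subjects: %d (+%d synthetic), partitions: %d\n",
              sum(!colData(x$featureTable)$is_synthetic),
              if (is.null(x$balancedTable)) 0L
              else sum(colData(x$balancedTable)$is_synthetic),
              length(x$partitions)))
  for (cl in colnames(agg))
    cat(sprintf("  %-9s validation F1 = %.3f +/- %.3f\n",
                cl, agg[1, cl], agg[2, cl]))
  if (length(x$masks))
    for (cl in names(x$masks))
      cat(sprintf("  mask %-6s: %d features\n", cl, sum(x$masks[[cl]])))
  invisible(x)
}
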