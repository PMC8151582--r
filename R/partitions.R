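## Repeated stratified holdout: each partition splits the rows into
## train / validation / test thirds with equal class proportions (within
## one row).

#' Stratified train/validation/test partitions
#'
#' @param labels factor (or character) of class labels, one per row.
#' @param nPartitions number of independent random partitions
#'   (default 30).
#' @param seed integer seed.
#' @return List of \code{nPartitions} elements, each a list of disjoint
#'   integer index vectors \code{train}, \code{validation}, \code{test}
#'   covering all rows, with per-class counts differing by at most one
#'   row between the three sets.
#' @export
makePartitions <- function(labels, nPartitions = 30, seed = 1) {
  if (nPartitions < 2L) stop("need at least 2 partitions")
  labels <- as.factor(labels)
  .withSeed(seed, {
    lapply(seq_len(nPartitions), function(p) {
      sets <- list(train = integer(0), validation = integer(0),
                   test = integer(0))
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        n <- length(idx)
        base <- n %/% 3L
        extra <- n %% 3L
        ## rotate which set receives the remainder rows across partitions
        sizes <- rep(base, 3L)
        if (extra > 0L)
          sizes[((p + seq_len(extra) - 2L) %% 3L) + 1L] <-
            sizes[((p + seq_len(extra) - 2L) %% 3L) + 1L] + 1L
        cut1 <- sizes[1L]
        cut2 <- sizes[1L] + sizes[2L]
        sets$train <- c(sets$train, idx[seq_len(cut1)])
        sets$validation <- c(sets$validation,
                             idx[(cut1 + 1L):cut2])
        sets$test <- c(sets$test, idx[(cut2 + 1L):n])
      }
      lapply(sets, sort)
    })
  })
}
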