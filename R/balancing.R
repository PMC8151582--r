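## SMOTE oversampling of the minority (preterm) class.
##
## Each synthetic row is x + u (x_nn - x) with u ~ U(0, 1), x a minority
## row and x_nn one of its k nearest minority neighbours; neighbour
## distances are Euclidean on z-scored features (the 203 features span Hz,
## mV and mV^3, so unscaled distances would be dominated by a few
## features).  Original rows are preserved verbatim and synthetic rows are
## flagged, so screening and leakage-aware protocols can always recover
## the original cohort.

#' Balance a feature table by SMOTE
#'
#' Oversamples the minority class (preterm) to parity with the majority
#' class.  Applied to the whole table this reproduces the emulated
#' protocol faithfully but leaks synthetic-parent information across
#' later train/validation/test splits; see the vignette, and
#' \code{smoteMode = "trainOnly"} in [pipelineConfig()] for the
#' leakage-free alternative.
#'
#' @param se feature \code{SummarizedExperiment} from
#'   [buildFeatureTable()].
#' @param k number of minority nearest neighbours (default 5; must be
#'   smaller than the minority count).
#' @param seed integer seed; identical seeds give identical synthetic rows.
#' @param scaleBeforeDistance z-score features (statistics over the whole
#'   table) before neighbour search (default TRUE).
#' @return A \code{SummarizedExperiment} with equal class counts; the
#'   synthetic columns have \code{is_synthetic = TRUE} and carry their
#'   parent and neighbour subject IDs in \code{colData} columns
#'   \code{smote_parent} and \code{smote_neighbor}.
#' @export
smoteBalance <- function(se, k = 5, seed = 1, scaleBeforeDistance = TRUE) {
  xy <- .tableXY(se)
  counts <- table(xy$y)
  if (any(counts == 0L)) stop("both classes must be present")
  minority <- names(which.min(counts))
  majority <- setdiff(levels(xy$y), minority)
  nMin <- counts[[minority]]
  nSyn <- counts[[majority]] - nMin
  if (nSyn == 0L) return(se)
  if (nMin <= k)
    stop(sprintf(
      "minority count (%d) must exceed k (%d); use a smaller k", nMin, k))
  minIdx <- which(xy$y == minority)
  xm <- xy$x[minIdx, , drop = FALSE]
  z <- if (scaleBeforeDistance) {
    mu <- colMeans(xy$x)
    sg <- apply(xy$x, 2L, sd)
    sg[sg == 0] <- 1
    sweep(sweep(xm, 2L, mu), 2L, sg, "/")
  } else xm
  d <- as.matrix(dist(z))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))

  .withSeed(seed, {
    parents <- sample.int(nMin, nSyn, replace = TRUE)
    chosen <- nn[cbind(parents, sample.int(k, nSyn, replace = TRUE))]
    u <- runif(nSyn)
    synth <- xm[parents, , drop = FALSE] +
      u * (xm[chosen, , drop = FALSE] - xm[parents, , drop = FALSE])
    rownames(synth) <- sprintf("smote%03d", seq_len(nSyn))

    ids <- colData(se)$subject_id
    cdOrig <- colData(se)
    if (!"smote_parent" %in% names(cdOrig)) {
      cdOrig$smote_parent <- NA_character_
      cdOrig$smote_neighbor <- NA_character_
    }
    cdSyn <- DataFrame(subject_id = rownames(synth),
                       label = factor(minority, levels(xy$y)),
                       is_synthetic = TRUE,
                       smote_parent = ids[minIdx][parents],
                       smote_neighbor = ids[minIdx][chosen])
    ## carry any further metadata columns (e.g. the obstetric covariates,
    ## which are also features and therefore interpolated) or mark NA
    for (nm in setdiff(names(cdOrig), names(cdSyn)))
      cdSyn[[nm]] <- if (nm %in% colnames(synth)) unname(synth[, nm])
                     else rep(NA, nSyn)
    cdSyn <- cdSyn[, names(cdOrig)]
    mat <- cbind(assay(se, "features"), t(synth))
    colnames(mat) <- c(ids, rownames(synth))
    SummarizedExperiment(assays = list(features = mat),
                         rowData = rowData(se),
                         colData = rbind(cdOrig, cdSyn))
  })
}
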