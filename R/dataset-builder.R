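## Assembly of the 203-entry per-recording feature vector:
## 3 channels x 66 window-median EHG descriptors + 5 obstetric covariates,
## and the per-feature rank-sum screening of term vs preterm.

#' Feature names of one recording channel (66 entries)
#'
#' Fixed, documented order: peak-to-peak amplitude in the four analysis
#' bands (4), temporal/spectral descriptors from the whole-band window
#' (18: Teager, MeanF, DF x2, NormEn x3, H/L, D1-D9, SpMR), then the 11
#' non-linear descriptors in each of the four bands (44).
#'
#' @return Character vector of length 66.
#' @export
channelFeatureNames <- function() {
  bands <- ehgBands()
  toks <- .bandToken(bands$f_lo, bands$f_hi)
  c(paste0("app_", toks),
    "teager", "meanf", "df_0p2_1", "df_0p34_1",
    "normen_0p2_0p34", "normen_0p34_0p6", "normen_0p6_1",
    "hl_ratio", paste0("d", 1:9), "spmr",
    as.vector(vapply(toks, function(tk)
      paste0(c("sampen", "fuzen", "spen", "lzbin", "lzmulti", "timerev",
               "kfd", "sd1", "sd2", "sdrr", "sd_ratio"), "_", tk),
      character(11))))
}

#' The full 203-entry feature-vector names
#'
#' S1 block, S2 block, S3 block (66 each, prefixed by channel), then the
#' five obstetric covariates.
#' @return Character vector of length 203.
#' @export
featureVectorNames <- function() {
  ch <- channelFeatureNames()
  c(paste0("S1_", ch), paste0("S2_", ch), paste0("S3_", ch),
    .obstetricNames)
}

## all 66 descriptors of one analysis window; individual failures -> NA
.windowFeatures <- function(win, fs, bands = ehgBands(),
                            config = entropyConfig()) {
  lin <- tryCatch(.linearFeatures(win$bandSamples, fs, bands),
                  error = function(e) setNames(rep(NA_real_, 22L),
                                               channelFeatureNames()[1:22]))
  nl <- tryCatch(
    suppressWarnings(.nonlinearFeatures(win$bandSamples, fs, bands, config)),
    error = function(e) setNames(rep(NA_real_, 44L),
                                 channelFeatureNames()[23:66]))
  c(lin, nl)
}

#' Median-aggregate per-window features of one channel
#'
#' Per-feature median over the analysis windows of a recording channel
#' (robust to occasional aberrant windows); windows where a feature could
#' not be computed are skipped for that feature.
#'
#' @param windowFeatureMatrix numeric matrix, one row per window, one
#'   column per feature.
#' @return Named numeric vector of medians; \code{NA} where a feature had
#'   no valid window.
#' @export
aggregateWindowFeatures <- function(windowFeatureMatrix) {
  m <- as.matrix(windowFeatureMatrix)
  if (nrow(m) < 1L) stop("no analysis windows to aggregate")
  apply(m, 2L, median, na.rm = TRUE)
}

#' Extract the 198 EHG features of one recording
#'
#' Cuts each channel into band-filtered 120-s windows, computes the 66
#' descriptors per window and takes the per-feature median across windows.
#'
#' @param rec an [EHGRecording-class].
#' @param windowS,overlap windowing parameters (see [segmentWindows()]).
#' @param config an [entropyConfig()].
#' @return Named numeric vector of length 198 (3 channels x 66).
#' @export
extractFeatures <- function(rec, windowS = 120, overlap = 0.5,
                            config = entropyConfig()) {
  wins <- segmentWindows(rec, windowS = windowS, overlap = overlap)
  fs <- rec@fs
  out <- lapply(names(wins), function(chn) {
    wm <- do.call(rbind, lapply(wins[[chn]], .windowFeatures, fs = fs,
                                config = config))
    v <- aggregateWindowFeatures(wm)
    names(v) <- paste0(chn, "_", names(v))
    v
  })
  unlist(out)
}

#' Build the cohort feature table
#'
#' Assembles the 203-feature vector of every subject (198 EHG features +
#' 5 obstetric covariates) into a features-by-subjects
#' \code{SummarizedExperiment}.  Subjects with any missing aggregated
#' feature are dropped with a warning.
#'
#' @param cohort an [EHGCohort-class].
#' @param windowS,overlap windowing parameters.
#' @param config an [entropyConfig()].
#' @param verbose report progress every few subjects.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{features} (203 x n), \code{rowData} columns \code{block}
#'   (S1/S2/S3/obstetric) and \code{feature}, and \code{colData} columns
#'   \code{subject_id}, \code{label}, the five obstetric covariates and
#'   \code{is_synthetic}.
#' @export
buildFeatureTable <- function(cohort, windowS = 120, overlap = 0.5,
                              config = entropyConfig(), verbose = FALSE) {
  stopifnot(is(cohort, "EHGCohort"))
  n <- length(cohort)
  fn <- featureVectorNames()
  mat <- matrix(NA_real_, nrow = length(fn), ncol = n,
                dimnames = list(fn, subjectID(cohort)))
  sd_ <- cohort@subjectData
  for (i in seq_len(n)) {
    rec <- cohort[[i]]
    ehg <- extractFeatures(rec, windowS = windowS, overlap = overlap,
                           config = config)
    obst <- as.numeric(sd_[i, .obstetricNames])
    v <- c(ehg, setNames(obst, .obstetricNames))
    if (!identical(names(v), fn))
      stop("feature naming mismatch for subject ", rec@subjectID)
    mat[, i] <- v
    if (verbose && i %% 10L == 0L)
      message(sprintf("  features: %d/%d subjects", i, n))
  }
  keep <- colSums(is.na(mat)) == 0L
  if (!all(keep))
    warning(sprintf("dropping %d subject(s) with missing features: %s",
                    sum(!keep), paste(colnames(mat)[!keep], collapse = ", ")))
  block <- rep(c("S1", "S2", "S3", "obstetric"), c(66L, 66L, 66L, 5L))
  SummarizedExperiment(
    assays = list(features = mat[, keep, drop = FALSE]),
    rowData = DataFrame(block = block,
                        feature = sub("^S[123]_", "", fn)),
    colData = DataFrame(subject_id = sd_$subject_id[keep],
                        label = factor(sd_$label[keep],
                                       c("term", "preterm")),
                        sd_[keep, .obstetricNames],
                        is_synthetic = FALSE))
}

## features-by-subjects matrix + labels from a feature SummarizedExperiment
.tableXY <- function(se) {
  list(x = t(assay(se, "features")),
       y = factor(colData(se)$label, c("term", "preterm")))
}

#' Per-feature Wilcoxon rank-sum screening
#'
#' Two-sided independent-samples rank-sum test of every feature between
#' term and preterm subjects, uncorrected by default (the screening is
#' descriptive, not a filter: downstream subset selection always starts
#' from all features).  SMOTE-synthetic rows are excluded by construction.
#'
#' @param se a feature \code{SummarizedExperiment} from
#'   [buildFeatureTable()] (balanced tables are screened on their original
#'   rows only).
#' @param alpha significance level (default 0.05).
#' @param adjust \code{"none"} (default, faithful to the descriptive
#'   protocol) or \code{"BH"} for Benjamini-Hochberg.
#' @return data.frame with \code{feature}, \code{p_value},
#'   \code{significant} and \code{stars} (\code{*}, \code{**},
#'   \code{***} at p < 0.05, 0.005, 0.0005).
#' @export
ranksumScreen <- function(se, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if ("is_synthetic" %in% names(colData(se)))
    se <- se[, !colData(se)$is_synthetic]
  xy <- .tableXY(se)
  if (nlevels(droplevels(xy$y)) < 2L || min(table(xy$y)) < 2L)
    stop("screening needs at least 2 subjects in each class")
  p <- apply(xy$x, 2L, function(v)
    suppressWarnings(wilcox.test(v[xy$y == "preterm"],
                                 v[xy$y == "term"])$p.value))
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  stars <- ifelse(p < 5e-4, "***", ifelse(p < 5e-3, "**",
                  ifelse(p < 5e-2, "*", "")))
  data.frame(feature = colnames(xy$x), p_value = as.numeric(p),
             significant = p < alpha, stars = stars,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a feature table as delimited text
#'
#' Tab-separated, one row per subject: \code{subject_id}, \code{label},
#' \code{is_synthetic}, then the 203 feature columns in canonical order.
#'
#' @param se feature \code{SummarizedExperiment}.
#' @param path file path.
#' @return \code{writeFeatureTable}: \code{path} invisibly;
#'   \code{readFeatureTable}: the \code{SummarizedExperiment}.
#' @export
writeFeatureTable <- function(se, path) {
  xy <- .tableXY(se)
  df <- data.frame(subject_id = colData(se)$subject_id,
                   label = as.character(xy$y),
                   is_synthetic = colData(se)$is_synthetic,
                   xy$x, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no feature table at '", path, "'")
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  featCols <- setdiff(names(df), c("subject_id", "label", "is_synthetic"))
  mat <- t(as.matrix(df[, featCols]))
  colnames(mat) <- df$subject_id
  obst <- df[, intersect(.obstetricNames, featCols)]
  SummarizedExperiment(
    assays = list(features = mat),
    colData = DataFrame(subject_id = df$subject_id,
                        label = factor(df$label, c("term", "preterm")),
                        obst,
                        is_synthetic = df$is_synthetic))
}
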