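#' Three-channel electrohysterogram recording
#'
#' Container for one abdominal-surface uterine EMG recording: three bipolar
#' channels (S1, S2, S3) sampled at a common rate, the intervals judged
#' physiologically usable, and the delivery outcome label.
#'
#' @slot subjectID single character identifier.
#' @slot channels numeric matrix with one column per bipolar channel
#'   (\code{S1}, \code{S2}, \code{S3}), samples in mV.
#' @slot fs sampling rate in Hz.
#' @slot usableSegments two-column matrix of half-open \code{[start, end)}
#'   intervals in seconds; sorted and non-overlapping.
#' @slot label \code{"term"} or \code{"preterm"}.
#'
#' @seealso [generateCohort()], [segmentWindows()], [extractFeatures()]
#' @export
setClass("EHGRecording",
  slots = c(
    subjectID = "character",
    channels = "matrix",
    fs = "numeric",
    usableSegments = "matrix",
    label = "character"
  )
)

setValidity("EHGRecording", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L)
    msg <- c(msg, "subjectID must be a single string")
  if (ncol(object@channels) != 3L)
    msg <- c(msg, "channels must have exactly 3 columns (S1, S2, S3)")
  if (!identical(colnames(object@channels), c("S1", "S2", "S3")))
    msg <- c(msg, "channel columns must be named S1, S2, S3")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!length(object@label) == 1L || !object@label %in% c("term", "preterm"))
    msg <- c(msg, "label must be 'term' or 'preterm'")
  seg <- object@usableSegments
  if (ncol(seg) != 2L) {
    msg <- c(msg, "usableSegments must be a two-column matrix")
  } else if (nrow(seg) > 0L) {
    dur <- nrow(object@channels) / object@fs
    if (any(seg[, 1L] < 0) || any(seg[, 2L] > dur + 1e-9))
      msg <- c(msg, "usableSegments must lie within [0, duration]")
    if (any(seg[, 2L] <= seg[, 1L]))
      msg <- c(msg, "usableSegments must have end > start")
    if (nrow(seg) > 1L && any(diff(seg[, 1L]) <= 0))
      msg <- c(msg, "usableSegments must be sorted by start time")
    if (nrow(seg) > 1L && any(seg[-1L, 1L] < seg[-nrow(seg), 2L]))
      msg <- c(msg, "usableSegments must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EHGRecording
#'
#' @param subjectID single character identifier.
#' @param channels numeric matrix (samples x 3); columns are renamed
#'   \code{S1}, \code{S2}, \code{S3}.
#' @param fs sampling rate (Hz).
#' @param label \code{"term"} or \code{"preterm"}.
#' @param usableSegments two-column matrix of \code{[start, end)} intervals
#'   in seconds; default the full record.
#' @return An [EHGRecording-class] object.
#' @examples
#' x <- matrix(rnorm(3 * 4800, sd = 0.02), ncol = 3)
#' rec <- EHGRecording("demo", x, fs = 20, label = "term")
#' rec
#' @export
EHGRecording <- function(subjectID, channels, fs = 20, label = "term",
                         usableSegments = NULL) {
  channels <- as.matrix(channels)
  colnames(channels) <- c("S1", "S2", "S3")[seq_len(ncol(channels))]
  if (is.null(usableSegments))
    usableSegments <- matrix(c(0, nrow(channels) / fs), ncol = 2L)
  storage.mode(usableSegments) <- "double"
  new("EHGRecording", subjectID = as.character(subjectID),
      channels = channels, fs = fs,
      usableSegments = usableSegments, label = label)
}

#' Cohort of EHG recordings with obstetric covariates
#'
#' A list of [EHGRecording-class] objects together with one row of subject
#' metadata each: outcome label and the five obstetric covariates
#' (maternal age, parity, abortions, weight, gestational week at recording).
#'
#' @slot recordings list of [EHGRecording-class] objects.
#' @slot subjectData data.frame with columns \code{subject_id},
#'   \code{label}, \code{maternal_age}, \code{parity}, \code{abortions},
#'   \code{weight}, \code{wog}; one row per recording, same order.
#' @export
setClass("EHGCohort",
  slots = c(recordings = "list", subjectData = "data.frame")
)

.obstetricNames <- c("maternal_age", "parity", "abortions", "weight", "wog")

setValidity("EHGCohort", function(object) {
  msg <- character()
  need <- c("subject_id", "label", .obstetricNames)
  if (!all(need %in% names(object@subjectData)))
    msg <- c(msg, paste("subjectData must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(object@recordings) != nrow(object@subjectData))
    msg <- c(msg, "one subjectData row is required per recording")
  if (!all(vapply(object@recordings, is, logical(1), "EHGRecording")))
    msg <- c(msg, "recordings must all be EHGRecording objects")
  if (length(msg) == 0L && length(object@recordings) > 0L) {
    ids <- vapply(object@recordings, function(r) r@subjectID, character(1))
    if (!identical(ids, as.character(object@subjectData$subject_id)))
      msg <- c(msg, "subjectData order must match recording subject IDs")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EHGCohort
#' @param recordings list of [EHGRecording-class] objects.
#' @param subjectData data.frame of per-subject metadata (see
#'   [EHGCohort-class]).
#' @return An [EHGCohort-class] object.
#' @export
EHGCohort <- function(recordings, subjectData) {
  new("EHGCohort", recordings = recordings,
      subjectData = as.data.frame(subjectData))
}

#' @describeIn EHGCohort-class number of subjects.
#' @param x an \code{EHGCohort}.
#' @export
setMethod("length", "EHGCohort", function(x) length(x@recordings))

#' @describeIn EHGCohort-class extract one recording.
#' @param i subject index.
#' @export
setMethod("[[", "EHGCohort", function(x, i) x@recordings[[i]])

setMethod("show", "EHGRecording", function(object) {
  dur <- nrow(object@channels) / object@fs
  cat(sprintf(
    "EHGRecording '%s' (%s): 3 channels, %.0f s at %g Hz, %d usable segment(s)\n",
    object@subjectID, object@label, dur, object@fs,
    nrow(object@usableSegments)))
})

setMethod("show", "EHGCohort", function(object) {
  tab <- table(factor(object@subjectData$label, c("term", "preterm")))
  cat(sprintf("EHGCohort: %d subjects (%d term, %d preterm)\n",
              length(object@recordings), tab[["term"]], tab[["preterm"]]))
})

#' Accessors for EHG objects
#'
#' @param object an [EHGRecording-class] or [EHGCohort-class].
#' @return \code{subjectID}: character ID(s); \code{samplingRate}: Hz;
#'   \code{channelMatrix}: the samples-by-3 matrix (mV);
#'   \code{usableSegments}: two-column matrix of seconds;
#'   \code{recordingLabel}: outcome label(s); \code{subjectData}: the cohort
#'   metadata data.frame.
#' @name ehg-accessors
NULL

#' @rdname ehg-accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
#' @rdname ehg-accessors
#' @export
setMethod("subjectID", "EHGRecording", function(object) object@subjectID)
#' @rdname ehg-accessors
#' @export
setMethod("subjectID", "EHGCohort",
          function(object) as.character(object@subjectData$subject_id))

#' @rdname ehg-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname ehg-accessors
#' @export
setMethod("samplingRate", "EHGRecording", function(object) object@fs)

#' @rdname ehg-accessors
#' @export
setGeneric("channelMatrix", function(object) standardGeneric("channelMatrix"))
#' @rdname ehg-accessors
#' @export
setMethod("channelMatrix", "EHGRecording", function(object) object@channels)

#' @rdname ehg-accessors
#' @export
setGeneric("usableSegments", function(object) standardGeneric("usableSegments"))
#' @rdname ehg-accessors
#' @export
setMethod("usableSegments", "EHGRecording",
          function(object) object@usableSegments)

#' @rdname ehg-accessors
#' @export
setGeneric("recordingLabel", function(object) standardGeneric("recordingLabel"))
#' @rdname ehg-accessors
#' @export
setMethod("recordingLabel", "EHGRecording", function(object) object@label)
#' @rdname ehg-accessors
#' @export
setMethod("recordingLabel", "EHGCohort",
          function(object) as.character(object@subjectData$label))

#' @rdname ehg-accessors
#' @export
setGeneric("subjectData", function(object) standardGeneric("subjectData"))
#' @rdname ehg-accessors
#' @export
setMethod("subjectData", "EHGCohort", function(object) object@subjectData)
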