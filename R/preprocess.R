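## Band filtering and windowing.
##
## The four canonical analysis bandwidths: the whole uterine-EMG band
## 0.1-4 Hz, the Fast Wave High band 0.34-4 Hz, the Fast Wave Low band
## 0.2-0.34 Hz and the noise-robust FWH sub-band 0.34-1 Hz.  Filtering is a
## 4th-order Butterworth applied forward-backward (zero phase), the usual
## convention in the uterine-EMG literature, applied to whole usable
## segments before windowing so windows carry no per-window edge
## transients.

#' The four canonical EHG analysis bands
#'
#' @return A data.frame with columns \code{name} (\code{B_whole},
#'   \code{B_fwh}, \code{B_fwl}, \code{B_fwh1}), \code{f_lo} and
#'   \code{f_hi} in Hz.
#' @export
ehgBands <- function() {
  data.frame(name = c("B_whole", "B_fwh", "B_fwl", "B_fwh1"),
             f_lo = c(0.1, 0.34, 0.2, 0.34),
             f_hi = c(4, 4, 0.34, 1),
             stringsAsFactors = FALSE)
}

## short tokens used in feature names, e.g. app_0p2_0p34
.bandToken <- function(fLo, fHi) {
  tok <- function(v) vapply(v, function(x) sub("\\.", "p", format(x)),
                            character(1))
  paste0(tok(fLo), "_", tok(fHi))
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (\code{signal::filtfilt}), giving zero phase distortion and an
#' effective 8th-order magnitude response.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate (Hz).
#' @param fLo,fHi band edges (Hz), \code{0 < fLo < fHi < fs/2}.
#' @param order filter order (default 4).
#' @return Filtered signal, same length as \code{x}.
#' @examples
#' y <- bandpassFilter(rnorm(2400), fs = 20, fLo = 0.34, fHi = 1)
#' @export
bandpassFilter <- function(x, fs, fLo, fHi, order = 4) {
  if (!(fLo > 0 && fLo < fHi && fHi < fs / 2))
    stop("band edges must satisfy 0 < fLo < fHi < fs/2")
  if (length(x) <= 3 * (2 * order + 1))
    stop(sprintf("signal too short to filter: %d samples (need > %d)",
                 length(x), 3 * (2 * order + 1)))
  bt <- signal::butter(order, c(fLo, fHi) / (fs / 2), type = "pass")
  signal::filtfilt(bt, x)
}

#' Cut a recording into band-filtered analysis windows
#'
#' Each usable segment of each channel is filtered into the four analysis
#' bands and then cut into 120-s windows advancing by 60 s (50 % overlap).
#' Windows never span a non-usable gap; segments shorter than one window
#' contribute nothing.
#'
#' @param rec an [EHGRecording-class].
#' @param windowS window length in seconds (default 120).
#' @param overlap fractional overlap between consecutive windows
#'   (default 0.5).
#' @param bands band table as returned by [ehgBands()].
#' @return A list with one element per channel (\code{S1}, \code{S2},
#'   \code{S3}); each is a list of windows, each window a list with
#'   \code{channelId}, \code{windowIndex}, \code{startS} and
#'   \code{bandSamples} (named list of band-filtered sample vectors of
#'   length \code{round(windowS * fs)}).
#' @examples
#' rec <- generateCohort(synthCohortConfig(1, 1, durationS = 240,
#'                                         seed = 1))[[1]]
#' w <- segmentWindows(rec)
#' length(w$S1)  # floor((240 - 120)/60) + 1 = 3 windows
#' @export
segmentWindows <- function(rec, windowS = 120, overlap = 0.5,
                           bands = ehgBands()) {
  stopifnot(is(rec, "EHGRecording"))
  fs <- rec@fs
  nWin <- round(windowS * fs)
  step <- round(windowS * (1 - overlap) * fs)
  seg <- rec@usableSegments
  segLenS <- seg[, 2] - seg[, 1]
  if (!any(segLenS >= windowS))
    stop(sprintf(
      "no usable window of %g s fits; usable segment lengths (s): %s",
      windowS, paste(sprintf("%.1f", segLenS), collapse = ", ")))
  chNames <- colnames(rec@channels)
  out <- setNames(vector("list", length(chNames)), chNames)
  for (ch in seq_along(chNames)) {
    wins <- list()
    wi <- 0L
    for (si in seq_len(nrow(seg))) {
      k0 <- ceiling(seg[si, 1] * fs - 1e-9)        # 0-based first sample
      k1 <- ceiling(seg[si, 2] * fs - 1e-9) - 1L   # 0-based last sample
      nSeg <- k1 - k0 + 1L
      if (nSeg < nWin) next
      raw <- rec@channels[(k0 + 1L):(k1 + 1L), ch]
      filt <- lapply(seq_len(nrow(bands)), function(b)
        bandpassFilter(raw, fs, bands$f_lo[b], bands$f_hi[b]))
      names(filt) <- bands$name
      s <- 0L
      while (s + nWin <= nSeg) {
        wi <- wi + 1L
        wins[[wi]] <- list(
          channelId = chNames[ch],
          windowIndex = wi,
          startS = (k0 + s) / fs,
          bandSamples = lapply(filt, function(v) v[(s + 1L):(s + nWin)]))
        s <- s + step
      }
    }
    out[[ch]] <- wins
  }
  out
}
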