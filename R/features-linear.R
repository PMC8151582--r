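## Temporal and spectral window descriptors.
##
## Spectral descriptors are computed from a Welch estimate of the
## whole-band (0.1-4 Hz) filtered window; peak-to-peak amplitude is
## computed per analysis band and the Teager energy on the whole-band time
## series.  Band conventions (config-exposed defaults): mean frequency over
## 0.1-1 Hz, dominant frequency over 0.2-1 and 0.34-1 Hz, deciles over
## 0.34-1 Hz, normalised energies of 0.2-0.34 / 0.34-0.6 / 0.6-1 Hz over
## total 0.1-4 Hz power, H/L ratio = P(0.34-1)/P(0.2-0.34), spectral moment
## ratio M(-1)/M(5) over 0.1-1 Hz.

#' Peak-to-peak amplitude
#' @param x numeric samples (mV).
#' @return \code{max(x) - min(x)} (mV).
#' @export
peakToPeak <- function(x) {
  if (length(x) == 0L) stop("empty signal")
  max(x) - min(x)
}

#' Mean Teager-Kaiser energy
#'
#' Mean of the discrete Teager-Kaiser operator
#' \eqn{\psi[n] = x[n]^2 - x[n-1] x[n+1]} over interior samples; sensitive
#' to both amplitude and instantaneous frequency.
#' @param x numeric samples (length >= 3).
#' @return Mean operator value (mV^2).
#' @export
teagerEnergy <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
}

#' Welch power spectral density estimate
#'
#' Hamming-tapered Welch estimate with 50 % segment overlap, one-sided and
#' scaled so that the integral of the PSD over frequency equals the signal
#' power (Parseval-consistent).
#'
#' @param x numeric samples.
#' @param fs sampling rate (Hz).
#' @param segLength samples per Welch segment (default 1024; \code{x} must
#'   be at least this long).
#' @param overlap fractional segment overlap (default 0.5).
#' @return An object of class \code{SpectralEstimate}: list with
#'   \code{freqs} (Hz, 0 to fs/2) and \code{psd} (mV^2/Hz).
#' @examples
#' spec <- estimatePSD(rnorm(2400), fs = 20)
#' sum(spec$psd) * diff(spec$freqs[1:2])  # ~ 1, the signal variance
#' @export
estimatePSD <- function(x, fs, segLength = 1024, overlap = 0.5) {
  n <- length(x)
  if (n < segLength)
    stop(sprintf("signal length %d shorter than Welch segment length %d",
                 n, segLength))
  step <- max(1L, round(segLength * (1 - overlap)))
  starts <- seq(1L, n - segLength + 1L, by = step)
  k <- 0:(segLength - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (segLength - 1))  # Hamming
  U <- sum(w^2)
  half <- segLength %/% 2 + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)] * w
    X <- fft(seg)
    P <- Mod(X[seq_len(half)])^2 / (U * fs)
    P[2:(half - 1L)] <- 2 * P[2:(half - 1L)]   # fold negative frequencies
    acc <- acc + P
  }
  out <- list(freqs = (seq_len(half) - 1L) * fs / segLength,
              psd = acc / length(starts))
  class(out) <- "SpectralEstimate"
  out
}

#' @export
print.SpectralEstimate <- function(x, ...) {
  cat(sprintf("SpectralEstimate: %d bins, 0-%.3g Hz, df = %.4g Hz\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

## indices of bins inside [lo, hi]; halfOpen drops the hi-edge bin
.bandIdx <- function(spec, lo, hi, halfOpen = FALSE) {
  f <- spec$freqs
  if (lo < f[1] - 1e-12 || hi > f[length(f)] + 1e-12)
    stop("band outside the estimated frequency grid")
  if (halfOpen) which(f >= lo - 1e-12 & f < hi - 1e-12)
  else which(f >= lo - 1e-12 & f <= hi + 1e-12)
}

## integrated power (mV^2) in a band
.bandPower <- function(spec, lo, hi, halfOpen = FALSE) {
  idx <- .bandIdx(spec, lo, hi, halfOpen)
  sum(spec$psd[idx]) * (spec$freqs[2] - spec$freqs[1])
}

#' Mean (power-weighted) frequency
#' @param spec a [estimatePSD()] result.
#' @param band two-element band in Hz (default \code{c(0.1, 1)}).
#' @return Hz.
#' @export
meanFrequency <- function(spec, band = c(0.1, 1)) {
  idx <- .bandIdx(spec, band[1], band[2])
  p <- spec$psd[idx]
  if (sum(p) <= 0) stop("zero in-band power")
  sum(spec$freqs[idx] * p) / sum(p)
}

#' Dominant frequency
#'
#' Frequency of the maximal in-band PSD bin; ties resolve to the lowest
#' frequency.
#' @inheritParams meanFrequency
#' @param band two-element band in Hz.
#' @return Hz.
#' @export
dominantFrequency <- function(spec, band) {
  idx <- .bandIdx(spec, band[1], band[2])
  p <- spec$psd[idx]
  if (sum(p) <= 0) stop("zero in-band power")
  spec$freqs[idx][which.max(p)]
}

#' Power-spectrum deciles D1..D9
#'
#' \code{dk} is the smallest grid frequency at which the cumulative in-band
#' power reaches k/10 of the total in-band power; D5 is the median
#' frequency.
#' @inheritParams meanFrequency
#' @param band two-element band in Hz (default \code{c(0.34, 1)}).
#' @return Named numeric vector \code{d1}..\code{d9} (Hz), non-decreasing.
#' @export
spectrumDeciles <- function(spec, band = c(0.34, 1)) {
  idx <- .bandIdx(spec, band[1], band[2])
  p <- spec$psd[idx]
  tot <- sum(p)
  if (tot <= 0) stop("zero in-band power")
  cum <- cumsum(p) / tot
  f <- spec$freqs[idx]
  d <- vapply(1:9, function(k) f[which(cum >= k / 10 - 1e-12)[1]],
              numeric(1))
  names(d) <- paste0("d", 1:9)
  d
}

#' Normalised band energies
#'
#' Power in each sub-band divided by total power in the denominator band.
#' @inheritParams meanFrequency
#' @param subBands list of two-element bands (Hz); defaults
#'   0.2-0.34, 0.34-0.6, 0.6-1 Hz.
#' @param denomBand denominator band (default 0.1-4 Hz).
#' @return Numeric fractions in \code{[0, 1]}, one per sub-band; their sum
#'   never exceeds 1 for disjoint sub-bands inside the denominator band.
#' @export
normalizedEnergies <- function(spec,
    subBands = list(c(0.2, 0.34), c(0.34, 0.6), c(0.6, 1)),
    denomBand = c(0.1, 4)) {
  tot <- .bandPower(spec, denomBand[1], denomBand[2])
  if (tot <= 0) stop("zero power in denominator band")
  vapply(seq_along(subBands), function(i) {
    b <- subBands[[i]]
    ## half-open sub-bands keep adjacent sub-bands disjoint; the last one
    ## keeps its upper edge
    .bandPower(spec, b[1], b[2], halfOpen = i < length(subBands)) / tot
  }, numeric(1))
}

#' High/low frequency energy ratio
#'
#' Power in 0.34-1 Hz divided by power in 0.2-0.34 Hz (Fast Wave High over
#' Fast Wave Low energy).
#' @inheritParams meanFrequency
#' @return Unitless ratio.
#' @export
hlRatio <- function(spec) {
  lo <- .bandPower(spec, 0.2, 0.34, halfOpen = TRUE)
  if (lo <= 0) stop("zero power in 0.2-0.34 Hz band")
  .bandPower(spec, 0.34, 1) / lo
}

#' Spectral moment ratio M(-1)/M(5)
#'
#' Dimitrov-style spectral index \eqn{M_{-1}/M_5} with
#' \eqn{M_k = \sum f^k P(f)} over the band (f in Hz); decreases strictly as
#' spectral content shifts to higher frequencies.
#' @inheritParams meanFrequency
#' @param band two-element band in Hz (default \code{c(0.1, 1)}).
#' @return Unitless ratio.
#' @export
spectralMomentRatio <- function(spec, band = c(0.1, 1)) {
  idx <- .bandIdx(spec, band[1], band[2])
  p <- spec$psd[idx]
  if (sum(p) <= 0) stop("zero in-band power")
  f <- spec$freqs[idx]
  keep <- f > 0
  sum(p[keep] / f[keep]) / sum(p[keep] * f[keep]^5)
}

## the 22 temporal + spectral descriptors of one analysis window
.linearFeatures <- function(bandSamples, fs, bands = ehgBands()) {
  app <- vapply(seq_len(nrow(bands)), function(b)
    peakToPeak(bandSamples[[bands$name[b]]]), numeric(1))
  names(app) <- paste0("app_", .bandToken(bands$f_lo, bands$f_hi))
  whole <- bandSamples[["B_whole"]]
  spec <- estimatePSD(whole, fs)
  nen <- normalizedEnergies(spec)
  names(nen) <- c("normen_0p2_0p34", "normen_0p34_0p6", "normen_0p6_1")
  c(app,
    teager = teagerEnergy(whole),
    meanf = meanFrequency(spec),
    df_0p2_1 = dominantFrequency(spec, c(0.2, 1)),
    df_0p34_1 = dominantFrequency(spec, c(0.34, 1)),
    nen,
    hl_ratio = hlRatio(spec),
    spectrumDeciles(spec),
    spmr = spectralMomentRatio(spec))
}
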