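## Non-linear window descriptors, each computed in all four analysis bands:
## sample entropy, fuzzy entropy, spectral entropy, Lempel-Ziv complexity
## (binary and 6-state), time reversibility, Katz fractal dimension and
## Poincare-plot dispersions.  Entropy parameters m = 2, r = 0.15 x window
## SD and fuzzy exponent 2 are the conventional uterine-EMG settings and
## are config-exposed.

#' Entropy parameter configuration
#'
#' @param m embedding (template) dimension, >= 1.
#' @param rFactor tolerance as a fraction of the window SD, > 0.
#' @param fuzzyExponent exponent of the fuzzy membership function.
#' @return List of class \code{EntropyConfig}.
#' @export
entropyConfig <- function(m = 2, rFactor = 0.15, fuzzyExponent = 2) {
  if (m < 1) stop("m must be >= 1")
  if (rFactor <= 0) stop("rFactor must be > 0")
  structure(list(m = as.integer(m), rFactor = rFactor,
                 fuzzyExponent = fuzzyExponent),
            class = "EntropyConfig")
}

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where B counts Chebyshev-matching template pairs at
#' length m and A at length m + 1, tolerance \code{r = rFactor * sd(x)},
#' self-matches excluded (Richman & Moorman convention: both counts over
#' the same N - m templates).  When no template pair matches at either
#' length the value is undefined; the documented sentinel
#' \code{-log(2 / ((N - m)(N - m - 1)))} (the largest finite estimate at
#' this length) is returned with a warning.
#'
#' @param x numeric samples (length >= 100, non-constant).
#' @param config an [entropyConfig()].
#' @return Unitless non-negative entropy rate estimate.
#' @export
sampleEntropy <- function(x, config = entropyConfig()) {
  n <- length(x)
  if (n < 100L) stop("need at least 100 samples")
  s <- sd(x)
  if (s == 0) stop("constant signal: sample entropy undefined (SD = 0)")
  r <- config$rFactor * s
  ab <- .sampenCounts(as.numeric(x), config$m, r)
  if (ab[1] == 0 || ab[2] == 0) {
    nt <- n - config$m
    warning("no matching templates; returning sentinel upper bound")
    return(-log(2 / (nt * (nt - 1))))
  }
  -log(ab[1] / ab[2])
}

#' Fuzzy entropy
#'
#' \eqn{-\ln(\phi_{m+1}/\phi_m)} with mean-centred templates and soft
#' membership \eqn{\exp(-d^n / r)} of the Chebyshev distance d; invariant
#' to constant offsets by construction.  A constant signal has identical
#' centred templates (d = 0 everywhere) and returns exactly 0.
#'
#' @inheritParams sampleEntropy
#' @return Unitless non-negative value.
#' @export
fuzzyEntropy <- function(x, config = entropyConfig()) {
  n <- length(x)
  if (n < 100L) stop("need at least 100 samples")
  s <- sd(x)
  if (s == 0) return(0)
  r <- config$rFactor * s
  v <- .fuzenValue(as.numeric(x), config$m, r, config$fuzzyExponent)
  if (is.na(v)) {
    warning("fuzzy membership sums vanished; returning sentinel 0")
    return(0)
  }
  v
}

#' Spectral entropy
#'
#' Shannon entropy of the normalised in-band power spectrum divided by the
#' log of the number of in-band bins: 0 for a pure line, 1 for a perfectly
#' flat spectrum.
#'
#' @param x numeric samples.
#' @param fs sampling rate (Hz).
#' @param band two-element band (Hz) over which to normalise.
#' @param segLength Welch segment length; capped at \code{length(x)}.
#' @return Fraction in \code{[0, 1]}.
#' @export
spectralEntropy <- function(x, fs, band = c(0.1, 4), segLength = 1024) {
  spec <- estimatePSD(x, fs, segLength = min(segLength, length(x)))
  idx <- .bandIdx(spec, band[1], band[2])
  p <- spec$psd[idx]
  tot <- sum(p)
  if (tot <= 0) stop("zero in-band power")
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(idx))
}

#' Lempel-Ziv complexity (LZ76, exhaustive parsing)
#'
#' The signal is symbolised (binary: above-median threshold, ties to the
#' lower symbol; 6-state: equiprobable quantile bins, ties to the lower
#' bin), parsed into c exhaustive-history components, and normalised as
#' \eqn{C = c \log_\alpha(N) / N} with alphabet size \eqn{\alpha} equal to
#' the number of states, so binary and 6-state values are comparable
#' (roughly 1 for iid symbols).
#'
#' @param x numeric samples (length >= 10).
#' @param nStates alphabet size, 2 or 6.
#' @return Unitless normalised complexity.
#' @seealso [lz76Count()] for the raw component count of a pre-symbolised
#'   sequence.
#' @export
lempelZiv <- function(x, nStates = 2) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (!nStates %in% c(2, 6)) stop("nStates must be 2 or 6")
  if (length(unique(x)) == 1L)
    stop("degenerate quantization: all samples equal")
  if (nStates == 2) {
    s <- as.integer(x > median(x))
  } else {
    breaks <- quantile(x, probs = (1:5) / 6, names = FALSE)
    s <- findInterval(x, unique(breaks), left.open = TRUE)
  }
  c_ <- lz76Count(s)
  c_ * (log(n) / log(nStates)) / n
}

#' LZ76 exhaustive-parse component count
#'
#' Number of components of the exhaustive-history Lempel-Ziv parse of a
#' symbol sequence.
#'
#' @param symbols integer vector of symbols (any alphabet).
#' @return Integer component count.
#' @examples
#' lz76Count(as.integer(strsplit("0001101001000101", "")[[1]]))  # 6
#' @export
lz76Count <- function(symbols) {
  .lz76CountC(as.integer(symbols))
}

#' Time reversibility
#'
#' Third moment of lagged differences,
#' \eqn{(N - \ell)^{-1} \sum (x[n] - x[n-\ell])^3}; zero for
#' time-symmetric signals, sign-antisymmetric under amplitude inversion.
#'
#' @param x numeric samples.
#' @param lag lag in samples (default 1).
#' @return Value in mV^3.
#' @export
timeReversibility <- function(x, lag = 1) {
  if (length(x) <= lag) stop("signal not longer than lag")
  mean(diff(x, lag = lag)^3)
}

#' Katz fractal dimension
#'
#' \eqn{KFD = \log_{10}(n) / (\log_{10}(n) + \log_{10}(d/L))} with n the
#' number of steps, L the summed Euclidean step length of the waveform
#' graph (abscissa unit = 1 sample) and d the maximum distance from the
#' first point; exactly 1 for any straight line.
#'
#' @param x numeric samples (length >= 2, non-constant).
#' @return Unitless dimension >= 1.
#' @export
katzFD <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (max(x) == min(x)) stop("constant signal: KFD undefined")
  d <- max(sqrt((seq_len(n) - 1)^2 + (x - x[1])^2))
  if (n == 2L) return(1)
  L <- sum(sqrt(1 + diff(x)^2))
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}

#' Poincare-plot dispersions
#'
#' Dispersions of the lag-1 return map x[n] vs x[n-1]:
#' \code{SD1^2 = var(diff(x))/2} (short-term), \code{SD2^2 = 2 var(x) -
#' SD1^2} (long-term), \code{SDRR = sqrt((SD1^2 + SD2^2)/2)} and the
#' randomness index \code{SD1/SD2}.
#'
#' @param x numeric samples (length >= 3, non-constant).
#' @return Named list with \code{sd1}, \code{sd2}, \code{sdrr},
#'   \code{sdRatio} (all mV except the unitless ratio).  \code{sdRatio} is
#'   \code{NA} with a warning when SD2 = 0.
#' @export
poincareDescriptors <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples")
  if (sd(x) == 0) stop("constant signal: Poincare descriptors undefined")
  sd1sq <- var(diff(x)) / 2
  sd2sq <- max(0, 2 * var(x) - sd1sq)
  sd1 <- sqrt(sd1sq)
  sd2 <- sqrt(sd2sq)
  ratio <- if (sd2 == 0) {
    warning("SD2 = 0; SD1/SD2 reported as NA")
    NA_real_
  } else sd1 / sd2
  list(sd1 = sd1, sd2 = sd2, sdrr = sqrt((sd1sq + sd2sq) / 2),
       sdRatio = ratio)
}

## the 44 non-linear descriptors of one analysis window (11 per band)
.nonlinearFeatures <- function(bandSamples, fs, bands = ehgBands(),
                               config = entropyConfig()) {
  out <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    v <- bandSamples[[bands$name[b]]]
    tok <- .bandToken(bands$f_lo[b], bands$f_hi[b])
    pc <- poincareDescriptors(v)
    vals <- c(sampleEntropy(v, config),
              fuzzyEntropy(v, config),
              spectralEntropy(v, fs, c(bands$f_lo[b], bands$f_hi[b])),
              lempelZiv(v, 2),
              lempelZiv(v, 6),
              timeReversibility(v),
              katzFD(v),
              pc$sd1, pc$sd2, pc$sdrr, pc$sdRatio)
    names(vals) <- paste0(
      c("sampen", "fuzen", "spen", "lzbin", "lzmulti", "timerev", "kfd",
        "sd1", "sd2", "sdrr", "sd_ratio"), "_", tok)
    out <- c(out, vals)
  }
  out
}
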