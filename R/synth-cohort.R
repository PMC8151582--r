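## Synthetic EHG cohort generator.
##
## Signals are pink (1/f) background noise, independent per channel, plus
## intermittent band-limited bursts shared across channels with per-channel
## multiplicative gain jitter.  Bursts arrive as a Poisson process; each is
## band-pass-filtered white noise under a Hanning envelope, centred at a
## class-dependent frequency and scaled by a class-dependent amplitude.
## Later gestational age at recording slightly raises burst amplitude so the
## Wog covariate carries signal.  This emulates the burst phenomenology of
## real uterine EMG, not its physiology.

#' Configuration for the synthetic EHG cohort generator
#'
#' Defaults encode the emulated study conditions: 20 Hz sampling, 1800 s
#' recordings, obstetric covariate distributions matching the published
#' term/preterm demographics, and a modest preterm shift of burst spectral
#' content towards higher frequencies with larger amplitude.
#'
#' @param nTerm,nPreterm subjects per class (each >= 1).
#' @param durationS recording duration in seconds (>= 240, i.e. at least
#'   two 120-s analysis windows).
#' @param fs sampling rate in Hz (the emulated acquisition uses 20).
#' @param burstRate expected bursts per minute.
#' @param burstCenterFreqTerm,burstCenterFreqPreterm burst carrier centre
#'   frequency (Hz), per class; must lie in (0, fs/2).
#' @param burstAmplitudeTerm,burstAmplitudePreterm burst envelope peak
#'   amplitude (mV), per class.
#' @param backgroundNoiseLevel SD of the pink background noise (mV).
#' @param channelGainSpread SD of the per-channel multiplicative burst gain
#'   around 1.
#' @param obstetricMeansTerm,obstetricSdsTerm,obstetricMeansPreterm,obstetricSdsPreterm
#'   named length-5 vectors (maternal_age, parity, abortions, weight, wog)
#'   of truncated-Gaussian means and SDs; defaults follow the published
#'   cohort demographics.
#' @param artifactGapRate expected non-usable artifact gaps per minute
#'   (0 = full record usable, the default).
#' @param seed integer seed; identical configurations and seeds yield
#'   bit-identical cohorts.
#' @return A validated list of class \code{SyntheticCohortConfig}.
#' @examples
#' cfg <- synthCohortConfig(nTerm = 4, nPreterm = 2, durationS = 240, seed = 1)
#' @export
synthCohortConfig <- function(nTerm, nPreterm, durationS = 1800, fs = 20,
    burstRate = 0.5,
    burstCenterFreqTerm = 0.35, burstCenterFreqPreterm = 0.45,
    burstAmplitudeTerm = 0.08, burstAmplitudePreterm = 0.12,
    backgroundNoiseLevel = 0.02, channelGainSpread = 0.1,
    obstetricMeansTerm = c(maternal_age = 29.33, parity = 0.40,
                           abortions = 0.23, weight = 68.55, wog = 26.95),
    obstetricSdsTerm = c(maternal_age = 4.34, parity = 0.74,
                         abortions = 0.61, weight = 10.55, wog = 4.19),
    obstetricMeansPreterm = c(maternal_age = 29.08, parity = 0.41,
                              abortions = 0.26, weight = 66.82, wog = 27.59),
    obstetricSdsPreterm = c(maternal_age = 5.26, parity = 0.64,
                            abortions = 0.60, weight = 11.24, wog = 3.72),
    artifactGapRate = 0, seed = 1) {
  cfg <- list(nTerm = nTerm, nPreterm = nPreterm, durationS = durationS,
    fs = fs, burstRate = burstRate,
    burstCenterFreqTerm = burstCenterFreqTerm,
    burstCenterFreqPreterm = burstCenterFreqPreterm,
    burstAmplitudeTerm = burstAmplitudeTerm,
    burstAmplitudePreterm = burstAmplitudePreterm,
    backgroundNoiseLevel = backgroundNoiseLevel,
    channelGainSpread = channelGainSpread,
    obstetricMeansTerm = obstetricMeansTerm,
    obstetricSdsTerm = obstetricSdsTerm,
    obstetricMeansPreterm = obstetricMeansPreterm,
    obstetricSdsPreterm = obstetricSdsPreterm,
    artifactGapRate = artifactGapRate, seed = seed)
  .checkField <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid config field '%s': %s", field, what),
                  call. = FALSE)
  }
  .checkField(is.numeric(nTerm) && nTerm >= 1, "nTerm", "must be >= 1")
  .checkField(is.numeric(nPreterm) && nPreterm >= 1, "nPreterm",
              "must be >= 1")
  .checkField(durationS >= 240, "durationS",
              "must be >= 240 s (two analysis windows)")
  .checkField(fs > 0, "fs", "must be positive")
  .checkField(burstRate >= 0, "burstRate", "must be non-negative")
  .checkField(burstCenterFreqTerm > 0 && burstCenterFreqTerm < fs / 2,
              "burstCenterFreqTerm", "must lie in (0, fs/2)")
  .checkField(burstCenterFreqPreterm > 0 && burstCenterFreqPreterm < fs / 2,
              "burstCenterFreqPreterm", "must lie in (0, fs/2)")
  .checkField(burstAmplitudeTerm >= 0, "burstAmplitudeTerm",
              "must be non-negative")
  .checkField(burstAmplitudePreterm >= 0, "burstAmplitudePreterm",
              "must be non-negative")
  .checkField(backgroundNoiseLevel > 0, "backgroundNoiseLevel",
              "must be positive")
  .checkField(channelGainSpread >= 0, "channelGainSpread",
              "must be non-negative")
  for (nm in c("obstetricMeansTerm", "obstetricSdsTerm",
               "obstetricMeansPreterm", "obstetricSdsPreterm"))
    .checkField(length(cfg[[nm]]) == 5L, nm, "must have 5 entries")
  .checkField(length(seed) == 1L && is.finite(seed), "seed",
              "must be a single finite number")
  class(cfg) <- "SyntheticCohortConfig"
  cfg
}

## evaluate expr under a local RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## pink noise (spectral slope -1 in power) with unit SD, length n
.pinkNoise <- function(n) {
  w <- rnorm(n)
  X <- fft(w)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

.truncNorm <- function(mean, sd, lo, hi) {
  for (i in seq_len(50L)) {
    v <- rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

.drawObstetric <- function(means, sds) {
  means <- as.numeric(means); sds <- as.numeric(sds)
  c(maternal_age = .truncNorm(means[1], sds[1], 18, 47),
    parity = round(max(0, .truncNorm(means[2], sds[2], 0, 6))),
    abortions = round(max(0, .truncNorm(means[3], sds[3], 0, 6))),
    weight = .truncNorm(means[4], sds[4], 40, 120),
    wog = .truncNorm(means[5], sds[5], 22, 37))
}

.burstTrack <- function(nS, fs, rate, f0, amp) {
  durS <- nS / fs
  track <- numeric(nS)
  nBurst <- rpois(1, rate * durS / 60)
  for (b in seq_len(nBurst)) {
    dur <- runif(1, 30, 90)
    nb <- round(dur * fs)
    start <- floor(runif(1, 0, max(1, nS - nb)))
    fc <- f0 * .truncNorm(1, 0.05, 0.8, 1.2)
    lo <- max(0.05, fc - 0.08)
    hi <- min(fc + 0.08, fs / 2 * 0.9)
    carrier <- bandpassFilter(rnorm(nb + 200L), fs, lo, hi)
    carrier <- carrier[101:(100 + nb)]
    carrier <- carrier / max(sd(carrier), .Machine$double.eps)
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nb)))
    idx <- start + seq_len(nb)
    track[idx] <- track[idx] + amp * env * carrier
  }
  track
}

.artifactSegments <- function(durS, gapRate) {
  if (gapRate <= 0) return(matrix(c(0, durS), ncol = 2L))
  nGap <- rpois(1, gapRate * durS / 60)
  if (nGap == 0L) return(matrix(c(0, durS), ncol = 2L))
  starts <- sort(runif(nGap, 0, durS - 30))
  gaps <- cbind(starts, pmin(starts + runif(nGap, 10, 30), durS))
  ## merge overlapping gaps, then take the complement
  merged <- gaps[1, , drop = FALSE]
  for (i in seq_len(nGap)[-1]) {
    if (gaps[i, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], gaps[i, 2])
    else merged <- rbind(merged, gaps[i, ])
  }
  bounds <- c(0, as.vector(t(merged)), durS)
  seg <- matrix(bounds, ncol = 2L, byrow = TRUE)
  seg <- seg[seg[, 2] - seg[, 1] > 1e-9, , drop = FALSE]
  seg
}

#' Generate a synthetic labelled EHG cohort
#'
#' Produces \code{nTerm + nPreterm} three-channel recordings plus obstetric
#' covariates under the model described in the package vignette.  The same
#' configuration (including its seed) always yields a bit-identical cohort.
#'
#' @param config a [synthCohortConfig()] object.
#' @return An [EHGCohort-class].
#' @examples
#' coh <- generateCohort(synthCohortConfig(4, 2, durationS = 240, seed = 7))
#' coh
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SyntheticCohortConfig"))
    stop("config must be created by synthCohortConfig()")
  .withSeed(config$seed, {
    n <- config$nTerm + config$nPreterm
    labels <- rep(c("term", "preterm"), c(config$nTerm, config$nPreterm))
    nS <- round(config$durationS * config$fs)
    recs <- vector("list", n)
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      obst <- if (lab == "term")
        .drawObstetric(config$obstetricMeansTerm, config$obstetricSdsTerm)
      else
        .drawObstetric(config$obstetricMeansPreterm,
                       config$obstetricSdsPreterm)
      f0 <- if (lab == "term") config$burstCenterFreqTerm
            else config$burstCenterFreqPreterm
      amp <- if (lab == "term") config$burstAmplitudeTerm
             else config$burstAmplitudePreterm
      amp <- amp * (1 + 0.02 * (obst[["wog"]] - 27))  # Wog carries signal
      burst <- .burstTrack(nS, config$fs, config$burstRate, f0, amp)
      gains <- pmax(0.1, rnorm(3, 1, config$channelGainSpread))
      ch <- vapply(seq_len(3), function(k)
        config$backgroundNoiseLevel * .pinkNoise(nS) + gains[k] * burst,
        numeric(nS))
      colnames(ch) <- c("S1", "S2", "S3")
      seg <- .artifactSegments(config$durationS, config$artifactGapRate)
      id <- sprintf("subj%03d", i)
      recs[[i]] <- new("EHGRecording", subjectID = id, channels = ch,
                       fs = config$fs, usableSegments = seg, label = lab)
      meta[[i]] <- data.frame(subject_id = id, label = lab,
                              t(obst), stringsAsFactors = FALSE)
    }
    EHGCohort(recs, do.call(rbind, meta))
  })
}

#' Write / read a cohort as delimited text
#'
#' One tab-separated file per subject (columns \code{time_s}, \code{S1},
#' \code{S2}, \code{S3} in mV) plus a \code{manifest.tsv} index holding the
#' label, obstetric covariates, usable segments (encoded
#' \code{"start-end;start-end"}) and the per-subject file name.  Values
#' are written with full double precision, so the round trip is lossless
#' well beyond the emulated 16-bit quantisation step.
#'
#' @param cohort an [EHGCohort-class].
#' @param directory output directory (created if missing).
#' @return \code{writeCohort}: the manifest path, invisibly.
#'   \code{readCohort}: an [EHGCohort-class].
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "EHGCohort"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  sd_ <- cohort@subjectData
  files <- character(length(cohort))
  segcol <- character(length(cohort))
  for (i in seq_len(length(cohort))) {
    rec <- cohort[[i]]
    files[i] <- paste0(rec@subjectID, ".txt")
    tt <- (seq_len(nrow(rec@channels)) - 1L) / rec@fs
    df <- data.frame(time_s = round(tt, 6), rec@channels)
    write.table(df, file.path(directory, files[i]), sep = "\t",
                row.names = FALSE, quote = FALSE)
    segcol[i] <- paste(sprintf("%.10g-%.10g", rec@usableSegments[, 1],
                               rec@usableSegments[, 2]), collapse = ";")
  }
  man <- cbind(sd_, fs = vapply(cohort@recordings, samplingRate, numeric(1)),
               segments = segcol, file = files)
  manPath <- file.path(directory, "manifest.tsv")
  write.table(man, manPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manPath)
}

#' @rdname writeCohort
#' @export
readCohort <- function(directory) {
  manPath <- file.path(directory, "manifest.tsv")
  if (!file.exists(manPath))
    stop("no manifest.tsv found in '", directory, "'")
  man <- read.table(manPath, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("subject_id", "label", .obstetricNames, "fs", "segments", "file")
  if (!all(need %in% names(man)))
    stop("malformed manifest: missing columns ",
         paste(setdiff(need, names(man)), collapse = ", "))
  recs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(directory, man$file[i])
    if (!file.exists(f)) stop("missing subject file '", f, "'")
    df <- read.table(f, sep = "\t", header = TRUE)
    seg <- do.call(rbind, lapply(strsplit(man$segments[i], ";")[[1]],
      function(s) as.numeric(strsplit(s, "-")[[1]])))
    recs[[i]] <- EHGRecording(man$subject_id[i],
                              as.matrix(df[, c("S1", "S2", "S3")]),
                              fs = man$fs[i], label = man$label[i],
                              usableSegments = seg)
  }
  EHGCohort(recs, man[, c("subject_id", "label", .obstetricNames)])
}

#' Planted-signal feature table for wrapper-selection benchmarks
#'
#' Builds a small balanced classification problem in which only the first
#' \code{nInformative} features carry class signal and the signal is
#' complementary rather than redundant: preterm rows are assigned
#' round-robin to informative features, and each such row is shifted by
#' \code{delta} in its own feature only.  Dropping any single informative
#' feature therefore hides one fifth of the preterm class, so a correct
#' subset search must retain all of them while discarding the
#' \code{nNoise} pure-noise features.
#'
#' @param nPerClass rows per class.
#' @param nInformative,nNoise feature counts.
#' @param delta class shift (in SD units of the unit-variance noise).
#' @param seed integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] (features x rows)
#'   with \code{label} in \code{colData} and an \code{informative} flag in
#'   \code{rowData}.
#' @export
simulatePlantedTable <- function(nPerClass = 100, nInformative = 5,
                                 nNoise = 15, delta = 6, seed = 1) {
  .withSeed(seed, {
    p <- nInformative + nNoise
    n <- 2L * nPerClass
    x <- matrix(rnorm(n * p), nrow = n)
    lab <- rep(c("term", "preterm"), each = nPerClass)
    pre <- which(lab == "preterm")
    grp <- rep_len(seq_len(nInformative), length(pre))
    for (g in seq_len(nInformative))
      x[pre[grp == g], g] <- x[pre[grp == g], g] + delta
    colnames(x) <- sprintf("feat%02d", seq_len(p))
    rownames(x) <- sprintf("row%03d", seq_len(n))
    SummarizedExperiment(
      assays = list(features = t(x)),
      rowData = DataFrame(informative = seq_len(p) <= nInformative),
      colData = DataFrame(subject_id = rownames(x),
                          label = factor(lab, c("term", "preterm")),
                          is_synthetic = FALSE))
  })
}
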