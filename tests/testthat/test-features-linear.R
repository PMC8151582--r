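test_that("peak-to-peak amplitude is max minus min", {
  expect_identical(peakToPeak(rep(0.3, 10)), 0)
  expect_equal(peakToPeak(sineWindow(0.5)), 2, tolerance = 1e-3)
  expect_equal(peakToPeak(c(-1.2, 0.4, 3.1)), 4.3)
  expect_error(peakToPeak(numeric(0)), "empty")
})

test_that("Teager energy matches its analytic values", {
  ## pure sine: every psi[n] = A^2 sin^2(omega)
  A <- 0.7; om <- 0.4
  x <- A * sin(om * (0:499))
  expect_equal(teagerEnergy(x), A^2 * sin(om)^2, tolerance = 1e-10)
  expect_equal(teagerEnergy(rep(2, 100)), 0)
  expect_equal(teagerEnergy(as.numeric(0:99)), 1)   # n^2 - (n-1)(n+1) = 1
  expect_error(teagerEnergy(c(1, 2)), "3 samples")
})

test_that("Welch estimate conserves power and localises tones", {
  set.seed(2)
  x <- rnorm(2400)
  spec <- estimatePSD(x, 20)
  df <- spec$freqs[2] - spec$freqs[1]
  expect_equal(sum(spec$psd) * df, var(x), tolerance = 0.05)

  s <- estimatePSD(sineWindow(0.5), 20)
  expect_equal(s$freqs[which.max(s$psd)], 0.5, tolerance = df)

  ## equal-amplitude two-tone (on the analysis grid, so both tones see
  ## the same taper gain): peak powers agree within 10 % and match a
  ## direct full-length periodogram oracle
  fLo <- 16 * 20 / 1024          # 0.3125 Hz
  fHi <- 36 * 20 / 1024          # 0.703125 Hz
  x2 <- sineWindow(fLo) + sineWindow(fHi)
  s2 <- estimatePSD(x2, 20)
  ## integrate each tone's power over a +/- 0.05 Hz neighbourhood so the
  ## comparison is leakage-proof for both estimators
  tone <- function(f, p, at) sum(p[abs(f - at) < 0.05])
  p03 <- tone(s2$freqs, s2$psd, fLo)
  p07 <- tone(s2$freqs, s2$psd, fHi)
  expect_equal(p03 / p07, 1, tolerance = 0.1)
  pg <- Mod(fft(x2)[1:1200])^2
  fg <- (0:1199) * 20 / 2400
  pgRatio <- tone(fg, pg, fLo) / tone(fg, pg, fHi)
  expect_equal(pgRatio, p03 / p07, tolerance = 0.1)

  expect_error(estimatePSD(rnorm(100), 20), "shorter")
})

test_that("mean frequency is the in-band spectral centroid", {
  expect_equal(meanFrequency(lineSpec(0.5)), 0.5, tolerance = 0.011)
  expect_equal(meanFrequency(flatSpec()), 0.55, tolerance = 0.011)
  expect_equal(meanFrequency(lineSpec(c(0.3, 0.7), c(1, 1))), 0.5,
               tolerance = 0.011)
  empty <- lineSpec(5)      # no power inside 0.1-1
  expect_error(meanFrequency(empty), "zero in-band power")
})

test_that("dominant frequency picks the maximal bin, ties to the lowest", {
  expect_equal(dominantFrequency(lineSpec(0.45), c(0.2, 1)), 0.45,
               tolerance = 0.011)
  expect_equal(dominantFrequency(lineSpec(0.45), c(0.34, 1)), 0.45,
               tolerance = 0.011)
  two <- lineSpec(c(0.25, 0.5), c(1, 0.5))
  expect_equal(dominantFrequency(two, c(0.2, 1)), 0.25, tolerance = 0.011)
  expect_equal(dominantFrequency(two, c(0.34, 1)), 0.5, tolerance = 0.011)
  tie <- lineSpec(c(0.4, 0.6), c(1, 1))
  expect_equal(dominantFrequency(tie, c(0.2, 1)), 0.4, tolerance = 0.011)
})

test_that("deciles split the in-band power mass as defined", {
  d <- spectrumDeciles(flatSpec())
  expect_equal(unname(d), 0.34 + (1:9) * 0.066, tolerance = 0.011)
  expect_true(!is.unsorted(d))

  d6 <- spectrumDeciles(lineSpec(0.6))
  expect_true(all(abs(d6 - 0.6) < 1e-9))

  twoMass <- lineSpec(c(0.4, 0.8), c(1, 1))
  dm <- spectrumDeciles(twoMass)
  expect_true(all(abs(dm[1:5] - 0.4) < 1e-9))
  expect_true(all(abs(dm[6:9] - 0.8) < 1e-9))
})

test_that("decile monotonicity and D5 = median frequency hold on random spectra", {
  set.seed(4)
  for (i in 1:25) {
    f <- seq(0, 10, by = 0.01)
    spec <- structure(list(freqs = f, psd = rexp(length(f))),
                      class = "SpectralEstimate")
    d <- spectrumDeciles(spec)
    expect_true(!is.unsorted(d))
    ## D5: half the in-band mass lies at or below it
    idx <- f >= 0.34 & f <= 1
    cum <- cumsum(spec$psd[idx]) / sum(spec$psd[idx])
    expect_equal(unname(d["d5"]), f[idx][which(cum >= 0.5)[1]])
  }
})

test_that("normalised energies are fractions of whole-band power", {
  ne <- normalizedEnergies(lineSpec(0.5))
  expect_equal(ne, c(0, 1, 0), tolerance = 1e-9)
  neFlat <- normalizedEnergies(flatSpec())
  expect_equal(neFlat, c(0.14, 0.26, 0.4) / 3.9, tolerance = 0.05)
  set.seed(5)
  for (i in 1:20) {
    spec <- structure(list(freqs = seq(0, 10, 0.01),
                           psd = rexp(1001)), class = "SpectralEstimate")
    expect_lte(sum(normalizedEnergies(spec)), 1 + 1e-12)
  }
})

test_that("H/L ratio compares FWH to FWL power", {
  expect_equal(hlRatio(lineSpec(c(0.25, 0.5), c(1, 1))), 1,
               tolerance = 0.1)
  expect_equal(hlRatio(flatSpec()), 0.66 / 0.14, tolerance = 0.1)
  expect_error(hlRatio(lineSpec(0.5)), "zero power")
})

test_that("spectral moment ratio has its analytic values and monotonicity", {
  expect_equal(spectralMomentRatio(lineSpec(1)), 1, tolerance = 1e-6)
  expect_equal(spectralMomentRatio(lineSpec(0.5)), 64, tolerance = 1e-6)
  expect_gt(spectralMomentRatio(lineSpec(0.4)),
            spectralMomentRatio(lineSpec(0.6)))
})

test_that("amplitude scaling moves App and Teager but no spectral shape feature", {
  set.seed(6)
  rec <- smallCohort()[[1]]
  w <- segmentWindows(rec)$S1[[1]]
  f1 <- pretermEHG:::.linearFeatures(w$bandSamples, 20)
  w2 <- w
  w2$bandSamples <- lapply(w$bandSamples, function(v) 2 * v)
  f2 <- pretermEHG:::.linearFeatures(w2$bandSamples, 20)
  appIdx <- grep("^app", names(f1))
  expect_equal(f2[appIdx], 2 * f1[appIdx], tolerance = 1e-9)
  expect_equal(f2[["teager"]], 4 * f1[["teager"]], tolerance = 1e-9)
  shape <- setdiff(names(f1), c(names(f1)[appIdx], "teager"))
  expect_equal(f2[shape], f1[shape], tolerance = 1e-9)
})
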