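test_that("sample entropy is zero for a strict alternation and errors on constants", {
  x <- rep(c(0, 1), 200)
  expect_equal(sampleEntropy(x), 0)
  expect_error(sampleEntropy(rep(1, 400)), "constant")
  expect_error(sampleEntropy(rnorm(50)), "100 samples")
})

test_that("sample and fuzzy entropy match brute-force oracles", {
  set.seed(7)
  cfg <- entropyConfig()
  for (i in 1:6) {
    x <- rnorm(300)
    r <- 0.15 * sd(x)
    expect_equal(sampleEntropy(x, cfg), oracleSampen(x, 2, r),
                 tolerance = 1e-12)
  }
  for (i in 1:4) {
    x <- rnorm(500)
    r <- 0.15 * sd(x)
    expect_equal(fuzzyEntropy(x, cfg), oracleFuzen(x, 2, r),
                 tolerance = 1e-10)
  }
})

test_that("low-pass filtering makes noise more regular (lower SampEn)", {
  set.seed(8)
  drops <- vapply(1:20, function(i) {
    x <- rnorm(2400)
    y <- bandpassFilter(x, 20, 0.1, 1)
    sampleEntropy(x) - sampleEntropy(y)
  }, numeric(1))
  expect_true(all(drops > 0))
})

test_that("sample entropy returns its documented sentinel when nothing matches", {
  ## vanishing tolerance: no two continuous samples ever match
  set.seed(99)
  x <- rnorm(200)
  expect_warning(v <- sampleEntropy(x, entropyConfig(rFactor = 1e-9)),
                 "sentinel")
  nt <- 200 - 2
  expect_equal(v, -log(2 / (nt * (nt - 1))))
})

test_that("fuzzy entropy is offset-invariant and zero for constants", {
  expect_equal(fuzzyEntropy(rep(3.2, 400)), 0)
  set.seed(9)
  x <- rnorm(300)
  expect_equal(fuzzyEntropy(x), fuzzyEntropy(x + 17.3), tolerance = 1e-9)
})

test_that("spectral entropy spans its [0, 1] range as spectra flatten", {
  expect_lt(spectralEntropy(sineWindow(0.5), 20), 0.2)
  set.seed(10)
  expect_gt(spectralEntropy(rnorm(2400), 20, band = c(0.1, 9.9)), 0.95)
  for (i in 1:10) {
    v <- spectralEntropy(rnorm(1200) + sineWindow(runif(1, 0.2, 1),
                                                  n = 1200), 20)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("LZ76 component counts match the brute-force parser", {
  textbook <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_identical(lz76Count(textbook), 6L)
  expect_identical(lz76Count(textbook), oracleLZ(textbook))
  set.seed(11)
  for (i in 1:30) {
    n <- sample(20:300, 1)
    a <- sample(c(2L, 6L), 1)
    s <- sample(0:(a - 1L), n, replace = TRUE)
    expect_identical(lz76Count(s), oracleLZ(s))
  }
})

test_that("normalised LZ is low for periodic and near 1 for iid signals", {
  ## periodic: component count stays O(1) so C -> 0 with N
  cs <- vapply(c(100, 600, 2400), function(n)
    lempelZiv(rep(c(0, 1e-4), n / 2) + 0.5, 2), numeric(1))
  expect_true(all(diff(cs) < 0))
  expect_lt(cs[3], 0.1)

  set.seed(12)
  x <- rnorm(2400)
  expect_equal(lempelZiv(x, 2), 1, tolerance = 0.15)
  expect_equal(lempelZiv(x, 6), 1, tolerance = 0.15)
  expect_error(lempelZiv(rep(1, 100), 2), "degenerate")
})

test_that("time reversibility has its analytic values and antisymmetry", {
  expect_equal(timeReversibility(0.3 * (0:99)), 0.3^3, tolerance = 1e-12)
  x <- sineWindow(0.5, n = 2401)   # 2400 diffs = 60 whole periods
  expect_lt(abs(timeReversibility(x)), 1e-10)
  set.seed(13)
  y <- cumsum(rnorm(500))
  expect_equal(timeReversibility(-y), -timeReversibility(y),
               tolerance = 1e-12)
  expect_error(timeReversibility(1:3, lag = 5), "lag")
})

test_that("Katz dimension is 1 for lines and grows with roughness", {
  expect_equal(katzFD(5 + 0.7 * (0:199)), 1, tolerance = 1e-12)
  expect_equal(katzFD(c(0, 1)), 1)
  expect_error(katzFD(rep(2, 10)), "constant")
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(500)
    expect_gt(katzFD(x), katzFD(cumsum(x)))
    expect_gte(katzFD(x), 1)
  }
})

test_that("Poincare descriptors satisfy their defining identities", {
  ramp <- 0.1 * (0:499)
  pc <- poincareDescriptors(ramp)
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sdRatio, 0)

  set.seed(15)
  x <- rnorm(2400)
  pci <- poincareDescriptors(x)
  expect_equal(pci$sdRatio, 1, tolerance = 0.1)

  for (i in 1:10) {
    v <- rnorm(100)
    p <- poincareDescriptors(v)
    expect_equal(p$sdrr^2, (p$sd1^2 + p$sd2^2) / 2, tolerance = 1e-12)
  }
  expect_error(poincareDescriptors(rep(1, 10)), "constant")
})

test_that("band-limited activity raises features in its own band only", {
  set.seed(16)
  fs <- 20
  base <- 0.02 * pretermEHG:::.pinkNoise(6000)
  burst <- sineWindow(0.25, n = 6000, amp = 0.3)
  mkFeats <- function(x) {
    bands <- ehgBands()
    bs <- lapply(seq_len(nrow(bands)), function(b)
      bandpassFilter(x, fs, bands$f_lo[b], bands$f_hi[b])[2001:4400])
    names(bs) <- bands$name
    list(bandSamples = bs)
  }
  quiet <- pretermEHG:::.windowFeatures(mkFeats(base), fs)
  loud <- pretermEHG:::.windowFeatures(mkFeats(base + burst), fs)
  ## the 0.25 Hz burst lives in the FWL band (0.2-0.34 Hz) ...
  expect_gt(loud[["app_0p2_0p34"]] / quiet[["app_0p2_0p34"]], 5)
  ## ... and barely touches the 0.34-1 Hz band
  expect_lt(loud[["app_0p34_1"]] / quiet[["app_0p34_1"]], 2)
  expect_gt(loud[["sd2_0p2_0p34"]] / quiet[["sd2_0p2_0p34"]], 5)
})
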