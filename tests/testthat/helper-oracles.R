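## Independent brute-force oracles used to cross-check the fast kernels.
## These deliberately re-derive each quantity from its definition with
## plain R loops / vector algebra, sharing no code with the package.

## sample entropy counts: templates of length m (and m+1) over the same
## N - m index range, Chebyshev distance, self-matches excluded
oracleSampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
      }
    }
  }
  -log(A / B)
}

## fuzzy entropy via explicit membership sums over mean-centred templates
oracleFuzen <- function(x, m, r, nexp = 2) {
  n <- length(x)
  nt <- n - m
  phi <- function(len) {
    tpl <- t(vapply(seq_len(nt), function(i) {
      v <- x[i:(i + len - 1L)]
      v - mean(v)
    }, numeric(len)))
    s <- 0
    for (i in seq_len(nt - 1L)) {
      d <- apply(abs(sweep(tpl[(i + 1L):nt, , drop = FALSE], 2L,
                           tpl[i, ])), 1L, max)
      s <- s + sum(exp(-d^nexp / r))
    }
    s
  }
  -log(phi(m + 1L) / phi(m))
}

## LZ76 exhaustive parse by direct substring search
oracleLZ <- function(s) {
  n <- length(s)
  ch <- paste0(s, collapse = "")
  cnt <- 0L; p <- 1L
  while (p <= n) {
    q <- p
    while (q <= n) {
      phrase <- substr(ch, p, q)
      if (grepl(phrase, substr(ch, 1L, q - 1L), fixed = TRUE)) {
        q <- q + 1L
      } else break
    }
    cnt <- cnt + 1L
    p <- q + 1L
  }
  cnt
}

## exact two-sided rank-sum p-value by enumeration of all group-1
## assignments (small samples only)
oracleRanksumP <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  wObs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2L, function(ix) sum(r[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

## Friedman chi-square from the textbook rank formula (no ties expected)
oracleFriedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- colSums(t(apply(m, 1L, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

## small helper: band-limited noise burst test signal
sineWindow <- function(freq, fs = 20, n = 2400, amp = 1) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
}

## synthetic spectral estimates for direct descriptor tests
flatSpec <- function(lo = 0, hi = 10, df = 0.01, value = 1) {
  f <- seq(lo, hi, by = df)
  structure(list(freqs = f, psd = rep(value, length(f))),
            class = "SpectralEstimate")
}

lineSpec <- function(at, power = 1, lo = 0, hi = 10, df = 0.01) {
  f <- seq(lo, hi, by = df)
  p <- numeric(length(f))
  for (i in seq_along(at))
    p[which.min(abs(f - at[i]))] <- power[min(i, length(power))] / df
  structure(list(freqs = f, psd = p), class = "SpectralEstimate")
}

## fast small feature table for balancing / GA / eval tests
toyFeatureSE <- function(nTerm, nPreterm, p = 10, seed = 1, shift = 0) {
  set.seed(seed)
  n <- nTerm + nPreterm
  x <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(sprintf("r%03d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  lab <- rep(c("term", "preterm"), c(nTerm, nPreterm))
  x[lab == "preterm", ] <- x[lab == "preterm", ] + shift
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(x)),
    colData = S4Vectors::DataFrame(
      subject_id = rownames(x),
      label = factor(lab, c("term", "preterm")),
      is_synthetic = FALSE))
}
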