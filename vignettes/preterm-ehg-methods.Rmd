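---
title: "Preterm-labor prediction from EHG: models, parameters and design choices"
author: "pretermEHG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preterm-labor prediction from EHG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what is modelled, which parameters matter, where the design was genuinely
open and how those choices were resolved, and what the synthetic-cohort
results do and do not demonstrate.

## The problem and the modelling strategy

Uterine myoelectrical activity recorded on the abdomen (the
electrohysterogram, EHG) changes measurably with the approach of labor:
amplitude grows as more cells join each contraction, spectral content
shifts upward with cell excitability, and regularity indices change with
time to delivery. The package turns a 3-channel, 20 Hz EHG recording
plus five obstetric covariates (maternal age, parity, abortions, weight,
week of gestation) into a 203-entry feature vector and trains simple,
clinically interpretable classifiers — KNN, LDA, logistic regression —
on a genetic-algorithm-selected feature subset, aggregated by majority
vote.

Whole-window analysis is used deliberately: windows are characterised
wholesale rather than after contraction detection, so only
non-physiological segments need to be excluded (the `usableSegments`
slot of an `EHGRecording`; the package accepts these as given intervals
and performs no artifact detection itself).

## Signal characterisation

**Bands.** Four zero-phase band-passes: 0.1–4 Hz (whole EHG band),
0.34–4 Hz (Fast Wave High), 0.2–0.34 Hz (Fast Wave Low) and 0.34–1 Hz
(the FWH portion with the best signal-to-noise ratio). The filter is a
4th-order Butterworth applied forward–backward (`signal::filtfilt`),
the usual convention in this literature; zero phase keeps every
descriptor insensitive to group delay. Filtering precedes windowing and
is applied to whole usable segments, so no window carries filter edge
transients. Windows of 120 s advance by 60 s (50 % overlap); windows
that would span a non-usable gap are dropped rather than shortened.
Per-recording values are the median over windows, robust to occasional
aberrant windows.

**Feature inventory.** 66 descriptors per channel: peak-to-peak
amplitude in each of the four bands (4); Teager energy, mean frequency
(0.1–1 Hz), dominant frequency in 0.2–1 and 0.34–1 Hz, normalised
energies of 0.2–0.34 / 0.34–0.6 / 0.6–1 Hz over total 0.1–4 Hz power,
the H/L energy ratio P(0.34–1)/P(0.2–0.34), power-spectrum deciles
D1–D9 over 0.34–1 Hz and the spectral moment ratio M(−1)/M(5) over
0.1–1 Hz (18); and 11 non-linear descriptors in each band (44). The
band assignments for the scalar spectral descriptors are the package's
reconstruction — the descriptor list and the per-channel total fix the
arithmetic but not every band — and each band is config-exposed. All
spectral descriptors are computed from the Welch estimate of the
whole-band (0.1–4 Hz) filtered window; Teager energy from the
whole-band time series.

**Welch estimator.** 1024-sample Hamming-tapered segments with 50 %
overlap on the 2400-sample windows, one-sided, scaled so the PSD
integral equals signal power (the tests assert Parseval consistency
within 5 % on white noise). The ~0.02 Hz grid is fine enough that
decile and dominant-frequency quantisation is below the bin-width
tolerances used throughout.

**Non-linear descriptors.** Sample entropy uses m = 2,
r = 0.15 × window SD, both the defaults of the uterine-EMG literature
(the source protocol does not state them); they are exposed via
`entropyConfig()`. Fuzzy entropy uses mean-centred templates with
membership exp(−d²/r). Both kernels are exact O(N²) template counts in
C++, cross-checked against brute-force R implementations in the test
suite. Lempel–Ziv uses the exhaustive LZ76 parse; binary symbolisation
thresholds at the median (ties to the lower symbol), the 6-state
variant uses equiprobable quantile bins (ties to the lower bin), and
the count is normalised by log_α(N)/N with α the alphabet size so the
two variants are commensurate. Time reversibility is the lag-1 third
moment of differences, un-normalised (amplitude-bearing, like the App
features). Katz fractal dimension uses an abscissa unit of one sample;
a constant window is treated as degenerate (error → window skipped)
rather than as a horizontal line. Poincaré SD1/SD2 derive from
var(diff)/2 and 2 var − SD1²; SDRR² = (SD1² + SD2²)/2 holds by
construction. Windows on which a descriptor fails (degenerate
quantisation, zero in-band power) contribute NA for that descriptor
only; a subject needs at least one valid window per descriptor or is
dropped with a warning.

## Screening, balancing, partitions

The per-feature Wilcoxon rank-sum screen is *descriptive*: results are
reported (with the conventional star levels) but never remove features,
because subset search can retain individually non-significant features
for their complementary value. The test is the independent-samples
rank-sum test (the two cohorts are unrelated groups), two-sided,
uncorrected by default with an optional Benjamini–Hochberg switch.
Screening always runs on original rows only — SMOTE output is excluded
structurally, and a test asserts it.

SMOTE (k = 5) interpolates minority rows towards one of their k nearest
minority neighbours with a single U(0,1) weight per synthetic row.
Neighbour distances are Euclidean on z-scored features, since the raw
features span mV³ to Hz. Whether the emulated protocol standardised
before the distance computation is unknown; standardising is the
defensible default and is switchable.

The faithful protocol balances the **whole** table and then draws 30
stratified train/validation/test thirds. This leaks information:
synthetic rows in validation/test interpolate training-set parents, so
absolute performance estimates are optimistic. The package keeps this
mode as the default (`smoteMode = "whole"`) because it reproduces the
emulated design, and provides `smoteMode = "trainOnly"` which
re-balances each training fold only. The null-effect analyses below use
the leakage-free mode, since their purpose is to check the *generator*
and the *screen*, not the protocol.

## The genetic-algorithm wrapper

Chromosomes are 203-bit inclusion masks. Fitness is
`mean validation F1 × (NFeat − NCFeat)` with F1 a fraction in [0, 1],
so the reduction term dominates unless a feature buys at least
F1/(NFeat − NCFeat) of mean F1 — the selection pressure that drives
subsets small. Operators follow the stated protocol: tournament size 2,
elite count 2, arithmetic crossover with probability 0.8, uniform
mutation at 0.01, stall termination at 1e-6 over 150 generations.
Three interpretations were required and are documented here:

* *Arithmetic crossover on binary genes.* The operator is real-valued
  in its source toolbox; the package draws one convex weight u per
  child and rounds, which preserves "average of the parents" semantics
  while keeping genes binary (agreeing genes pass through unchanged; an
  exact 0.5 rounds by fair coin).
* *Offspring composition.* The crossover probability is read as the
  toolbox crossover fraction: of the non-elite children, 80 % come from
  crossover of tournament parents and 20 % are mutation-only copies of
  tournament parents.
* *Initial population and termination.* Genes start iid Bernoulli(0.5);
  the stall rule watches the best fitness only. All-zero masks are
  guarded (a random gene is switched on; a caller-supplied all-zero
  mask receives fitness −Inf).

Fitness evaluations are cached by mask, and the fitness wrapper only
ever touches train and validation rows — a test corrupts all test rows
and asserts an identical selection trajectory.

## Classifiers, ensemble, comparison

Features are z-scored with training-fold statistics. KNN uses k = 5
(odd, to avoid vote ties; unstated in the emulated protocol and
config-exposed) with the preterm-neighbour fraction as its score. LDA
falls back to a ridge-regularised pooled-covariance implementation when
the within-class covariance is singular (common under wide masks).
Logistic regression is fitted by maximum likelihood (`glm.fit`);
rank-deficient or separable fits are accepted with aliased coefficients
treated as zero — training F1 of 1 under separation is expected
behaviour, and the holdout protocol is what measures generalisation.
The preterm class is positive throughout; labels threshold scores at
0.5 (ties to preterm). The ensemble is the 2-of-3 majority vote; its
ROC score is the mean base score (an extension — the voting protocol
defines labels only, but a continuous score is needed for an ensemble
AUC). Classifiers are compared by the Friedman rank test across
partitions with Nemenyi post-hoc critical differences
(q_α/√2 · √(k(k+1)/(6n))) on validation F1; the comparison includes
the ensemble, and a completely tied table short-circuits to p = 1.
Coefficient-of-variation tables report SD/mean per metric per
classifier plus the min/mean/max across bases.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
clinical data. Each subject is three channels of pink (1/f) background
noise (independent per channel, SD `backgroundNoiseLevel` = 0.02 mV)
plus band-limited bursts shared across channels with per-channel gain
jitter N(1, 0.1). Bursts arrive as a Poisson process (0.5/min), last
30–90 s (uniform), and are Hanning-enveloped band-pass-filtered white
noise centred at a class-dependent frequency (term 0.35 Hz, preterm
0.45 Hz — the upward spectral shift) with class-dependent peak
amplitude (term 0.08 mV, preterm 0.12 mV — the amplitude increase).
Obstetric covariates are truncated Gaussians with the published
term/preterm demographic means and SDs; gestational week at recording
additionally scales burst amplitude by 1 + 0.02 (wog − 27), so the Wog
covariate carries real signal. Optional Poisson artifact gaps exercise
segment exclusion. Effect sizes are tuning knobs, not estimates — there
is no published signal-level ground truth for term-vs-preterm waveform
differences — so synthetic results support *relative* and *structural*
claims only (ensemble vs base patterns, null behaviour, recovery of
planted effects), never absolute clinical performance. The published
absolute figures require the real cohorts and are deliberately not
reproduction targets.

## Scale of the bundled analyses

The test suite and the acceptance script run on deliberately small
problems chosen as the smallest sizes at which each claim is
statistically meaningful: recordings of 240 s (three analysis windows
per channel — the per-window kernels are O(N²) in the 2400-sample
windows, and window count multiplies everything); a 60 term / 12
preterm cohort with 10 partitions and a GA capped at population 40 /
12 generations for the ensemble-pattern check; a 24/24 null cohort
with 30 partitions, full masks and training-fold-only SMOTE for the
null checks; and a 20-feature planted benchmark (5 informative, 15
noise) for GA recovery. The planted benchmark gives each informative
feature *complementary* signal — each one separates a disjoint fifth
of the preterm rows, shifted 6 SD in that feature only — because under
the reduction term a redundant design is correctly solved by dropping
informative features, which would make "recovery" unmeasurable; the
6-SD shift is what makes each feature's marginal F1 contribution
exceed F1/(NFeat − NCFeat), the algebraic threshold below which
discarding wins.

## Known limitations

* No physiological realism is claimed for the burst model (no Alvarez
  or Braxton-Hicks waveform structure, no tocogram).
* The faithful whole-table SMOTE protocol overstates absolute
  performance (see above); use `trainOnly` for honest estimates.
* Artifact detection is out of scope; usable segments are inputs.
* The rank-sum screen is uncorrected by design; with 203 features ~10
  false positives are expected under the null (the tests assert this).
* WFDB ingestion is not implemented; recordings arrive as delimited
  text (`readCohort`) or as in-memory `EHGRecording` objects built by
  the caller from any reader.
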