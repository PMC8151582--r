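# pretermEHG

Preterm birth is the leading cause of newborn death, and the clinical
tools used at routine check-ups (tocodynamometry, cervical measures,
biochemical markers) detect the women who will actually deliver early
poorly. The electrohysterogram (EHG) — uterine myoelectrical activity
recorded on the abdominal surface — carries richer information: signal
amplitude rises as pregnancy progresses, spectral content shifts towards
higher frequencies as labor approaches, and regularity/complexity
measures change with time to delivery.

`pretermEHG` implements an end-to-end, interpretable prediction pipeline
for term/preterm classification from 3-channel EHG recordings sampled at
20 Hz plus five obstetric covariates:

1. **Characterisation** — each channel is band-filtered into four
   analysis bands (0.1–4, 0.34–4, 0.2–0.34, 0.34–1 Hz), cut into 120-s
   windows with 50 % overlap, and summarised by the per-recording median
   of 66 descriptors per channel: peak-to-peak amplitude per band, Teager
   energy, Welch-spectrum descriptors (mean frequency, dominant
   frequencies, deciles D1–D9, normalised band energies, H/L ratio,
   spectral moment ratio M(−1)/M(5)), and 11 non-linear descriptors per
   band (sample, fuzzy and spectral entropy, binary and 6-state
   Lempel–Ziv, time reversibility, Katz fractal dimension, Poincaré
   SD1/SD2/SDRR/SD1:SD2). With the obstetric covariates this gives a
   203-entry feature vector per subject (3 × 66 + 5).
2. **Screening** — per-feature two-sided Wilcoxon rank-sum test
   (descriptive only; nothing is filtered out).
3. **Balancing** — SMOTE (k = 5) oversampling of the preterm minority to
   class parity.
4. **Wrapper selection** — a genetic algorithm over binary feature masks
   maximising

   `fitness = mean validation F1 × (NFeat − NCFeat)`

   i.e. mean F1 across stratified train/validation/test partitions times
   the number of discarded features, with arithmetic crossover (0.8),
   uniform mutation (0.01), tournament selection (size 2), elitism (2)
   and a 1e-6/150-generation stall rule.
5. **Evaluation** — KNN, LDA and logistic-regression base classifiers
   (each with its own optimised mask), a majority-vote ensemble,
   accuracy/F1/sensitivity/specificity/PPV/NPV/AUC per partition,
   Friedman + Nemenyi comparison, and coefficient-of-variation
   reporting.

A synthetic cohort generator (pink-noise background plus class-dependent
band-limited bursts, obstetric covariates drawn from published
demographics) makes the whole pipeline testable without clinical data;
real recordings can be supplied as delimited text via `readCohort()`.

## Worked example

```r
library(pretermEHG)

cfg <- pipelineConfig(
  cohort = synthCohortConfig(nTerm = 14, nPreterm = 6,
                             durationS = 240, seed = 5),
  nPartitions = 4,
  ga = gaConfig(populationSize = 12, maxGenerations = 5, seed = 2),
  seed = 9)
res <- runPipeline(cfg, verbose = FALSE)
print(res)
#> Preterm-labor prediction pipeline result
#>   subjects: 20 (+8 synthetic), partitions: 4
#>   ensemble  validation F1 = 0.845 +/- 0.086
#>   KNN       validation F1 = 0.789 +/- 0.070
#>   LDA       validation F1 = 0.792 +/- 0.242
#>   LR        validation F1 = 0.732 +/- 0.164
#>   mask KNN   : 86 features
#>   mask LDA   : 104 features
#>   mask LR    : 100 features
```

The printout shows mean ± SD validation F1 (preterm = positive class)
across the holdout partitions and the size of each classifier's
GA-selected feature subset. Here the majority-vote ensemble already
beats every base classifier and is less variable than LDA/LR — the
qualitative pattern the method is designed to produce. At this toy
scale (20 subjects, 5 GA generations) the masks are still large; longer
GA runs shrink them, since the fitness explicitly rewards discarding
features.

`inst/scripts/run_pipeline.R` wraps the same flow for shell use
(`--stage simulate|extract|screen|balance|select|evaluate|all`), writing
every intermediate as delimited text.

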