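## Shared, lazily built fixtures (feature extraction is the expensive step,
## so the small cohort and its feature table are computed once per run).

.fixtures <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generateCohort(
      synthCohortConfig(nTerm = 14, nPreterm = 6, durationS = 240,
                        seed = 5))
  .fixtures$cohort
}

smallFeatureTable <- function() {
  if (is.null(.fixtures$featureTable))
    .fixtures$featureTable <- buildFeatureTable(smallCohort())
  .fixtures$featureTable
}
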