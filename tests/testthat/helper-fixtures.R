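## Shared fixtures, memoized across test files (helpers are sourced once
## per test run). All cohorts are generated in code at test time.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

## small cohort for unit tests: 12 patients, short images, few views
smallCohort <- function() memo("smallCohort", {
  generateCohort(cohortSpec(nPatients = 12, imageRows = 120,
                            viewsPerVessel = 4, seed = 42))
})

smallStack <- function() memo("smallStack", buildROIStack(smallCohort(), 107L))

smallRadiomics <- function() memo("smallRadiomics",
                                  radiomicFeatures(smallStack()))

## ---- desk-scale study fixture -------------------------------------------
## The scaled-down study conditions: 60 patients, 107 x 41 crops, the full
## cohort structure (3 vessels x 8 views, 10% missing views), radiomic +
## latent features. The autoencoder trains for 50 epochs on a 400-image
## subsample of the training partition (latent 64, scaled encoder 256-128).
studyFixture <- function() memo("studyFixture", {
  cohort <- generateCohort(cohortSpec(nPatients = 60, imageRows = 120,
                                      seed = 2024))
  stack <- buildROIStack(cohort, targetRows = 107L)
  truth <- groundTruth(cohort)
  splits <- makeSplits(truth$patientId, truth$classLabel,
                       testFraction = 0.15, innerRepeats = 0, seed = 77)
  radFs <- radiomicFeatures(stack)
  trainStack <- subsetPatients(stack, splits$trainPool)
  Xtrain <- aeInput(trainStack)
  sub <- stenomics:::.withSeed(7, sample(nrow(Xtrain), min(400, nrow(Xtrain))))
  ae <- buildAE(aeConfig(64, inputDim = ncol(Xtrain)), seed = 7)
  ae <- trainAE(ae, Xtrain[sub, ], epochs = 50, seed = 7)
  aeFs <- aeFeatures(ae, stack)
  list(cohort = cohort, stack = stack, truth = truth, splits = splits,
       radFs = radFs, aeFs = aeFs,
       combined = fuseFeatures(radFs, aeFs), ae = ae,
       trainStack = trainStack)
})
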