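test_that("cohort generation is bit-identical for identical spec and seed", {
  spec <- cohortSpec(nPatients = 4, imageRows = 100, viewsPerVessel = 3,
                     seed = 7)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(lapply(cohortImages(a), slot, "pixels"),
                   lapply(cohortImages(b), slot, "pixels"))
  expect_identical(groundTruth(a), groundTruth(b))
  ## a different seed changes the pixels
  c <- generateCohort(cohortSpec(nPatients = 4, imageRows = 100,
                                 viewsPerVessel = 3, seed = 8))
  expect_false(identical(cohortImages(a)[[1]]@pixels,
                         cohortImages(c)[[1]]@pixels))
})

test_that("class proportions force stenosis fractions and labels", {
  co <- generateCohort(cohortSpec(nPatients = 5,
                                  classProportions = c(1, 0, 0),
                                  imageRows = 100, viewsPerVessel = 2,
                                  seed = 3))
  expect_true(all(groundTruth(co)$maxStenosisFraction == 0))
  expect_true(all(groundTruth(co)$classLabel == "noCAD"))
  ## labels always consistent with the 0 / 0.50 thresholds
  co2 <- generateCohort(cohortSpec(nPatients = 9, imageRows = 100,
                                   viewsPerVessel = 2, seed = 4))
  tr <- groundTruth(co2)
  expect_identical(tr$classLabel, stenomics:::.classFromStenosis(
    tr$maxStenosisFraction))
  vt <- vesselTruth(co2)
  agg <- tapply(vt$maxStenosisFraction, vt$patientId, max)
  expect_equal(as.vector(agg[tr$patientId]), tr$maxStenosisFraction)
})

test_that("view dropping matches its binomial expectation", {
  co <- generateCohort(cohortSpec(nPatients = 60,
                                  classProportions = c(0.2, 0.4, 0.4),
                                  missingViewRate = 0.1, imageRows = 100,
                                  seed = 11))
  perPatient <- table(vapply(cohortImages(co), slot, "", "patientId"))
  expected <- 3 * 8 * 0.9 # 21.6 surviving views per patient
  se <- sqrt(3 * 8 * 0.9 * 0.1 / 60)
  expect_lt(abs(mean(perPatient) - expected), 4 * se + 0.1)
})

test_that("stenosis profile composes lesions by per-row max depth", {
  expect_equal(stenosisProfile(50), rep(1, 50))
  p <- stenosisProfile(100, data.frame(center = 50, length = 30, depth = 0.6))
  expect_equal(min(p), 0.4)
  expect_equal(p[1:30], rep(1, 30)) # untouched outside the lesion
  ## two disjoint lesions: class comes from the deeper one
  p2 <- stenosisProfile(200, data.frame(center = c(50, 150),
                                        length = c(30, 40),
                                        depth = c(0.3, 0.55)))
  expect_equal(min(p2), 0.45)
  expect_identical(stenomics:::.classFromStenosis(1 - min(p2)), "obstructive")
  expect_error(stenosisProfile(50, data.frame(center = 2, length = 30,
                                              depth = 0.5)), "outside")
  expect_error(stenosisProfile(50, data.frame(center = 25, length = 10,
                                              depth = 1.2)), "depth")
})

test_that("invalid specs are rejected", {
  expect_error(cohortSpec(nPatients = 5, classProportions = c(0.5, 0.4, 0.2)),
               "sum")
  expect_error(cohortSpec(nPatients = 2), "nPatients")
  expect_error(cohortSpec(imageCols = 30), "imageCols")
  expect_error(cohortSpec(missingViewRate = 1), "missingViewRate")
})

test_that("the oracle stenosis feature separates the classes perfectly", {
  co <- generateCohort(cohortSpec(nPatients = 12, imageRows = 120,
                                  viewsPerVessel = 2, seed = 5))
  tr <- groundTruth(co)
  ## patient-level min over each patient's truth profiles
  minProf <- tapply(vapply(cohortImages(co), function(im)
    min(im@truthProfile), 0),
    vapply(cohortImages(co), slot, "", "patientId"), min)
  sten <- 1 - minProf[tr$patientId]
  ## a decision stump at the class thresholds classifies every patient
  pred <- stenomics:::.classFromStenosis(round(sten, 10))
  expect_identical(as.vector(pred), tr$classLabel)
})

test_that("views of one vessel correlate more than views across patients", {
  co <- smallCohort()
  imgs <- cohortImages(co)
  key <- vapply(imgs, function(im) paste(im@patientId, im@vesselId), "")
  pid <- vapply(imgs, slot, "", "patientId")
  set.seed(1)
  sameCor <- crossCor <- c()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    sameCor <- c(sameCor, cor(as.vector(imgs[[idx[1]]]@pixels),
                              as.vector(imgs[[idx[2]]]@pixels)))
  }
  for (r in 1:120) {
    i <- sample(length(imgs), 2)
    if (pid[i[1]] != pid[i[2]])
      crossCor <- c(crossCor, cor(as.vector(imgs[[i[1]]]@pixels),
                                  as.vector(imgs[[i[2]]]@pixels)))
  }
  expect_gt(length(crossCor), 100)
  expect_gt(mean(sameCor), mean(crossCor))
})

test_that("cohorts round-trip through PNG + manifest + truth files", {
  dir <- tempfile("cohort")
  co <- generateCohort(cohortSpec(nPatients = 3,
                                  classProportions = c(1, 1, 1) / 3,
                                  imageRows = 80, viewsPerVessel = 2,
                                  seed = 9))
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readCohort(dir)
  expect_equal(length(cohortImages(back)), length(cohortImages(co)))
  expect_equal(groundTruth(back)$classLabel, groundTruth(co)$classLabel)
  ## 8-bit PNG quantization: intensities preserved to half a gray step
  expect_lt(max(abs(cohortImages(back)[[1]]@pixels -
                    cohortImages(co)[[1]]@pixels /
                      max(1, max(cohortImages(co)[[1]]@pixels)))), 0.5 / 255 + 1e-9)
})

test_that("clinical covariates are generated per patient", {
  clin <- clinicalTable(smallCohort())
  expect_equal(nrow(clin), 12)
  expect_true(all(c("age", "sex", "hypertension", "diabetes") %in%
                    names(clin)))
  expect_true(all(clin$age >= 30 & clin$age <= 90))
})
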