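test_that("splits stratify by patient class and never leak", {
  set.seed(1)
  pats <- sprintf("P%03d", 1:100)
  labs <- rep(c("noCAD", "nonobstructive", "obstructive"), c(20, 40, 40))
  sp <- makeSplits(pats, labs, testFraction = 0.15, innerRepeats = 30,
                   seed = 9)
  expect_length(sp$test, 15)
  testLabs <- labs[match(sp$test, pats)]
  expect_equal(unname(table(testLabs)[c("noCAD", "nonobstructive",
                                        "obstructive")]),
               c(3L, 6L, 6L), ignore_attr = TRUE)
  ## deterministic
  sp2 <- makeSplits(pats, labs, testFraction = 0.15, innerRepeats = 30,
                    seed = 9)
  expect_identical(sp, sp2)
  ## partition property for every inner split
  for (inner in sp$inner) {
    expect_length(intersect(inner$train, inner$validation), 0)
    expect_setequal(c(inner$train, inner$validation), sp$trainPool)
  }
  expect_length(intersect(sp$test, sp$trainPool), 0)
  expect_error(makeSplits(pats[1:3], c("a", "a", "b")), ">= 2")
})

test_that("macro metrics match hand-computed values", {
  ## perfect predictions
  y <- rep(c("noCAD", "nonobstructive", "obstructive"), each = 4)
  rep1 <- suppressWarnings(computeMetrics(y, y))
  expect_true(all(evaluationMetrics(rep1)[c("balancedAccuracy", "macroF1",
                                            "macroSpecificity")] == 1))
  expect_equal(sum(diag(confusionMatrix(rep1))), 12)
  ## constant predictor on balanced truth: balanced accuracy 1/3
  repC <- suppressWarnings(computeMetrics(y, rep("noCAD", 12)))
  expect_equal(unname(evaluationMetrics(repC)["balancedAccuracy"]), 1 / 3)
  ## the worked 6-sample case: recalls 0.5, 1, 0.5 -> 2/3
  yt <- c("noCAD", "noCAD", "nonobstructive", "nonobstructive",
          "obstructive", "obstructive")
  yp <- c("noCAD", "nonobstructive", "nonobstructive", "nonobstructive",
          "obstructive", "noCAD")
  repH <- suppressWarnings(computeMetrics(yt, yp))
  expect_equal(unname(evaluationMetrics(repH)["balancedAccuracy"]), 2 / 3)
  ## relabeling permutes the confusion matrix, macro metrics unchanged
  perm <- c(noCAD = "obstructive", nonobstructive = "noCAD",
            obstructive = "nonobstructive")
  repP <- suppressWarnings(computeMetrics(unname(perm[yt]), unname(perm[yp])))
  expect_equal(evaluationMetrics(repP), evaluationMetrics(repH))
  ## AUC: perfect scores give 1, reversed scores give 0
  sc <- matrix(0, 6, 3, dimnames = list(NULL, c("noCAD", "nonobstructive",
                                                "obstructive")))
  for (i in seq_along(yt)) sc[i, yt[i]] <- 1
  repA <- computeMetrics(yt, yt, sc)
  expect_equal(unname(evaluationMetrics(repA)["macroAUC"]), 1)
  ## degenerate inputs warn (absent classes and missing scores)
  w <- capture_warnings(computeMetrics(c("noCAD", "noCAD"),
                                       c("noCAD", "noCAD")))
  expect_match(w, "absent", all = FALSE)
})

test_that("metrics agree with a rank-statistic AUC oracle", {
  set.seed(7)
  y <- sample(c("noCAD", "nonobstructive", "obstructive"), 60, replace = TRUE)
  sc <- matrix(runif(180), 60, 3,
               dimnames = list(NULL, c("noCAD", "nonobstructive",
                                       "obstructive")))
  rep <- computeMetrics(y, colnames(sc)[max.col(sc)], sc)
  oracle <- mean(vapply(colnames(sc), function(cl)
    stenomics:::.aucRank(sc[, cl], y == cl), 0))
  expect_equal(unname(evaluationMetrics(rep)["macroAUC"]), oracle,
               tolerance = 1e-10)
})

test_that("clinical association finds planted signal and respects degeneracy", {
  co <- smallCohort()
  fs <- smallRadiomics()[1:3, ]
  clin <- clinicalTable(co)
  res <- associateClinical(fs, clin)
  expect_true(all(c("feature", "variable", "p") %in% names(res$binary)))
  expect_equal(nrow(res$age), 3)
  ## a feature equal to age plus small noise: rho > 0.9
  keys <- imageKeys(fs)
  agePerImage <- clin$age[match(keys$patientId, clin$patientId)]
  M <- rbind(ageLike = agePerImage + rnorm(ncol(fs), 0, 0.5),
             konst = rep(1, ncol(fs)))
  fake <- new("FeatureSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = M),
    rowData = S4Vectors::DataFrame(provenance = c("ae", "ae"),
                                   row.names = rownames(M)),
    colData = SummarizedExperiment::colData(fs)))
  res2 <- associateClinical(fake, clin)
  expect_gt(res2$age$rho[res2$age$feature == "ageLike"], 0.9)
  ## constant feature is reported not-assessable
  expect_false(res2$age$assessable[res2$age$feature == "konst"])
  expect_true(all(is.na(res2$binary$p[res2$binary$feature == "konst"])))
})

test_that("the clinical screen holds its type-I error on null features", {
  ## 200 patients, one image each, 200 independent null features tested
  ## against two balanced binary variables: 400 null hypotheses
  set.seed(123)
  n <- 200
  pid <- sprintf("P%03d", 1:n)
  M <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("null%03d", 1:200), pid))
  cd <- S4Vectors::DataFrame(patientId = pid, vesselId = "V1",
                             viewIndex = 0L, classLabel = "noCAD",
                             row.names = pid)
  fs <- new("FeatureSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = M),
    rowData = S4Vectors::DataFrame(provenance = rep("ae", 200),
                                   row.names = rownames(M)),
    colData = cd))
  clin <- data.frame(patientId = pid, age = rnorm(n, 60, 10),
                     varA = rep(c(0, 1), n / 2),
                     varB = sample(rep(c(0, 1), n / 2)))
  res <- associateClinical(fs, clin)
  rate <- mean(res$binary$p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})
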