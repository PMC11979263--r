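## Two-stage cascade classification with patient-level majority voting.
## Stage A (no CAD vs. any CAD) classifies every image; a patient whose
## image majority is "no CAD" stops there. Otherwise stage B
## (nonobstructive vs. obstructive), trained on images of CAD patients
## only, classifies the patient's images and its majority decides. Ties at
## either stage are broken toward the more severe class (clinically
## conservative documented policy).

#' Fuse two feature sets column-wise (by image)
#'
#' Concatenates the feature rows of two [FeatureSet-class] objects sharing
#' the same image columns, preserving provenance tags.
#'
#' @param a,b [FeatureSet-class] objects with identical column keys (`b` may
#'   be NULL, returning `a` unchanged).
#' @return A fused [FeatureSet-class].
#' @export
fuseFeatures <- function(a, b = NULL) {
  if (is.null(b)) return(a)
  if (!identical(colnames(a), colnames(b))) {
    bad <- union(setdiff(colnames(a), colnames(b)),
                 setdiff(colnames(b), colnames(a)))
    .stopf("image keys differ between feature sets: %s",
           paste(head(bad, 5), collapse = ", "))
  }
  M <- rbind(assay(a, "features"), assay(b, "features"))
  rd <- DataFrame(provenance = c(as.character(rowData(a)$provenance),
                                 as.character(rowData(b)$provenance)),
                  row.names = rownames(M))
  se <- SummarizedExperiment(assays = list(features = M), rowData = rd,
                             colData = colData(a))
  new("FeatureSet", se)
}

## images x features matrix + keys for a FeatureSet restricted to given ids
.designMatrix <- function(fs, imageIdx = NULL) {
  M <- t(assay(fs, "features"))
  if (!is.null(imageIdx)) M <- M[imageIdx, , drop = FALSE]
  M
}

## one stage: scale -> chain -> SMOTE -> forest
.fitStage <- function(X, y, task, ntree, rhoMax, alpha, seed) {
  sel <- selectionChain(X, y, task = task, rhoMax = rhoMax, alpha = alpha,
                        seed = .deriveSeed(seed, paste0("lasso", task)))
  feats <- sel$report@selected
  Xs <- applyScaler(sel$scaler, X)[, feats, drop = FALSE]
  bal <- smoteBalance(Xs, y, seed = .deriveSeed(seed, paste0("smote", task)))
  forest <- .withSeed(.deriveSeed(seed, paste0("rf", task)), {
    randomForest::randomForest(
      x = bal$X, y = factor(bal$y), ntree = ntree,
      mtry = max(1, floor(sqrt(ncol(bal$X)))))
  })
  list(scaler = sel$scaler, report = sel$report, forest = forest,
       features = feats)
}

#' Fit the two-stage cascade
#'
#' Each stage runs its own scaling, three-step selection chain, SMOTE
#' balancing and a seeded random forest (500 trees, sqrt(p) features per
#' split by default). Stage A uses all training images with the binarized
#' label no CAD vs. CAD; stage B uses only images of CAD patients with the
#' label nonobstructive vs. obstructive (true labels, standard cascade
#' training).
#'
#' @param fs training [FeatureSet-class] (its `colData` supplies patientId
#'   and classLabel).
#' @param ntree forest size per stage (default 500).
#' @param rhoMax,alpha selection-chain thresholds.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return A [CascadeModel-class].
#' @export
fitCascade <- function(fs, ntree = 500, rhoMax = 0.95, alpha = 0.05,
                       seed = 1) {
  keys <- imageKeys(fs)
  lab <- keys$classLabel
  if (length(unique(lab)) != 3)
    .stopf("training data must contain all three classes, got: %s",
           paste(unique(lab), collapse = ", "))
  X <- .designMatrix(fs)
  yA <- ifelse(lab == "noCAD", "noCAD", "CAD")
  stageA <- .fitStage(X, yA, "a", ntree, rhoMax, alpha, seed)
  cadRows <- which(lab != "noCAD")
  stageB <- .fitStage(X[cadRows, , drop = FALSE], lab[cadRows], "b",
                      ntree, rhoMax, alpha, seed)
  new("CascadeModel", stageA = stageA, stageB = stageB,
      votePolicy = "majority-severe-ties", seed = as.integer(seed))
}

.stagePredict <- function(stage, X) {
  Xs <- applyScaler(stage$scaler, X)[, stage$features, drop = FALSE]
  prob <- predict(stage$forest, Xs, type = "prob")
  lab <- colnames(prob)[max.col(prob, ties.method = "first")]
  list(label = lab, prob = prob)
}

#' Patient-level majority vote over per-image cascade decisions
#'
#' Pure aggregation rule: if a strict majority of a patient's images is
#' voted "noCAD" at stage A, the patient is labeled noCAD and stage B is
#' never consulted; otherwise (including exact stage-A ties — the
#' severity-biased rule) the stage-B majority decides, with stage-B ties
#' resolved toward "obstructive". Permutation-invariant in image order.
#'
#' @param stageALabels per-image stage-A labels (`"noCAD"` / `"CAD"`).
#' @param stageBLabels per-image stage-B labels (`"nonobstructive"` /
#'   `"obstructive"`), same length.
#' @return List with `finalLabel`, `votesNoCAD`, `votesCAD`,
#'   `votesNonobstructive`, `votesObstructive` (the last two NA when the
#'   cascade stops at stage A).
#' @examples
#' majorityVote(rep(c("noCAD", "CAD"), c(13, 8)),
#'              rep("obstructive", 21))$finalLabel # "noCAD"
#' @export
majorityVote <- function(stageALabels, stageBLabels) {
  nImg <- length(stageALabels)
  nNo <- sum(stageALabels == "noCAD")
  nCAD <- nImg - nNo
  if (nNo > nCAD)
    return(list(finalLabel = "noCAD", votesNoCAD = nNo, votesCAD = nCAD,
                votesNonobstructive = NA_integer_,
                votesObstructive = NA_integer_))
  nObs <- sum(stageBLabels == "obstructive")
  nNon <- nImg - nObs
  list(finalLabel = if (nObs >= nNon) "obstructive" else "nonobstructive",
       votesNoCAD = nNo, votesCAD = nCAD,
       votesNonobstructive = nNon, votesObstructive = nObs)
}

#' Patient-level cascade prediction with majority voting
#'
#' Stage A classifies every image of every patient; if the strict majority
#' votes "noCAD" the patient is labeled noCAD and stage B is never invoked
#' for that patient. Otherwise (including exact ties — the severity-biased
#' tie rule) stage B classifies the images and its majority decides, ties
#' again resolved toward "obstructive". Chained pseudo-probabilities
#' (stage-A mean P(CAD), stage-B mean P(obstructive), multiplied) are
#' reported for ROC analysis.
#'
#' @param model a [CascadeModel-class].
#' @param fs a [FeatureSet-class] of images to classify.
#' @return A [CascadePrediction-class].
#' @export
predictPatients <- function(model, fs) {
  keys <- imageKeys(fs)
  X <- .designMatrix(fs)
  predA <- .stagePredict(model@stageA, X)
  predB <- .stagePredict(model@stageB, X)
  img <- data.frame(patientId = keys$patientId, vesselId = keys$vesselId,
                    viewIndex = keys$viewIndex,
                    stageALabel = predA$label, stageBLabel = predB$label,
                    stringsAsFactors = FALSE)
  rows <- lapply(split(seq_len(nrow(img)), img$patientId), function(idx) {
    v <- majorityVote(predA$label[idx], predB$label[idx])
    pCAD <- mean(predA$prob[idx, "CAD"])
    pObs <- mean(predB$prob[idx, "obstructive"])
    data.frame(patientId = img$patientId[idx[1]], nImages = length(idx),
               votesNoCAD = v$votesNoCAD, votesCAD = v$votesCAD,
               votesNonobstructive = v$votesNonobstructive,
               votesObstructive = v$votesObstructive,
               finalLabel = v$finalLabel,
               scoreNoCAD = 1 - pCAD,
               scoreNonobstructive = pCAD * (1 - pObs),
               scoreObstructive = pCAD * pObs,
               stringsAsFactors = FALSE)
  })
  pat <- do.call(rbind, rows)
  rownames(pat) <- NULL
  ## patients stopped at stage A never receive stage-B vote records
  stopped <- pat$patientId[pat$finalLabel == "noCAD"]
  img$stageBLabel[img$patientId %in% stopped] <- NA_character_
  new("CascadePrediction", patients = pat, imageLabels = img)
}
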