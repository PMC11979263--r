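## Central S4 containers. Accessor functions are preferred over direct slot
## access throughout the package and in user code.

#' Cohort specification for the synthetic vessel-image generator
#'
#' Describes the statistical structure of a synthetic straightened-vessel
#' cohort: number of patients, class mix over the three severity groups
#' (no CAD / nonobstructive / obstructive, split at stenosis fractions 0 and
#' 0.50), vessels and rotational views per patient, the rate of randomly
#' missing views, image geometry, lumen width and additive noise level.
#'
#' @slot nPatients integer, total patients (>= 3).
#' @slot classProportions numeric(3), proportions of the classes in the order
#'   no CAD, nonobstructive, obstructive; must sum to 1.
#' @slot vesselsPerPatient integer, vessels imaged per patient.
#' @slot viewsPerVessel integer, rotational views acquired per vessel.
#' @slot missingViewRate numeric in [0, 1), probability a view is missing.
#' @slot imageRows,imageCols integer image geometry (imageCols >= 41 so the
#'   41-column centerline crop always fits).
#' @slot lumenWidthPx integer, nominal healthy lumen width in pixels.
#' @slot noiseSd numeric, sd of additive Gaussian intensity noise.
#' @slot seed integer master seed; identical spec + seed reproduces the
#'   cohort bit for bit.
#' @seealso [cohortSpec()], [generateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nPatients = "integer",
  classProportions = "numeric",
  vesselsPerPatient = "integer",
  viewsPerVessel = "integer",
  missingViewRate = "numeric",
  imageRows = "integer",
  imageCols = "integer",
  lumenWidthPx = "integer",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!.isCount(object@nPatients, min = 3))
    msg <- c(msg, "nPatients must be an integer >= 3")
  p <- object@classProportions
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "classProportions must be 3 nonnegative fractions summing to 1")
  if (length(p) == 3 && all(p >= 0) && abs(sum(p) - 1) <= 1e-9 &&
      .isCount(object@nPatients, min = 3)) {
    counts <- .apportion(object@nPatients, p)
    if (any(counts == 0 & p > 0))
      msg <- c(msg, "nPatients too small: every nonzero-proportion class needs >= 1 patient")
  }
  if (object@missingViewRate < 0 || object@missingViewRate >= 1)
    msg <- c(msg, "missingViewRate must lie in [0, 1)")
  if (!.isCount(object@imageCols, min = 41))
    msg <- c(msg, "imageCols must be an integer >= 41")
  if (!.isCount(object@imageRows, min = 16))
    msg <- c(msg, "imageRows too small")
  if (!.isCount(object@vesselsPerPatient) || !.isCount(object@viewsPerVessel))
    msg <- c(msg, "vesselsPerPatient and viewsPerVessel must be positive integers")
  if (!.isCount(object@lumenWidthPx, min = 4) || object@lumenWidthPx > 38)
    msg <- c(msg, "lumenWidthPx must be an integer in [4, 38] so the lumen fits the crop")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' One straightened-vessel view
#'
#' A single 2D grayscale view of one vessel: pixel intensities plus identity
#' (patient, vessel, view index), the centerline column, the first usable row
#' below the ventricular-muscle band, and — for synthetic images — the
#' ground-truth per-row lumen-width fraction.
#'
#' @slot pixels numeric matrix of nonnegative intensities.
#' @slot patientId,vesselId character identifiers.
#' @slot viewIndex integer rotational view index (0-based).
#' @slot centerlineCol integer column of the straightened centerline.
#' @slot upperBoundRow integer first row below the ventricular band (the ROI
#'   upper boundary).
#' @slot truthProfile numeric per-row lumen-width fraction in (0, 1], or
#'   length-0 when unknown.
#' @exportClass MPRImage
setClass("MPRImage", representation(
  pixels = "matrix",
  patientId = "character",
  vesselId = "character",
  viewIndex = "integer",
  centerlineCol = "integer",
  upperBoundRow = "integer",
  truthProfile = "numeric"
))

setValidity("MPRImage", function(object) {
  px <- object@pixels
  if (!all(is.finite(px))) return("pixels must be finite")
  if (any(px < 0)) return("pixels must be nonnegative")
  if (object@centerlineCol < 1 || object@centerlineCol > ncol(px))
    return("centerlineCol outside column range")
  if (length(object@truthProfile) && length(object@truthProfile) != nrow(px))
    return("truthProfile length must equal nrow(pixels)")
  TRUE
})

#' Synthetic cohort container
#'
#' Images plus ground truth for a generated cohort: the views as
#' [MPRImage-class] objects, patient- and vessel-level stenosis truth, a
#' synthetic clinical covariate table, and the generating [CohortSpec-class].
#'
#' @slot images list of [MPRImage-class].
#' @slot truth data.frame with columns patientId, classLabel,
#'   maxStenosisFraction (max over the patient's vessels).
#' @slot vesselTruth data.frame with columns patientId, vesselId,
#'   maxStenosisFraction.
#' @slot clinical data.frame of per-patient synthetic covariates (age plus
#'   binary risk factors).
#' @slot spec the generating [CohortSpec-class].
#' @exportClass MPRCohort
setClass("MPRCohort", representation(
  images = "list",
  truth = "data.frame",
  vesselTruth = "data.frame",
  clinical = "data.frame",
  spec = "CohortSpec"
))

setValidity("MPRCohort", function(object) {
  tr <- object@truth
  if (!all(c("patientId", "classLabel", "maxStenosisFraction") %in% names(tr)))
    return("truth must have patientId, classLabel, maxStenosisFraction")
  expect <- .classFromStenosis(tr$maxStenosisFraction)
  if (!all(expect == tr$classLabel))
    return("classLabel inconsistent with maxStenosisFraction under thresholds {0, 0.50}")
  TRUE
})

#' Stack of fixed-size normalized centerline crops
#'
#' A [SummarizedExperiment-class] whose single assay `"roi"` holds one
#' flattened crop per column (row-major flattening of the rows x 41 crop,
#' so each column has length `roiRows * 41`). `colData` carries patientId,
#' vesselId, viewIndex, padRows and classLabel; `metadata` carries
#' `roiRows`/`roiCols`.
#'
#' @exportClass ROIStack
setClass("ROIStack", contains = "SummarizedExperiment")

#' Feature matrix with provenance
#'
#' A [SummarizedExperiment-class] whose single assay `"features"` holds one
#' feature vector per column (features x images). `rowData$provenance` tags
#' every feature `"radiomic"` or `"ae"`; `colData` carries the image keys and
#' the patient-level class label.
#'
#' @exportClass FeatureSet
setClass("FeatureSet", contains = "SummarizedExperiment")

#' Dense autoencoder architecture
#'
#' Symmetric fully connected autoencoder: input, encoder widths, latent
#' width, mirrored decoder, with ReLU hidden layers, a linear bottleneck and
#' a sigmoid output so reconstructions live in [0, 1].
#'
#' @slot inputDim integer flattened input length (854 x 41 = 35014 at full
#'   scale).
#' @slot encoderWidths integer vector of hidden widths between input and
#'   latent, strictly decreasing.
#' @slot latentDim integer bottleneck width.
#' @exportClass AEConfig
setClass("AEConfig", representation(
  inputDim = "integer",
  encoderWidths = "integer",
  latentDim = "integer"
))

setValidity("AEConfig", function(object) {
  w <- c(object@inputDim, object@encoderWidths, object@latentDim)
  if (any(w < 1)) return("all layer widths must be positive")
  if (any(diff(w) >= 0)) return("widths must be strictly decreasing toward the latent layer")
  TRUE
})

#' A (possibly trained) dense autoencoder
#'
#' @slot config the [AEConfig-class].
#' @slot weights list of affine layers, each `list(W, b)`; encoder layers
#'   first, then the mirrored decoder.
#' @slot history data.frame with per-epoch columns epoch, train, validation
#'   (empty before training).
#' @slot trained logical.
#' @exportClass TrainedAE
setClass("TrainedAE", representation(
  config = "AEConfig",
  weights = "list",
  history = "data.frame",
  trained = "logical"
))

#' Report of the three-step feature-selection chain
#'
#' @slot task character, `"a"` (no CAD vs. CAD) or `"b"` (nonobstructive vs.
#'   obstructive).
#' @slot keptAfterCorrelation character, survivors of the Spearman redundancy
#'   filter.
#' @slot keptAfterWilcoxon character, survivors of the rank-sum filter.
#' @slot wilcoxonP named numeric, two-sided p-values for every feature
#'   entering the rank-sum step.
#' @slot selected character, the final LASSO-selected ordered feature list.
#' @slot coefficients named numeric, LASSO coefficients of `selected`.
#' @slot thresholds named numeric `c(rhoMax=, alpha=)`.
#' @exportClass SelectionReport
setClass("SelectionReport", representation(
  task = "character",
  keptAfterCorrelation = "character",
  keptAfterWilcoxon = "character",
  wilcoxonP = "numeric",
  selected = "character",
  coefficients = "numeric",
  thresholds = "numeric"
))

setValidity("SelectionReport", function(object) {
  if (!all(object@keptAfterWilcoxon %in% object@keptAfterCorrelation))
    return("rank-sum survivors must be nested in correlation survivors")
  if (!all(object@selected %in% object@keptAfterWilcoxon))
    return("LASSO-selected features must be nested in rank-sum survivors")
  TRUE
})

#' Two-stage cascade classifier
#'
#' Stage A separates no CAD from any CAD on every image; stage B separates
#' nonobstructive from obstructive on images of CAD patients. Each stage
#' carries its own fitted scaler, selection report and random forest.
#'
#' @slot stageA,stageB lists with elements `scaler`, `report`
#'   ([SelectionReport-class]), `forest` (randomForest), `features`.
#' @slot votePolicy character, currently `"majority-severe-ties"`: per-stage
#'   patient majority with ties broken toward the more severe class.
#' @slot seed integer seed the fit was run under.
#' @exportClass CascadeModel
setClass("CascadeModel", representation(
  stageA = "list",
  stageB = "list",
  votePolicy = "character",
  seed = "integer"
))

#' Patient-level cascade predictions
#'
#' @slot patients data.frame with one row per patient: patientId, nImages,
#'   votesNoCAD, votesCAD, votesNonobstructive, votesObstructive (NA when
#'   stage B was not reached), finalLabel, and the chained pseudo-probability
#'   scores scoreNoCAD / scoreNonobstructive / scoreObstructive.
#' @slot imageLabels data.frame with per-image stage decisions.
#' @exportClass CascadePrediction
setClass("CascadePrediction", representation(
  patients = "data.frame",
  imageLabels = "data.frame"
))

#' Evaluation report
#'
#' @slot confusion 3x3 patient-level confusion matrix (rows = truth).
#' @slot metrics named numeric: balancedAccuracy, macroSensitivity,
#'   macroSpecificity, macroF1 and (when scores are available) macroAUC.
#' @slot perSplit data.frame of per-split metrics for repeated validation
#'   (empty for a single evaluation).
#' @exportClass EvaluationReport
setClass("EvaluationReport", representation(
  confusion = "matrix",
  metrics = "numeric",
  perSplit = "data.frame"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatients, "patients (",
      paste(sprintf("%s=%.2f", .CLASSES, object@classProportions), collapse = ", "),
      ")\n  vessels/patient:", object@vesselsPerPatient,
      " views/vessel:", object@viewsPerVessel,
      " missing-view rate:", object@missingViewRate, "\n  image:",
      object@imageRows, "x", object@imageCols,
      " lumen:", object@lumenWidthPx, "px  noise sd:", object@noiseSd,
      " seed:", object@seed, "\n")
})

setMethod("show", "MPRImage", function(object) {
  cat(sprintf("MPRImage %s/%s view %d: %d x %d, centerline col %d\n",
              object@patientId, object@vesselId, object@viewIndex,
              nrow(object@pixels), ncol(object@pixels), object@centerlineCol))
})

setMethod("show", "MPRCohort", function(object) {
  cat(sprintf("MPRCohort: %d patients, %d images\n",
              nrow(object@truth), length(object@images)))
  print(table(object@truth$classLabel))
})

setMethod("show", "TrainedAE", function(object) {
  w <- c(object@config@inputDim, object@config@encoderWidths,
         object@config@latentDim)
  cat(sprintf("Dense autoencoder %s (mirrored decoder), %s; %s parameters\n",
              paste(w, collapse = " -> "),
              if (object@trained) sprintf("trained (%d epochs)", nrow(object@history))
              else "untrained",
              format(countParams(object, "full"), big.mark = ",")))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf(
    "SelectionReport task (%s): correlation %d -> rank-sum %d -> LASSO %d features\n",
    object@task, length(object@keptAfterCorrelation),
    length(object@keptAfterWilcoxon), length(object@selected)))
})

setMethod("show", "CascadeModel", function(object) {
  cat(sprintf("CascadeModel: stage A %d features, stage B %d features (vote policy: %s)\n",
              length(object@stageA$features), length(object@stageB$features),
              object@votePolicy))
})

setMethod("show", "CascadePrediction", function(object) {
  cat(sprintf("CascadePrediction for %d patients\n", nrow(object@patients)))
  print(table(object@patients$finalLabel))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@confusion)
  print(round(object@metrics, 4))
})

## ---- accessors ----------------------------------------------------------

#' Cohort accessors
#'
#' `cohortImages()` returns the list of [MPRImage-class] views;
#' `groundTruth()` the per-patient truth table; `vesselTruth()` the
#' per-vessel maxima; `clinicalTable()` the synthetic clinical covariates;
#' `manifest()` a per-image key table (patientId, vesselId, viewIndex,
#' centerlineCol, upperBoundRow, classLabel).
#'
#' @param cohort an [MPRCohort-class].
#' @return A list or data.frame as described.
#' @export
cohortImages <- function(cohort) cohort@images

#' @rdname cohortImages
#' @export
groundTruth <- function(cohort) cohort@truth

#' @rdname cohortImages
#' @export
vesselTruth <- function(cohort) cohort@vesselTruth

#' @rdname cohortImages
#' @export
clinicalTable <- function(cohort) cohort@clinical

#' @rdname cohortImages
#' @export
manifest <- function(cohort) {
  lab <- setNames(cohort@truth$classLabel, cohort@truth$patientId)
  do.call(rbind, lapply(cohort@images, function(im) {
    data.frame(patientId = im@patientId, vesselId = im@vesselId,
               viewIndex = im@viewIndex, centerlineCol = im@centerlineCol,
               upperBoundRow = im@upperBoundRow,
               classLabel = unname(lab[im@patientId]),
               stringsAsFactors = FALSE)
  }))
}

#' Feature / prediction accessors
#'
#' `featureProvenance()` returns the per-feature `"radiomic"`/`"ae"` tag of a
#' [FeatureSet-class]; `featureValues()` its features x images matrix;
#' `imageKeys()` the per-image key table of a [FeatureSet-class] or
#' [ROIStack-class]; `selectionReport()` a stage's [SelectionReport-class]
#' from a [CascadeModel-class]; `patientPredictions()` the per-patient table
#' of a [CascadePrediction-class]; `lossHistory()` the training history of a
#' [TrainedAE-class].
#'
#' @param x the object.
#' @param stage `"a"` or `"b"` (for `selectionReport`).
#' @return See each description.
#' @export
featureProvenance <- function(x) {
  stopifnot(is(x, "FeatureSet"))
  setNames(as.character(rowData(x)$provenance), rownames(x))
}

#' @rdname featureProvenance
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureSet"))
  assay(x, "features")
}

#' @rdname featureProvenance
#' @export
imageKeys <- function(x) as.data.frame(colData(x))

#' @rdname featureProvenance
#' @export
selectionReport <- function(x, stage = c("a", "b")) {
  stopifnot(is(x, "CascadeModel"))
  stage <- match.arg(stage)
  if (stage == "a") x@stageA$report else x@stageB$report
}

#' @rdname featureProvenance
#' @export
patientPredictions <- function(x) {
  stopifnot(is(x, "CascadePrediction"))
  x@patients
}

#' @rdname featureProvenance
#' @export
lossHistory <- function(x) {
  stopifnot(is(x, "TrainedAE"))
  x@history
}

#' @rdname featureProvenance
#' @export
evaluationMetrics <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  x@metrics
}

#' @rdname featureProvenance
#' @export
confusionMatrix <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  x@confusion
}
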