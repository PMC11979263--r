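## Patient-stratified splitting, macro-averaged metrics and the
## clinical-association analysis of latent features.

#' Patient- and label-stratified splits
#'
#' Partitions patients into a test set (default 15%) and, within the
#' remaining training pool, `innerRepeats` further stratified
#' training/validation splits (default 30 splits at 80/20). All images of a
#' patient follow the patient; class proportions are preserved within one
#' patient per class.
#'
#' @param patients character vector of patient ids.
#' @param labels class label per patient.
#' @param testFraction fraction of patients per class held out (default
#'   0.15).
#' @param innerRepeats number of training/validation splits (default 30).
#' @param innerValFraction validation fraction within the training pool.
#' @param seed seed.
#' @return List with `test` (ids), `trainPool` (ids), and `inner` (list of
#'   `list(train, validation)` id vectors).
#' @export
makeSplits <- function(patients, labels, testFraction = 0.15,
                       innerRepeats = 30, innerValFraction = 0.2, seed = 1) {
  stopifnot(length(patients) == length(labels))
  tab <- table(labels)
  if (any(tab < 2)) .stopf("every class needs >= 2 patients")
  .withSeed(seed, {
    byClass <- split(patients, labels)
    test <- unlist(lapply(byClass, function(ids) {
      n <- max(1, round(testFraction * length(ids)))
      sample(ids, n)
    }), use.names = FALSE)
    pool <- setdiff(patients, test)
    poolLab <- labels[match(pool, patients)]
    inner <- lapply(seq_len(innerRepeats), function(r) {
      val <- unlist(lapply(split(pool, poolLab), function(ids) {
        n <- max(1, round(innerValFraction * length(ids)))
        sample(ids, n)
      }), use.names = FALSE)
      list(train = setdiff(pool, val), validation = val)
    })
    list(test = sort(test), trainPool = sort(pool), inner = inner)
  })
}

#' Subset a feature set to the images of given patients
#'
#' @param fs a [FeatureSet-class] (or [ROIStack-class]).
#' @param patientIds character vector.
#' @return The subset object.
#' @export
subsetPatients <- function(fs, patientIds) {
  fs[, imageKeys(fs)$patientId %in% patientIds]
}

## rank-statistic AUC used as a cross-check; pROC is the reporting route
.aucRank <- function(score, pos) {
  r <- rank(score)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged three-class metrics
#'
#' Balanced accuracy (mean per-class recall), macro sensitivity (identical
#' construction), macro specificity and macro F1 via one-vs-rest
#' binarization, and macro AUC (one-vs-rest, unweighted mean) when a score
#' matrix is supplied. A class absent from `yTrue` is excluded from the
#' macro means with a warning.
#'
#' @param yTrue,yPred class labels (subset of the three severity labels).
#' @param scores optional matrix of per-class scores (columns named by
#'   class); AUC is skipped with a warning when absent.
#' @return An [EvaluationReport-class].
#' @examples
#' computeMetrics(c("noCAD", "obstructive"), c("noCAD", "obstructive"))
#' @export
computeMetrics <- function(yTrue, yPred, scores = NULL) {
  stopifnot(length(yTrue) == length(yPred))
  lv <- .CLASSES
  conf <- table(factor(yTrue, lv), factor(yPred, lv))
  present <- lv[rowSums(conf) > 0]
  if (length(present) < 3)
    .warnf("class(es) absent from truth excluded from macro averages: %s",
           paste(setdiff(lv, present), collapse = ", "))
  recall <- spec <- f1 <- setNames(numeric(length(present)), present)
  for (cl in present) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- sum(conf) - tp - fn - fp
    recall[cl] <- tp / (tp + fn)
    spec[cl] <- tn / (tn + fp)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[cl] <- if (prec + recall[cl] > 0)
      2 * prec * recall[cl] / (prec + recall[cl]) else 0
  }
  metrics <- c(balancedAccuracy = mean(recall),
               macroSensitivity = mean(recall),
               macroSpecificity = mean(spec),
               macroF1 = mean(f1))
  if (!is.null(scores)) {
    aucs <- vapply(present, function(cl) {
      pos <- yTrue == cl
      if (all(pos) || !any(pos)) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(pos, scores[, cl], quiet = TRUE,
                                     direction = "<", levels = c(FALSE, TRUE))))
    }, 0)
    metrics["macroAUC"] <- mean(aucs, na.rm = TRUE)
  } else {
    .warnf("no scores supplied; macro AUC skipped")
  }
  new("EvaluationReport", confusion = unclass(conf), metrics = metrics,
      perSplit = data.frame())
}

#' Evaluate a cascade prediction against patient ground truth
#'
#' @param prediction a [CascadePrediction-class].
#' @param truth data.frame with patientId and classLabel.
#' @return An [EvaluationReport-class].
#' @export
evaluatePrediction <- function(prediction, truth) {
  pat <- patientPredictions(prediction)
  yTrue <- truth$classLabel[match(pat$patientId, truth$patientId)]
  scores <- as.matrix(pat[, c("scoreNoCAD", "scoreNonobstructive",
                              "scoreObstructive")])
  colnames(scores) <- .CLASSES
  computeMetrics(yTrue, pat$finalLabel, scores)
}

#' Associate latent features with clinical variables
#'
#' Features are aggregated per patient (mean over images by default), then
#' each (feature, binary variable) pair is tested with a two-sided
#' Mann-Whitney U test and each feature is correlated with age by Spearman
#' correlation. No multiplicity correction by default (configurable).
#'
#' @param fs a [FeatureSet-class] (typically latent features only).
#' @param clinical per-patient data.frame with `patientId`, numeric `age`
#'   and binary columns.
#' @param features feature names to test (default: all rows of `fs`).
#' @param aggregate `"mean"` or `"median"` image-to-patient aggregation.
#' @param adjust p-adjustment method (default `"none"`).
#' @return List with `binary` (data.frame: feature, variable, p, assessable)
#'   and `age` (data.frame: feature, rho, p, assessable).
#' @export
associateClinical <- function(fs, clinical, features = rownames(fs),
                              aggregate = c("mean", "median"),
                              adjust = "none") {
  aggregate <- match.arg(aggregate)
  keys <- imageKeys(fs)
  M <- assay(fs, "features")[features, , drop = FALSE]
  agg <- vapply(split(seq_len(ncol(M)), keys$patientId), function(idx) {
    apply(M[, idx, drop = FALSE], 1, aggregate)
  }, numeric(length(features)))
  agg <- matrix(agg, nrow = length(features),
                dimnames = list(features, unique(sort(keys$patientId))))
  clin <- clinical[match(colnames(agg), clinical$patientId), ]
  binVars <- setdiff(names(clin)[vapply(clin, function(v)
    all(v %in% c(0, 1)), TRUE)], "patientId")
  bin <- do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(binVars, function(v) {
      g <- clin[[v]] == 1
      ok <- sum(g) >= 3 && sum(!g) >= 3 && sd(agg[f, ]) > 0
      p <- if (ok) wilcox.test(agg[f, g], agg[f, !g], exact = FALSE)$p.value
           else NA_real_
      data.frame(feature = f, variable = v, p = p, assessable = ok,
                 stringsAsFactors = FALSE)
    }))
  }))
  bin$p <- stats::p.adjust(bin$p, method = adjust)
  age <- do.call(rbind, lapply(features, function(f) {
    ok <- sd(agg[f, ]) > 0 && !is.null(clin$age)
    if (ok) {
      ct <- suppressWarnings(stats::cor.test(agg[f, ], clin$age,
                                             method = "spearman"))
      data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value,
                 assessable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(feature = f, rho = NA_real_, p = NA_real_,
                 assessable = FALSE, stringsAsFactors = FALSE)
    }
  }))
  list(binary = bin, age = age)
}
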