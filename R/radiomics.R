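## Radiomic feature computation: 18 first-order statistics plus 75 texture
## features (24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) per image type,
## computed on the original crop and its four single-level wavelet bands —
## 93 x 5 = 465 features per image. Formulas follow the IBSI reference
## definitions; degenerate cases (zero variance, single gray level) use the
## documented conventions noted inline.

.EPS <- .Machine$double.eps

.FIRSTORDER <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                 "10Percentile", "90Percentile", "Maximum", "Mean", "Median",
                 "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                 "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                 "Skewness", "Kurtosis", "Variance", "Uniformity")
.GLCM_FEATS <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                 "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
                 "DifferenceAverage", "DifferenceEntropy",
                 "DifferenceVariance", "JointEnergy", "JointEntropy", "Imc1",
                 "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
                 "MaximumProbability", "SumAverage", "SumEntropy",
                 "SumSquares", "MCC")
.GLRLM_FEATS <- c("ShortRunEmphasis", "LongRunEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                  "RunPercentage", "GrayLevelVariance", "RunVariance",
                  "RunEntropy", "LowGrayLevelRunEmphasis",
                  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                  "ShortRunHighGrayLevelEmphasis",
                  "LongRunLowGrayLevelEmphasis",
                  "LongRunHighGrayLevelEmphasis")
.GLSZM_FEATS <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                  "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                  "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                  "HighGrayLevelZoneEmphasis",
                  "SmallAreaLowGrayLevelEmphasis",
                  "SmallAreaHighGrayLevelEmphasis",
                  "LargeAreaLowGrayLevelEmphasis",
                  "LargeAreaHighGrayLevelEmphasis")
.NGTDM_FEATS <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                  "Strength")
.GLDM_FEATS <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                 "GrayLevelNonUniformity", "DependenceNonUniformity",
                 "DependenceNonUniformityNormalized", "GrayLevelVariance",
                 "DependenceVariance", "DependenceEntropy",
                 "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                 "SmallDependenceLowGrayLevelEmphasis",
                 "SmallDependenceHighGrayLevelEmphasis",
                 "LargeDependenceLowGrayLevelEmphasis",
                 "LargeDependenceHighGrayLevelEmphasis")
.IMAGE_TYPES <- c("original", "wavelet-LL", "wavelet-LH", "wavelet-HL",
                  "wavelet-HH")

#' The frozen radiomic feature registry
#'
#' Enumerates the 465 feature names in extraction order: for each image type
#' (original, then the four wavelet bands) the 18 first-order features and
#' the five texture families (24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14
#' GLDM). Names follow the `imageType_family_Feature` scheme, e.g.
#' `wavelet-HH_glcm_Contrast`.
#'
#' @return data.frame with columns `name`, `imageType`, `family`, `feature`.
#' @export
featureRegistry <- function() {
  fam <- list(firstorder = .FIRSTORDER, glcm = .GLCM_FEATS,
              glrlm = .GLRLM_FEATS, glszm = .GLSZM_FEATS,
              ngtdm = .NGTDM_FEATS, gldm = .GLDM_FEATS)
  out <- do.call(rbind, lapply(.IMAGE_TYPES, function(tp) {
    do.call(rbind, lapply(names(fam), function(f) {
      data.frame(imageType = tp, family = f, feature = fam[[f]],
                 stringsAsFactors = FALSE)
    }))
  }))
  out$name <- paste(out$imageType, out$family, out$feature, sep = "_")
  out[, c("name", "imageType", "family", "feature")]
}

## ---- first order --------------------------------------------------------

.firstOrderFeatures <- function(x, d) {
  x <- as.vector(x)
  n <- length(x)
  p <- tabulate(as.vector(d$levels), nbins = d$nLevels) / n
  pNz <- p[p > 0]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  inRobust <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = sum(x^2), # unit pixel spacing: equals Energy
    Entropy = -sum(pNz * log2(pNz)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(inRobust - mean(inRobust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pNz^2))
}

## ---- GLCM ---------------------------------------------------------------

.glcmFeatures <- function(P) {
  px <- rowSums(P)
  keep <- px > 0
  P <- P[keep, keep, drop = FALSE]
  iv <- which(keep) # actual gray-level values of surviving rows/cols
  Ng <- length(iv)
  px <- rowSums(P); py <- colSums(P)
  I <- matrix(iv, Ng, Ng); J <- t(I)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sigx <- sqrt(sum((iv - mux)^2 * px)); sigy <- sqrt(sum((iv - muy)^2 * py))
  ## diagonal-band distributions
  kSum <- as.vector(I + J); kDiff <- as.vector(abs(I - J))
  pv <- as.vector(P)
  pSum <- vapply(sort(unique(kSum)), function(k) sum(pv[kSum == k]), 0)
  sSum <- sort(unique(kSum))
  pDiff <- vapply(sort(unique(kDiff)), function(k) sum(pv[kDiff == k]), 0)
  sDiff <- sort(unique(kDiff))
  DA <- sum(sDiff * pDiff)
  HXY <- -sum(pv[pv > 0] * log2(pv[pv > 0]))
  pxpy <- as.vector(outer(px, py))
  HXY1 <- -sum(pv * log2(pxpy + .EPS))
  HXY2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(I * J * P) - mux * muy) / (sigx * sigy) else 1 # degenerate: 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  mcc <- if (Ng > 1) {
    Q <- (P / px) %*% t(sweep(P, 2, py, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, ev[2]))
  } else 1
  c(Autocorrelation = sum(I * J * P),
    JointAverage = mux,
    ClusterProminence = sum((I + J - mux - muy)^4 * P),
    ClusterShade = sum((I + J - mux - muy)^3 * P),
    ClusterTendency = sum((I + J - mux - muy)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(pDiff[pDiff > 0] * log2(pDiff[pDiff > 0])),
    DifferenceVariance = sum((sDiff - DA)^2 * pDiff),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + ((I - J) / Ng)^2)),
    Id = sum(P / (1 + abs(I - J))),
    Idn = sum(P / (1 + abs(I - J) / Ng)),
    InverseVariance = sum(P[I != J] / (I - J)[I != J]^2),
    MaximumProbability = max(P),
    SumAverage = sum(sSum * pSum),
    SumEntropy = -sum(pSum[pSum > 0] * log2(pSum[pSum > 0])),
    SumSquares = sum((I - mux)^2 * P),
    MCC = mcc)
}

## ---- run-length / size-zone shared scaffold -----------------------------

## P: levels x size count matrix; Np: pixel count; prefix: feature names
.rlszFeatures <- function(P, Np, names16) {
  Ns <- sum(P)
  i <- seq_len(nrow(P)); s <- seq_len(ncol(P))
  Ri <- rowSums(P); Cs <- colSums(P)
  p <- P / Ns
  mui <- sum(i * rowSums(p)); mus <- sum(s * colSums(p))
  pNz <- p[p > 0]
  vals <- c(
    sum(Cs / s^2) / Ns,
    sum(Cs * s^2) / Ns,
    sum(Ri^2) / Ns,
    sum(Ri^2) / Ns^2,
    sum(Cs^2) / Ns,
    sum(Cs^2) / Ns^2,
    Ns / Np,
    sum((i - mui)^2 * rowSums(p)),
    sum((s - mus)^2 * colSums(p)),
    -sum(pNz * log2(pNz + .EPS)),
    sum(Ri / i^2) / Ns,
    sum(Ri * i^2) / Ns,
    sum(P * outer(1 / i^2, 1 / s^2)) / Ns,
    sum(P * outer(i^2, 1 / s^2)) / Ns,
    sum(P * outer(1 / i^2, s^2)) / Ns,
    sum(P * outer(i^2, s^2)) / Ns)
  setNames(vals, names16)
}

## ---- NGTDM --------------------------------------------------------------

.ngtdmFeatures <- function(tab) {
  n <- tab$n; s <- tab$s; lv <- tab$level
  Nvp <- sum(n)
  p <- n / Nvp
  nz <- p > 0
  Ngp <- sum(nz)
  iNz <- lv[nz]; pNz <- p[nz]; sNz <- s[nz]
  coarse <- if (sum(pNz * sNz) > 0) 1 / sum(pNz * sNz) else 1e6
  contrast <- if (Ngp > 1)
    (sum(outer(pNz, pNz) * outer(iNz, iNz, "-")^2) / (Ngp * (Ngp - 1))) *
      (sum(sNz) / Nvp) else 0
  busyDen <- sum(abs(outer(iNz * pNz, iNz * pNz, "-")))
  busy <- if (busyDen > 0) sum(pNz * sNz) / busyDen else 0
  pis <- outer(pNz * sNz, pNz * sNz, "+")
  psum <- outer(pNz, pNz, "+")
  complexity <- sum(abs(outer(iNz, iNz, "-")) * pis / psum) / Nvp
  strength <- if (sum(sNz) > 0)
    sum(psum * outer(iNz, iNz, "-")^2) / sum(sNz) else 0
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}

## ---- GLDM ---------------------------------------------------------------

.gldmFeatures <- function(P) {
  Nz <- sum(P)
  i <- seq_len(nrow(P)); d <- seq_len(ncol(P))
  Ri <- rowSums(P); Cd <- colSums(P)
  p <- P / Nz
  mui <- sum(i * rowSums(p)); mud <- sum(d * colSums(p))
  pNz <- p[p > 0]
  c(SmallDependenceEmphasis = sum(Cd / d^2) / Nz,
    LargeDependenceEmphasis = sum(Cd * d^2) / Nz,
    GrayLevelNonUniformity = sum(Ri^2) / Nz,
    DependenceNonUniformity = sum(Cd^2) / Nz,
    DependenceNonUniformityNormalized = sum(Cd^2) / Nz^2,
    GrayLevelVariance = sum((i - mui)^2 * rowSums(p)),
    DependenceVariance = sum((d - mud)^2 * colSums(p)),
    DependenceEntropy = -sum(pNz * log2(pNz)),
    LowGrayLevelEmphasis = sum(Ri / i^2) / Nz,
    HighGrayLevelEmphasis = sum(Ri * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P * outer(1 / i^2, 1 / d^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * outer(i^2, 1 / d^2)) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / i^2, d^2)) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * outer(i^2, d^2)) / Nz)
}

## ---- per image type -----------------------------------------------------

.featuresOneType <- function(pixels, nBins = 25L) {
  d <- discretizeImage(pixels, nBins)
  Np <- length(pixels)
  c(setNames(.firstOrderFeatures(pixels, d),
             paste0("firstorder_", .FIRSTORDER)),
    setNames(.glcmFeatures(glcmMatrix(d$levels, d$nLevels)),
             paste0("glcm_", .GLCM_FEATS)),
    setNames(.rlszFeatures(glrlmMatrix(d$levels, d$nLevels), Np, .GLRLM_FEATS),
             paste0("glrlm_", .GLRLM_FEATS)),
    setNames(.rlszFeatures(glszmMatrix(d$levels, d$nLevels), Np, .GLSZM_FEATS),
             paste0("glszm_", .GLSZM_FEATS)),
    setNames(.ngtdmFeatures(ngtdmMatrix(d$levels, d$nLevels)),
             paste0("ngtdm_", .NGTDM_FEATS)),
    setNames(.gldmFeatures(gldmMatrix(d$levels, d$nLevels)),
             paste0("gldm_", .GLDM_FEATS)))
}

#' Extract the 465 radiomic features of one crop
#'
#' Computes 18 first-order and 75 texture features on the original crop and
#' on each of its four single-level wavelet bands (each image type
#' re-discretized independently with 25 fixed bins).
#'
#' @param pixels numeric matrix (a normalized crop, or any finite 2D image).
#' @param nBins gray levels for discretization (default 25).
#' @return Named numeric vector of length 465, in [featureRegistry()] order.
#' @examples
#' f <- extractRadiomics(matrix(runif(64), 8, 8))
#' length(f) # 465
#' @export
extractRadiomics <- function(pixels, nBins = 25L) {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    .stopf("extractRadiomics expects a finite numeric matrix")
  bands <- waveletDecompose(pixels)
  types <- list(original = pixels, `wavelet-LL` = bands$LL,
                `wavelet-LH` = bands$LH, `wavelet-HL` = bands$HL,
                `wavelet-HH` = bands$HH)
  out <- unlist(lapply(names(types), function(tp) {
    f <- .featuresOneType(types[[tp]], nBins)
    setNames(f, paste(tp, names(f), sep = "_"))
  }))
  bad <- !is.finite(out)
  if (any(bad))
    .stopf("non-finite feature value(s): %s",
           paste(head(names(out)[bad], 5), collapse = ", "))
  out
}

#' Radiomic features for every crop of an ROI stack
#'
#' @param stack an [ROIStack-class].
#' @param nBins gray levels for discretization.
#' @param verbose print progress every 200 images.
#' @return A [FeatureSet-class] (465 rows, one column per image) with
#'   `rowData()$provenance == "radiomic"`.
#' @export
radiomicFeatures <- function(stack, nBins = 25L, verbose = FALSE) {
  n <- ncol(stack)
  nr <- metadata(stack)$roiRows
  A <- assay(stack, "roi")
  out <- matrix(NA_real_, nrow = 465, ncol = n)
  for (i in seq_len(n)) {
    f <- extractRadiomics(matrix(A[, i], nrow = nr, byrow = TRUE), nBins)
    if (i == 1) rownames(out) <- names(f)
    out[, i] <- f
    if (verbose && i %% 200 == 0) message("  radiomics: ", i, "/", n)
  }
  colnames(out) <- colnames(stack)
  se <- SummarizedExperiment(
    assays = list(features = out),
    rowData = DataFrame(provenance = rep("radiomic", nrow(out)),
                        row.names = rownames(out)),
    colData = colData(stack))
  new("FeatureSet", se)
}
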