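## ROI definition: a 41-column rectangle centered on the straightened
## centerline (centerline +/- 20 columns, a 40-pixel span plus the
## centerline column, reconciling the "40-pixel wide" delineation with the
## 854 x 41 model input). The lower boundary is the inferior image margin;
## the upper boundary excludes the ventricular-muscle band. Rows are padded
## (top, with the background median of the crop) or center-cropped to a
## fixed height, then intensities are min-max normalized per image.

.ROI_HALF <- 20L # columns kept on each side of the centerline
.ROI_COLS <- 41L

#' Extract the fixed-size normalized centerline crop from one view
#'
#' Crops columns `centerlineCol +/- 20` and rows `upperBoundRow..bottom`,
#' pads (top, with the crop's median intensity) or center-crops (excess to
#' the top when odd) to exactly `targetRows` rows, and min-max normalizes to
#' `[0, 1]` (a zero-range crop maps to all zeros).
#'
#' @param image an [MPRImage-class].
#' @param upperBoundRow ROI upper boundary row; defaults to the image's own.
#' @param targetRows output height (854 at full scale).
#' @param centerlineCol centerline column; defaults to the image's own.
#'   Passing both geometry arguments explicitly propagates a reference
#'   delineation to other views (see [propagateROI()]).
#' @return A list with elements `pixels` (targetRows x 41 matrix in [0, 1]),
#'   `padRows`, and `source` (patientId, vesselId, viewIndex).
#' @export
extractROI <- function(image, upperBoundRow = image@upperBoundRow,
                       targetRows = 854L, centerlineCol = image@centerlineCol) {
  px <- image@pixels
  if (centerlineCol - .ROI_HALF < 1 || centerlineCol + .ROI_HALF > ncol(px))
    .stopf("centerline col %d too close to an image edge (%s/%s view %d)",
           centerlineCol, image@patientId, image@vesselId, image@viewIndex)
  if (upperBoundRow >= nrow(px))
    .stopf("upperBoundRow %d must be < image rows %d", upperBoundRow, nrow(px))
  crop <- px[seq.int(upperBoundRow, nrow(px)),
             seq.int(centerlineCol - .ROI_HALF, centerlineCol + .ROI_HALF),
             drop = FALSE]
  usable <- nrow(crop)
  padRows <- 0L
  if (usable > targetRows) {
    excess <- usable - targetRows
    topCrop <- ceiling(excess / 2)
    crop <- crop[seq.int(topCrop + 1, topCrop + targetRows), , drop = FALSE]
  } else if (usable < targetRows) {
    padRows <- as.integer(targetRows - usable)
    pad <- matrix(median(crop), padRows, .ROI_COLS)
    crop <- rbind(pad, crop)
  }
  list(pixels = .minmax(crop), padRows = padRows,
       source = c(patientId = image@patientId, vesselId = image@vesselId,
                  viewIndex = as.character(image@viewIndex)))
}

#' Propagate one view's ROI geometry to all views of the same vessel
#'
#' The delineation (centerline column and upper boundary) is performed on a
#' single reference view and applied unchanged to every view of that vessel.
#'
#' @param reference an [MPRImage-class] supplying the geometry, or a list
#'   with `centerlineCol` and `upperBoundRow`.
#' @param images list of [MPRImage-class], all of the same vessel and shape.
#' @param targetRows output height.
#' @return List of crops as returned by [extractROI()].
#' @export
propagateROI <- function(reference, images, targetRows = 854L) {
  geom <- if (is(reference, "MPRImage"))
    list(centerlineCol = reference@centerlineCol,
         upperBoundRow = reference@upperBoundRow) else reference
  vids <- vapply(images, function(im) im@vesselId, "")
  pids <- vapply(images, function(im) im@patientId, "")
  if (length(unique(paste(pids, vids))) != 1)
    .stopf("propagateROI: images span multiple vessels (%s)",
           paste(unique(paste(pids, vids)), collapse = ", "))
  dims <- vapply(images, function(im) dim(im@pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .stopf("propagateROI: views of vessel %s have mismatched shapes", vids[1])
  lapply(images, extractROI, upperBoundRow = geom$upperBoundRow,
         targetRows = targetRows, centerlineCol = geom$centerlineCol)
}

#' Heuristic ROI upper boundary for synthetic images
#'
#' Finds the first row below the brightest horizontal band in the top third
#' of the image (the ventricular-muscle-like band). Real-data delineation is
#' manual; this heuristic serves generated cohorts when the manifest does
#' not carry the boundary.
#'
#' @param image an [MPRImage-class].
#' @return Integer row index.
#' @export
upperBoundHeuristic <- function(image) {
  px <- image@pixels
  topThird <- seq_len(max(2L, nrow(px) %/% 3))
  w <- rowMeans(px[topThird, , drop = FALSE])
  thr <- median(rowMeans(px)) + 0.5 * (max(w) - median(rowMeans(px)))
  band <- which(w > thr)
  if (!length(band)) return(1L)
  as.integer(min(max(band) + 2L, nrow(px) - 1L))
}

#' Build the ROI stack for a whole cohort
#'
#' Extracts the fixed-size crop from every view, propagating each vessel's
#' delineation from its first available view. Crops are flattened row-major
#' (row 1 left-to-right, then row 2, ...) into columns of the `"roi"` assay.
#'
#' @param cohort an [MPRCohort-class].
#' @param targetRows crop height (854 at full scale; 107 in the downscaled
#'   configuration used for desk-scale experiments).
#' @return An [ROIStack-class]; `metadata()` holds `roiRows`, `roiCols`.
#' @export
buildROIStack <- function(cohort, targetRows = 854L) {
  imgs <- cohort@images
  key <- vapply(imgs, function(im) paste(im@patientId, im@vesselId), "")
  lab <- setNames(cohort@truth$classLabel, cohort@truth$patientId)
  cols <- vector("list", length(imgs))
  cd <- vector("list", length(imgs))
  for (vk in unique(key)) {
    idx <- which(key == vk)
    rois <- propagateROI(imgs[[idx[1]]], imgs[idx], targetRows = targetRows)
    for (j in seq_along(idx)) {
      im <- imgs[[idx[j]]]
      cols[[idx[j]]] <- as.vector(t(rois[[j]]$pixels))
      cd[[idx[j]]] <- data.frame(
        patientId = im@patientId, vesselId = im@vesselId,
        viewIndex = im@viewIndex, padRows = rois[[j]]$padRows,
        classLabel = unname(lab[im@patientId]), stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  cd <- do.call(rbind, cd)
  colnames(mat) <- sprintf("%s_%s_view%d", cd$patientId, cd$vesselId,
                           cd$viewIndex)
  se <- SummarizedExperiment(assays = list(roi = mat),
                             colData = DataFrame(cd, row.names = colnames(mat)))
  metadata(se)$roiRows <- as.integer(targetRows)
  metadata(se)$roiCols <- .ROI_COLS
  new("ROIStack", se)
}

#' Recover one crop of an [ROIStack-class] as a matrix
#'
#' @param stack an [ROIStack-class].
#' @param i column index or name.
#' @return targetRows x 41 numeric matrix.
#' @export
roiImage <- function(stack, i) {
  v <- assay(stack, "roi")[, i]
  matrix(v, nrow = metadata(stack)$roiRows, byrow = TRUE)
}

#' Dimensions of the crops in an [ROIStack-class]
#' @param stack an [ROIStack-class].
#' @return Integer `c(rows, cols)`.
#' @export
roiDims <- function(stack) {
  c(rows = metadata(stack)$roiRows, cols = metadata(stack)$roiCols)
}
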