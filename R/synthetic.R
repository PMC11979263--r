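## Synthetic straightened-vessel cohort generator.
##
## The generator emulates the statistical structure the grading pipeline
## assumes: a bright tubular lumen along the vertical axis of each image,
## focal lesions narrowing the lumen by a controllable stenosis fraction
## (class defined by the per-patient maximum: 0 / <0.50 / >=0.50), ~8
## correlated rotational views per vessel, ~3 vessels per patient, randomly
## missing views, a ventricular-muscle-like bright band above the usable
## region, and additive Gaussian noise.

#' Build a cohort specification
#'
#' Defaults mirror the cohort structure the pipeline targets: three vessels
#' per patient, eight rotational views per vessel, ~10% of views missing,
#' 854-row images, and a class mix dominated by diseased patients
#' (20/40/100... i.e. proportions 0.18 / 0.36 / 0.45 correspond to a 40/80/100
#' split; the default here uses those fractions).
#'
#' @param nPatients total patients.
#' @param classProportions proportions of no CAD / nonobstructive /
#'   obstructive patients (sum to 1).
#' @param vesselsPerPatient,viewsPerVessel cohort structure.
#' @param missingViewRate probability each view is missing (at least one view
#'   per vessel always survives).
#' @param imageRows,imageCols image geometry; `imageCols >= 41`.
#' @param lumenWidthPx nominal healthy lumen width (pixels).
#' @param noiseSd additive Gaussian noise sd (intensity units; images are
#'   rendered on a [0, ~1] scale).
#' @param seed master seed.
#' @return A validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPatients = 6, seed = 1)
#' @export
cohortSpec <- function(nPatients = 60,
                       classProportions = c(40, 80, 100) / 220,
                       vesselsPerPatient = 3,
                       viewsPerVessel = 8,
                       missingViewRate = 0.1,
                       imageRows = 854,
                       imageCols = 120,
                       lumenWidthPx = 16,
                       noiseSd = 0.03,
                       seed = 1) {
  new("CohortSpec",
      nPatients = as.integer(nPatients),
      classProportions = as.numeric(classProportions),
      vesselsPerPatient = as.integer(vesselsPerPatient),
      viewsPerVessel = as.integer(viewsPerVessel),
      missingViewRate = as.numeric(missingViewRate),
      imageRows = as.integer(imageRows),
      imageCols = as.integer(imageCols),
      lumenWidthPx = as.integer(lumenWidthPx),
      noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Per-row lumen-width fraction for a set of focal lesions
#'
#' Each lesion is a raised-cosine narrowing: depth `depthFraction` at its
#' center row, tapering to 0 at `center +/- length/2`. Outside all lesions
#' the profile is 1. Overlapping lesions combine by the per-row maximum
#' depth, so the profile is `1 - max(depth contributions)`.
#'
#' @param nRows number of image rows.
#' @param lesions data.frame (or coercible) with columns `center`, `length`,
#'   `depth`; may have zero rows.
#' @return Numeric vector of length `nRows` with values in `[1 - max depth, 1]`.
#' @examples
#' p <- stenosisProfile(100, data.frame(center = 50, length = 30, depth = 0.6))
#' min(p) # 0.4
#' @export
stenosisProfile <- function(nRows, lesions = NULL) {
  prof <- rep(1, nRows)
  if (is.null(lesions) || NROW(lesions) == 0) return(prof)
  lesions <- as.data.frame(lesions)
  depthMap <- rep(0, nRows)
  for (k in seq_len(nrow(lesions))) {
    ctr <- lesions$center[k]; len <- lesions$length[k]; dep <- lesions$depth[k]
    if (dep < 0 || dep > 1) .stopf("lesion depth must lie in [0, 1], got %g", dep)
    lo <- ctr - len / 2; hi <- ctr + len / 2
    if (lo < 1 || hi > nRows)
      .stopf("lesion [%g, %g] extends outside image rows [1, %d]", lo, hi, nRows)
    rows <- seq.int(ceiling(lo), floor(hi))
    bump <- dep * 0.5 * (1 + cos(2 * pi * (rows - ctr) / len))
    depthMap[rows] <- pmax(depthMap[rows], bump)
  }
  1 - depthMap
}

## Lesion layout for one vessel. The most severe lesion carries the
## class-defining depth; additional shallow lesions add texture variety.
.sampleLesions <- function(nRows, upperBound, maxDepth) {
  if (maxDepth <= 0) return(data.frame(center = numeric(), length = numeric(),
                                       depth = numeric()))
  usable <- nRows - upperBound
  nLes <- sample.int(3, 1)
  lens <- round(runif(nLes, 0.06, 0.14) * usable)
  lens <- pmax(lens, 8)
  depths <- c(maxDepth,
              if (nLes > 1) runif(nLes - 1, 0.05, min(maxDepth, 0.45)))
  ## place lesions in disjoint vertical spans so they never overlap
  centers <- numeric(nLes)
  for (k in seq_len(nLes)) {
    span <- (nRows - upperBound) / nLes
    a <- upperBound + (k - 1) * span + lens[k] / 2 + 1
    b <- upperBound + k * span - lens[k] / 2 - 1
    centers[k] <- if (b > a) round(runif(1, a, b)) else round((a + b) / 2)
  }
  data.frame(center = centers, length = lens, depth = depths)
}

## Plaque blobs adjacent to a lesion: hyperdense (calcified-like) and/or
## hypodense (soft-plaque-like), drawn once per vessel so views stay
## correlated. Frequencies differ by class to give texture features signal
## beyond pure geometry.
.sampleBlobs <- function(lesions, classLabel, centerlineCol, lumenHalf) {
  if (nrow(lesions) == 0) return(NULL)
  pHyper <- switch(classLabel, noCAD = 0, nonobstructive = 0.45, obstructive = 0.7)
  pHypo <- switch(classLabel, noCAD = 0, nonobstructive = 0.30, obstructive = 0.35)
  out <- list()
  for (k in seq_len(nrow(lesions))) {
    side <- sample(c(-1, 1), 1)
    if (runif(1) < pHyper)
      out[[length(out) + 1]] <- list(
        row = lesions$center[k] + round(rnorm(1, 0, 2)),
        col = centerlineCol + side * (lumenHalf + runif(1, 1.5, 3.5)),
        sr = max(3, lesions$length[k] / 4), sc = 2.2, amp = runif(1, 0.25, 0.4))
    if (runif(1) < pHypo)
      out[[length(out) + 1]] <- list(
        row = lesions$center[k] + round(rnorm(1, 0, 3)),
        col = centerlineCol - side * (lumenHalf + runif(1, 1.0, 2.5)),
        sr = max(3, lesions$length[k] / 3), sc = 2.0, amp = -runif(1, 0.06, 0.12))
  }
  if (length(out)) out else NULL
}

## Render one view. Shared vessel geometry (profile, centerline, blobs) plus
## small per-view width/intensity jitter emulating rotational views.
.renderView <- function(spec, profile, centerlineCol, upperBoundRow,
                        blobs, widthJitter, intensityJitter) {
  R <- spec@imageRows; C <- spec@imageCols
  bg <- 0.12
  img <- matrix(bg, R, C)
  ## ventricular-muscle-like bright band above the ROI upper boundary
  if (upperBoundRow > 1) {
    bandRows <- seq_len(upperBoundRow - 1)
    edge <- plogis((upperBoundRow - 1 - bandRows) / 2)
    img[bandRows, ] <- bg + 0.45 * edge
  }
  ## lumen: soft-edged bright band of per-row half-width
  half <- 0.5 * spec@lumenWidthPx * widthJitter * profile
  half[seq_len(min(upperBoundRow - 1, R))] <- 0.5 * spec@lumenWidthPx * widthJitter
  dcol <- abs(seq_len(C) - centerlineCol)
  lum <- 0.85 * intensityJitter
  S <- plogis((outer(half, rep(1, C)) - outer(rep(1, R), dcol)) / 0.8)
  img <- img + (lum - bg) * S
  ## plaque blobs
  if (!is.null(blobs)) {
    rows <- seq_len(R); cols <- seq_len(C)
    for (b in blobs) {
      gr <- exp(-0.5 * ((rows - b$row) / b$sr)^2)
      gc <- exp(-0.5 * ((cols - b$col) / b$sc)^2)
      img <- img + (b$amp * intensityJitter) * outer(gr, gc)
    }
  }
  img <- img + matrix(rnorm(R * C, 0, spec@noiseSd), R, C)
  pmax(img, 0)
}

## Synthetic clinical covariates with class-conditional distributions
## loosely following a referral CCTA population (age increases and risk
## factors accumulate with severity).
.sampleClinical <- function(patientId, classLabel) {
  i <- match(classLabel, .CLASSES)
  age <- round(pmin(90, pmax(30, rnorm(1, c(51.4, 59.7, 65.6)[i],
                                       c(12.5, 11.2, 9.7)[i]))))
  draw <- function(p) rbinom(1, 1, p[i])
  data.frame(patientId = patientId, age = age,
             sex = draw(c(0.48, 0.73, 0.78)),
             hypertension = draw(c(0.20, 0.35, 0.41)),
             hyperlipidemia = draw(c(0.18, 0.20, 0.46)),
             diabetes = draw(c(0.02, 0.03, 0.17)),
             smoker = draw(c(0.13, 0.14, 0.24)),
             familyHistory = draw(c(0.35, 0.39, 0.33)),
             stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic cohort
#'
#' Produces straightened-vessel views with known ground truth. Patient class
#' is assigned by `spec`'s class proportions (largest-remainder apportionment);
#' for diseased patients every vessel carries lesions whose maximum depth is
#' drawn from the class range (nonobstructive: Uniform(0.05, 0.45);
#' obstructive: Uniform(0.50, 0.95) for the class-defining vessel maximum),
#' emulating diffuse disease so that the patient label is recoverable from
#' per-image majority voting. Views of one vessel share profile, centerline
#' and plaque blobs, differing by small width/intensity jitter and noise.
#' Each view is independently dropped with probability `missingViewRate`,
#' but at least one view per vessel always survives. Identical spec + seed
#' reproduces the cohort bit for bit.
#'
#' @param spec a [CohortSpec-class].
#' @return An [MPRCohort-class].
#' @examples
#' co <- generateCohort(cohortSpec(nPatients = 6, imageRows = 120, seed = 3))
#' groundTruth(co)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    counts <- .apportion(spec@nPatients, spec@classProportions)
    labels <- rep(.CLASSES, counts)
    images <- list()
    truth <- vesselTr <- clin <- list()
    for (p in seq_len(spec@nPatients)) {
      pid <- sprintf("P%03d", p)
      cls <- labels[p]
      vmax <- numeric(spec@vesselsPerPatient)
      for (v in seq_len(spec@vesselsPerPatient)) {
        vid <- sprintf("V%d", v)
        upperBound <- max(2L, as.integer(round(spec@imageRows *
                                                 runif(1, 0.04, 0.07))))
        centerline <- sample(seq.int(21L, spec@imageCols - 20L), 1)
        maxDepth <- switch(cls,
          noCAD = 0,
          nonobstructive = runif(1, 0.05, 0.45),
          obstructive = if (v == 1) runif(1, 0.50, 0.95) else
                        runif(1, 0.50, 0.95))
        lesions <- .sampleLesions(spec@imageRows, upperBound, maxDepth)
        profile <- stenosisProfile(spec@imageRows, lesions)
        vmax[v] <- if (nrow(lesions)) max(lesions$depth) else 0
        blobs <- .sampleBlobs(lesions, cls, centerline,
                              0.5 * spec@lumenWidthPx)
        keep <- runif(spec@viewsPerVessel) >= spec@missingViewRate
        if (!any(keep)) keep[1] <- TRUE
        for (w in seq_len(spec@viewsPerVessel)) {
          wj <- rnorm(1, 1, 0.03); ij <- rnorm(1, 1, 0.05)
          if (!keep[w]) next
          px <- .renderView(spec, profile, centerline, upperBound, blobs,
                            max(0.85, wj), max(0.8, ij))
          images[[length(images) + 1]] <- new("MPRImage",
            pixels = px, patientId = pid, vesselId = vid,
            viewIndex = w - 1L, centerlineCol = as.integer(centerline),
            upperBoundRow = upperBound, truthProfile = profile)
        }
        vesselTr[[length(vesselTr) + 1]] <- data.frame(
          patientId = pid, vesselId = vid, maxStenosisFraction = vmax[v],
          stringsAsFactors = FALSE)
      }
      truth[[p]] <- data.frame(patientId = pid, classLabel = cls,
                               maxStenosisFraction = max(vmax),
                               stringsAsFactors = FALSE)
      clin[[p]] <- .sampleClinical(pid, cls)
    }
    new("MPRCohort", images = images,
        truth = do.call(rbind, truth),
        vesselTruth = do.call(rbind, vesselTr),
        clinical = do.call(rbind, clin),
        spec = spec)
  })
}

#' Write / read a cohort as plain files
#'
#' `writeCohort()` writes 8-bit grayscale PNGs (one per view, intensities
#' clipped to [0, 1]... images are rescaled by their global max when any
#' pixel exceeds 1), a `manifest.csv` (patientId, vesselId, viewIndex, file,
#' centerlineCol, upperBoundRow, classLabel), `truth.json` and
#' `clinical.csv`. `readCohort()` reads them back (truth profiles are not
#' round-tripped; they exist only in memory for synthetic cohorts).
#'
#' @param cohort an [MPRCohort-class].
#' @param dir output directory (created if needed).
#' @return `writeCohort()` the directory invisibly; `readCohort()` an
#'   [MPRCohort-class] (with empty truth profiles).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- manifest(cohort)
  man$file <- sprintf("%s_%s_view%d.png", man$patientId, man$vesselId,
                      man$viewIndex)
  for (i in seq_along(cohort@images)) {
    px <- cohort@images[[i]]@pixels
    if (max(px) > 1) px <- px / max(px)
    png::writePNG(px, file.path(dir, man$file[i]), dpi = NULL)
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort@clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(patients = cohort@truth, vessels = cohort@vesselTruth),
    file.path(dir, "truth.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  clin <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(man)), function(i) {
    px <- png::readPNG(file.path(dir, man$file[i]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    new("MPRImage", pixels = px, patientId = man$patientId[i],
        vesselId = man$vesselId[i], viewIndex = as.integer(man$viewIndex[i]),
        centerlineCol = as.integer(man$centerlineCol[i]),
        upperBoundRow = as.integer(man$upperBoundRow[i]),
        truthProfile = numeric())
  })
  spec <- cohortSpec(nPatients = max(3, nrow(tr$patients)),
                     imageRows = nrow(images[[1]]@pixels),
                     imageCols = ncol(images[[1]]@pixels))
  new("MPRCohort", images = images, truth = tr$patients,
      vesselTruth = tr$vessels, clinical = clin, spec = spec)
}
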