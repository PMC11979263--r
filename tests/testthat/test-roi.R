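mkImage <- function(px, centerline = 21L, upper = 1L) {
  new("MPRImage", pixels = px, patientId = "P1", vesselId = "V1",
      viewIndex = 0L, centerlineCol = as.integer(centerline),
      upperBoundRow = as.integer(upper), truthProfile = numeric())
}

test_that("crops have the exact fixed geometry and flatten length", {
  px <- matrix(runif(900 * 60), 900, 60)
  roi <- extractROI(mkImage(px, centerline = 30), targetRows = 854L)
  expect_identical(dim(roi$pixels), c(854L, 41L))
  expect_length(as.vector(roi$pixels), 35014L)
  expect_true(all(roi$pixels >= 0 & roi$pixels <= 1))
})

test_that("905 usable rows are center-cropped 854 with excess to the top", {
  ## 905 rows usable -> 51 rows removed: 26 from the top, 25 from the bottom
  px <- matrix(rep(seq_len(905), 60), 905, 60) / 905
  roi <- extractROI(mkImage(px, centerline = 30), targetRows = 854L)
  expect_equal(roi$padRows, 0L)
  kept <- roi$pixels[, 1] * (905 - 27) / 905 # undo minmax of kept rows
  ## first kept row is original row 27, last is 880
  expect_equal(roi$pixels[1, 1], 0)
  expect_equal(roi$pixels[854, 1], 1)
  orig <- seq_len(905) / 905
  expect_equal(roi$pixels[, 1],
               (orig[27:880] - orig[27]) / (orig[880] - orig[27]))
})

test_that("short images are padded on top with the crop's median", {
  set.seed(4)
  px <- matrix(runif(800 * 60, 0.2, 0.8), 800, 60)
  img <- mkImage(px, centerline = 30)
  roi <- extractROI(img, targetRows = 854L)
  expect_equal(roi$padRows, 54L)
  crop <- px[, 10:50]
  med <- median(crop) # independent recomputation of the pad value
  rng <- range(crop)
  expect_equal(unique(as.vector(roi$pixels[1:54, ])),
               (med - rng[1]) / (rng[2] - rng[1]))
})

test_that("degenerate and error cases follow the documented rules", {
  const <- matrix(0.5, 200, 60)
  roi <- extractROI(mkImage(const, centerline = 30), targetRows = 150L)
  expect_true(all(roi$pixels == 0)) # zero range -> all zeros
  expect_error(extractROI(mkImage(const, centerline = 10)), "centerline")
  expect_error(extractROI(mkImage(const, centerline = 30, upper = 300)),
               "upperBoundRow")
})

test_that("normalization is idempotent on an already-normalized crop", {
  set.seed(9)
  px <- matrix(runif(200 * 60), 200, 60)
  px[1, 30] <- 0; px[2, 30] <- 1 # pin the range inside the crop
  roi1 <- extractROI(mkImage(px, centerline = 30), targetRows = 200L)
  renorm <- stenomics:::.minmax(roi1$pixels)
  expect_lt(max(abs(renorm - roi1$pixels)), 1e-12)
})

test_that("reference geometry propagates unchanged to all views", {
  set.seed(2)
  views <- lapply(0:3, function(v) {
    img <- mkImage(matrix(runif(200 * 60), 200, 60), centerline = 35,
                   upper = 12L)
    initialize(img, viewIndex = as.integer(v))
  })
  rois <- propagateROI(views[[1]], views, targetRows = 150L)
  expect_length(rois, 4)
  ## identical views -> identical crops
  same <- propagateROI(views[[1]], list(views[[1]], views[[1]]),
                       targetRows = 150L)
  expect_identical(same[[1]]$pixels, same[[2]]$pixels)
  ## geometry taken from the reference even if a view disagrees
  odd <- initialize(views[[3]], centerlineCol = 20L)
  rois2 <- propagateROI(views[[1]], list(views[[1]], odd), targetRows = 150L)
  expect_identical(dim(rois2[[2]]$pixels), c(150L, 41L))
  ## mismatched shapes are refused
  bad <- mkImage(matrix(runif(100 * 60), 100, 60), centerline = 35)
  expect_error(propagateROI(views[[1]], list(views[[1]], bad)), "shape")
})

test_that("the crop contains the full lumen in every generated view", {
  co <- smallCohort()
  imgs <- cohortImages(co)[1:20]
  for (im in imgs) {
    half <- 0.5 * co@spec@lumenWidthPx * max(im@truthProfile)
    ## lumen extent (with jitter margin) must fit inside centerline +/- 20
    expect_lt(half * 1.15, 20)
  }
  st <- smallStack()
  expect_identical(unname(roiDims(st)), c(107L, 41L))
  ## lumen column band is the brightest region of the crop
  px <- roiImage(st, 1)
  mid <- rowMeans(px[, 17:25])
  edge <- rowMeans(px[, c(1:4, 38:41)])
  expect_gt(mean(mid), mean(edge) + 0.2)
})

test_that("heuristic upper bound lands below the bright band", {
  im <- cohortImages(smallCohort())[[1]]
  ub <- upperBoundHeuristic(im)
  expect_gte(ub, im@upperBoundRow - 3L)
  expect_lte(ub, im@upperBoundRow + 6L)
})
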