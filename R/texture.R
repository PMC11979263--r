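## Gray-level discretization and the five texture-matrix families
## (GLCM, GLRLM, GLSZM, NGTDM, GLDM), following the IBSI reference
## definitions on the full rectangular ROI (no mask: the segmentation-free
## design point). All matrices use 25 fixed-width bins, distance 1 and, for
## region/neighbourhood families, 8-connectivity.

#' Fixed-bin-count gray-level discretization
#'
#' Equal-width bins spanning `[min, max]` of the image; the maximum
#' intensity falls in the top bin. A zero-range image maps every pixel to
#' level 1 (documented degenerate rule).
#'
#' @param pixels numeric matrix.
#' @param nBins number of gray levels (default 25).
#' @return List with `levels` (integer matrix in 1..nBins), `nLevels`, and
#'   `binEdges` (nBins + 1 ascending thresholds).
#' @export
discretizeImage <- function(pixels, nBins = 25L) {
  rng <- range(pixels)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  if (rng[2] - rng[1] <= 0) {
    lev <- matrix(1L, nrow(pixels), ncol(pixels))
  } else {
    width <- (rng[2] - rng[1]) / nBins
    lev <- pmin(floor((pixels - rng[1]) / width) + 1, nBins)
    storage.mode(lev) <- "integer"
  }
  list(levels = lev, nLevels = as.integer(nBins), binEdges = edges)
}

## Aligned pixel-pair index vectors for an offset (dr, dc); returns the two
## level vectors of all in-image pairs.
.pairsAtOffset <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  list(a = lev[r1, c1, drop = FALSE],
       b = lev[r1 + dr, c1 + dc, drop = FALSE])
}

## The four distance-1 2D directions (0, 45, 90, 135 degrees)
.DIRECTIONS <- list(c(0L, 1L), c(-1L, 1L), c(1L, 0L), c(1L, 1L))

#' Gray-level co-occurrence matrix
#'
#' Distance 1, four 2D directions, symmetrized; each direction's matrix is
#' normalized to sum 1 and the four are averaged (matrix averaging, not
#' count merging).
#'
#' @param lev integer level matrix (1..nLevels).
#' @param nLevels number of gray levels.
#' @return nLevels x nLevels matrix summing to 1.
#' @export
glcmMatrix <- function(lev, nLevels = 25L) {
  acc <- matrix(0, nLevels, nLevels)
  nDir <- 0L
  for (d in .DIRECTIONS) {
    pp <- .pairsAtOffset(lev, d[1], d[2])
    if (!length(pp$a)) next
    cnt <- tabulate(as.vector(pp$a) + nLevels * (as.vector(pp$b) - 1L),
                    nbins = nLevels * nLevels)
    M <- matrix(cnt, nLevels, nLevels)
    M <- M + t(M) # symmetrize
    acc <- acc + M / sum(M)
    nDir <- nDir + 1L
  }
  acc / nDir
}

## Run-length counts along one set of scan lines (list of level vectors)
.runCounts <- function(lines, nLevels, maxRun) {
  ks <- lapply(lines, function(v) {
    r <- rle(as.integer(v))
    r$values + nLevels * (pmin(r$lengths, maxRun) - 1L)
  })
  cnt <- tabulate(unlist(ks, use.names = FALSE), nbins = nLevels * maxRun)
  matrix(cnt, nLevels, maxRun)
}

#' Gray-level run-length matrix
#'
#' Runs of equal gray level along the four distance-1 directions; the four
#' per-direction count matrices are averaged.
#'
#' @inheritParams glcmMatrix
#' @return nLevels x maxRunLength matrix of (direction-averaged) run counts.
#' @export
glrlmMatrix <- function(lev, nLevels = 25L) {
  nr <- nrow(lev); nc <- ncol(lev)
  maxRun <- max(nr, nc)
  rowsOf <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])
  horiz <- rowsOf(lev)
  vert <- lapply(seq_len(nc), function(j) lev[, j])
  rr <- row(lev); cc <- col(lev)
  diag1 <- split(lev, cc - rr)   # down-right; column-major order follows the diagonal
  diag2 <- split(lev, cc + rr)   # down-left (45 degrees)
  P <- (.runCounts(horiz, nLevels, maxRun) +
        .runCounts(vert, nLevels, maxRun) +
        .runCounts(diag1, nLevels, maxRun) +
        .runCounts(diag2, nLevels, maxRun)) / 4
  P
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal gray level.
#'
#' @inheritParams glcmMatrix
#' @return nLevels x maxZoneSize matrix of zone counts.
#' @export
glszmMatrix <- function(lev, nLevels = 25L) {
  nr <- nrow(lev); nc <- ncol(lev)
  n <- nr * nc
  id <- matrix(seq_len(n), nr, nc)
  edges <- list()
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    pp <- .pairsAtOffset(lev, d[1], d[2])
    ii <- .pairsAtOffset(id, d[1], d[2])
    same <- as.vector(pp$a) == as.vector(pp$b)
    if (any(same))
      edges[[length(edges) + 1]] <- rbind(as.vector(ii$a)[same],
                                          as.vector(ii$b)[same])
  }
  if (length(edges)) {
    g <- igraph::make_graph(as.vector(do.call(cbind, edges)), n = n,
                            directed = FALSE)
    mem <- igraph::components(g)$membership
  } else {
    mem <- seq_len(n)
  }
  sizes <- tabulate(mem)
  lvComp <- integer(length(sizes))
  lvComp[mem] <- as.vector(lev)
  maxSize <- max(sizes)
  cnt <- tabulate(lvComp + nLevels * (sizes - 1L), nbins = nLevels * maxSize)
  matrix(cnt, nLevels, maxSize)
}

## Sum over the 8 neighbours of f(neighbour) with zero outside the image;
## returns list(sum, count of in-image neighbours).
.neighbourSum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ones <- matrix(0, nr + 2, nc + 2)
  ones[2:(nr + 1), 2:(nc + 1)] <- 1
  s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    cnt <- cnt + ones[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  list(sum = s, count = cnt)
}

#' Neighbouring gray-tone difference matrix
#'
#' For each gray level i: `n_i` pixels and `s_i`, the summed absolute
#' difference between i and the mean level of each pixel's in-image
#' 8-neighbourhood.
#'
#' @inheritParams glcmMatrix
#' @return data.frame with columns `level`, `n`, `s`.
#' @export
ngtdmMatrix <- function(lev, nLevels = 25L) {
  nb <- .neighbourSum(lev)
  avg <- nb$sum / pmax(nb$count, 1)
  diff <- abs(as.vector(lev) - as.vector(avg))
  lv <- as.vector(lev)
  s <- vapply(seq_len(nLevels), function(i) sum(diff[lv == i]), 0)
  n <- tabulate(lv, nbins = nLevels)
  data.frame(level = seq_len(nLevels), n = n, s = s)
}

#' Gray-level dependence matrix
#'
#' Dependence of a pixel = 1 + number of 8-neighbours with identical gray
#' level (alpha = 0), so dependence sizes run 1..9 and every pixel
#' contributes exactly one dependence.
#'
#' @inheritParams glcmMatrix
#' @return nLevels x maxDependence matrix of counts (total = pixel count).
#' @export
gldmMatrix <- function(lev, nLevels = 25L) {
  nr <- nrow(lev); nc <- ncol(lev)
  dep <- matrix(0L, nr, nc)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    pp <- .pairsAtOffset(lev, d[1], d[2])
    same <- pp$a == pp$b
    r1 <- max(1, 1 - d[1]):min(nr, nr - d[1])
    c1 <- max(1, 1 - d[2]):min(nc, nc - d[2])
    dep[r1, c1] <- dep[r1, c1] + same
    dep[r1 + d[1], c1 + d[2]] <- dep[r1 + d[1], c1 + d[2]] + same
  }
  dep <- dep + 1L
  maxDep <- max(dep)
  cnt <- tabulate(as.vector(lev) + nLevels * (as.vector(dep) - 1L),
                  nbins = nLevels * maxDep)
  matrix(cnt, nLevels, maxDep)
}

#' All five texture matrices of a discretized image
#'
#' @param d result of [discretizeImage()].
#' @return Named list `glcm`, `glrlm`, `glszm`, `ngtdm`, `gldm`.
#' @export
computeTextureMatrices <- function(d) {
  list(glcm = glcmMatrix(d$levels, d$nLevels),
       glrlm = glrlmMatrix(d$levels, d$nLevels),
       glszm = glszmMatrix(d$levels, d$nLevels),
       ngtdm = ngtdmMatrix(d$levels, d$nLevels),
       gldm = gldmMatrix(d$levels, d$nLevels))
}
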