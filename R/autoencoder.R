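## Dense symmetric autoencoder: affine layers with ReLU hidden activations,
## a linear bottleneck and a sigmoid output (reconstructions in [0, 1]).
## Trained by backpropagation with mean-squared-error loss and the Adam
## optimizer. Implemented directly on BLAS-backed matrix operations; all
## randomness (initialization, shuffling, validation split) is seeded.

#' Autoencoder architecture configuration
#'
#' The three reference architectures at full scale (input 35014 = 854 x 41):
#' AE256 = one encoder layer of 512 and a 256-wide bottleneck; AE128 adds a
#' 256 layer (latent 128); AE64 adds a 128 layer (latent 64) — a geometric
#' width progression with ratio ~0.5. The decoder mirrors the encoder.
#'
#' @param latentDim bottleneck width.
#' @param inputDim flattened input length.
#' @param encoderWidths hidden widths between input and latent; the default
#'   follows the halving progression `512, 256, ...` down to `2 * latentDim`
#'   when `inputDim` is full scale, and scales the start width down
#'   proportionally for smaller inputs.
#' @return An [AEConfig-class].
#' @examples
#' aeConfig(64)   # 35014 -> 512 -> 256 -> 128 -> 64 -> ... -> 35014
#' aeConfig(256)  # 35014 -> 512 -> 256 -> ... -> 35014
#' @export
aeConfig <- function(latentDim = 64, inputDim = 35014L,
                     encoderWidths = NULL) {
  if (is.null(encoderWidths)) {
    start <- if (inputDim >= 35014) 512L else
      max(2L * latentDim, 2^round(log2(inputDim / 16)))
    w <- start
    while (tail(w, 1) / 2 > latentDim) w <- c(w, tail(w, 1) / 2)
    encoderWidths <- as.integer(w)
  }
  new("AEConfig", inputDim = as.integer(inputDim),
      encoderWidths = as.integer(encoderWidths),
      latentDim = as.integer(latentDim))
}

.layerWidths <- function(config) {
  enc <- c(config@inputDim, config@encoderWidths, config@latentDim)
  c(enc, rev(enc)[-1]) # mirrored decoder back to inputDim
}

#' Build an (untrained) autoencoder
#'
#' Weights use seeded Glorot-uniform initialization; biases start at zero.
#'
#' @param config an [AEConfig-class].
#' @param seed initialization seed.
#' @return A [TrainedAE-class] with `trained = FALSE`.
#' @export
buildAE <- function(config, seed = 1) {
  validObject(config)
  widths <- .layerWidths(config)
  .withSeed(seed, {
    weights <- lapply(seq_len(length(widths) - 1), function(l) {
      fi <- widths[l]; fo <- widths[l + 1]
      lim <- sqrt(6 / (fi + fo))
      list(W = matrix(runif(fi * fo, -lim, lim), fi, fo), b = numeric(fo))
    })
    new("TrainedAE", config = config, weights = weights,
        history = data.frame(epoch = integer(), train = numeric(),
                             validation = numeric()),
        trained = FALSE)
  })
}

#' Parameter count of an autoencoder
#'
#' Counts weights + biases over affine layers: `sum(fanIn * fanOut + fanOut)`.
#' With `scope = "encoder"` only the input -> ... -> latent layers are
#' counted (the convention under which the three reference architectures
#' total 18,100,160 / 18,091,904 / 18,059,008 parameters); `scope = "full"`
#' counts the whole network.
#'
#' @param model a [TrainedAE-class] (trained or not).
#' @param scope `"encoder"` or `"full"`.
#' @return Integer-valued numeric count.
#' @examples
#' countParams(buildAE(aeConfig(64)), "encoder") # 18100160
#' @export
countParams <- function(model, scope = c("encoder", "full")) {
  scope <- match.arg(scope)
  nEnc <- length(model@config@encoderWidths) + 1L
  layers <- if (scope == "encoder") model@weights[seq_len(nEnc)] else
    model@weights
  sum(vapply(layers, function(l) nrow(l$W) * ncol(l$W) + length(l$b), 0))
}

## forward pass; returns list of layer activations (A[[1]] = input)
.aeForward <- function(weights, nEnc, X) {
  L <- length(weights)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% weights[[l]]$W
    Z <- sweep(Z, 2, weights[[l]]$b, "+")
    A[[l + 1]] <- if (l == L) plogis(Z)          # sigmoid output
    else if (l == nEnc) Z                        # linear bottleneck
    else pmax(Z, 0)                              # ReLU hidden
  }
  A
}

#' Train an autoencoder
#'
#' Backpropagation with MSE loss between input and reconstruction, Adam
#' optimizer, seeded shuffling and validation split. The per-epoch history
#' records mean training-batch loss and full validation loss.
#'
#' @param model a [TrainedAE-class] from [buildAE()].
#' @param X numeric matrix, images x inputDim, values in [0, 1] (rows are
#'   row-major flattened crops; see [aeInput()]).
#' @param epochs maximum training epochs (300 at full scale; reduced for
#'   desk-scale runs).
#' @param batchSize mini-batch size (default 48).
#' @param lr Adam learning rate (default 0.001; the swept range at full
#'   scale was 0.1 to 0.001).
#' @param validationFraction fraction of rows held out for validation loss.
#' @param seed seed for shuffling and the validation split.
#' @param verbose print loss every 10 epochs.
#' @return The trained [TrainedAE-class].
#' @export
trainAE <- function(model, X, epochs = 300, batchSize = 48, lr = 1e-3,
                    validationFraction = 0.2, seed = 1, verbose = FALSE) {
  stopifnot(is(model, "TrainedAE"))
  if (ncol(X) != model@config@inputDim)
    .stopf("input has %d columns; model expects %d", ncol(X),
           model@config@inputDim)
  if (nrow(X) < 2 * batchSize)
    .stopf("need at least 2 * batchSize = %d images, got %d", 2 * batchSize,
           nrow(X))
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9)
    .stopf("inputs must lie in [0, 1]")
  ## deep copies: the Adam kernel updates parameter blocks in place
  weights <- lapply(model@weights, function(l) list(W = l$W + 0, b = l$b + 0))
  L <- length(weights)
  nEnc <- length(model@config@encoderWidths) + 1L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(weights, function(l) l$W * 0)
  vW <- lapply(weights, function(l) l$W * 0)
  mB <- lapply(weights, function(l) l$b * 0)
  vB <- lapply(weights, function(l) l$b * 0)
  t <- 0
  .withSeed(seed, {
    idx <- sample.int(nrow(X))
    nVal <- max(1, round(validationFraction * nrow(X)))
    valIdx <- idx[seq_len(nVal)]
    trIdx <- idx[-seq_len(nVal)]
    Xval <- X[valIdx, , drop = FALSE]
    hist <- data.frame(epoch = integer(), train = numeric(),
                       validation = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(trIdx)
      batches <- split(ord, ceiling(seq_along(ord) / batchSize))
      epLoss <- 0
      for (bi in seq_along(batches)) {
        Xb <- X[batches[[bi]], , drop = FALSE]
        A <- .aeForward(weights, nEnc, Xb)
        err <- A[[L + 1]] - Xb
        loss <- mean(err^2)
        if (!is.finite(loss))
          .stopf("NaN/Inf training loss at epoch %d batch %d; reduce lr",
                 ep, bi)
        epLoss <- epLoss + loss
        ## backprop: dL/dZ for the sigmoid output under MSE
        nEl <- length(err)
        delta <- (2 / nEl) * err * A[[L + 1]] * (1 - A[[L + 1]])
        t <- t + 1
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gB <- colSums(delta)
          if (l > 1) {
            delta <- tcrossprod(delta, weights[[l]]$W)
            if (l - 1 != nEnc) delta <- delta * (A[[l]] > 0) # ReLU grad
          }
          .adamStep(weights[[l]]$W, mW[[l]], vW[[l]], gW,
                    lr, beta1, beta2, eps, corr1, corr2)
          .adamStep(weights[[l]]$b, mB[[l]], vB[[l]], gB,
                    lr, beta1, beta2, eps, corr1, corr2)
        }
      }
      Aval <- .aeForward(weights, nEnc, Xval)
      valLoss <- mean((Aval[[L + 1]] - Xval)^2)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train = epLoss / length(batches),
                                     validation = valLoss))
      if (verbose && ep %% 10 == 0)
        message(sprintf("  epoch %d: train %.5f val %.5f", ep,
                        epLoss / length(batches), valLoss))
    }
    initialize(model, weights = weights, history = hist, trained = TRUE)
  })
}

#' Flatten an ROI stack into the autoencoder input matrix
#'
#' Rows are images, columns the row-major flattened crop (the stack already
#' stores this flattening).
#'
#' @param stack an [ROIStack-class].
#' @return images x (rows * 41) numeric matrix.
#' @export
aeInput <- function(stack) t(assay(stack, "roi"))

#' Encode images to latent vectors
#'
#' @param model a trained [TrainedAE-class].
#' @param X images x inputDim matrix (or a single flattened vector).
#' @return images x latentDim matrix with columns `ae_0 ... ae_{latent-1}`.
#' @export
encodeLatent <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model@config@inputDim)
    .stopf("input has %d columns; model expects %d", ncol(X),
           model@config@inputDim)
  nEnc <- length(model@config@encoderWidths) + 1L
  A <- X
  for (l in seq_len(nEnc)) {
    A <- sweep(A %*% model@weights[[l]]$W, 2, model@weights[[l]]$b, "+")
    if (l < nEnc) A <- pmax(A, 0)
  }
  colnames(A) <- paste0("ae_", seq_len(ncol(A)) - 1)
  A
}

#' Reconstruct images through the full autoencoder
#'
#' @inheritParams encodeLatent
#' @return images x inputDim matrix of reconstructions in (0, 1).
#' @export
reconstruct <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  nEnc <- length(model@config@encoderWidths) + 1L
  A <- .aeForward(model@weights, nEnc, X)
  A[[length(A)]]
}

#' Latent features for every crop of an ROI stack
#'
#' @param model a trained [TrainedAE-class].
#' @param stack an [ROIStack-class].
#' @return A [FeatureSet-class] (latentDim rows) with
#'   `rowData()$provenance == "ae"`.
#' @export
aeFeatures <- function(model, stack) {
  Z <- t(encodeLatent(model, aeInput(stack)))
  colnames(Z) <- colnames(stack)
  se <- SummarizedExperiment(
    assays = list(features = Z),
    rowData = DataFrame(provenance = rep("ae", nrow(Z)),
                        row.names = rownames(Z)),
    colData = colData(stack))
  new("FeatureSet", se)
}

## ---- SSIM ---------------------------------------------------------------

## separable Gaussian filtering with reflect padding
.gaussFilter <- function(m, win = 11L, sigma = 1.5) {
  half <- (win - 1L) %/% 2L
  g <- exp(-0.5 * ((-half:half) / sigma)^2)
  g <- g / sum(g)
  reflectIdx <- function(n) {
    idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
    pmin(pmax(idx, 1L), n)
  }
  fmat <- function(n) {
    ri <- reflectIdx(n)
    Fm <- matrix(0, n, n + 2L * half)
    for (k in seq_len(win)) {
      i <- seq_len(n)
      Fm[cbind(i, i + k - 1L)] <- g[k]
    }
    ## fold the padded columns back onto the original indices
    M <- matrix(0, n, n)
    for (j in seq_along(ri)) M[, ri[j]] <- M[, ri[j]] + Fm[, j]
    M
  }
  Fr <- fmat(nrow(m)); Fc <- fmat(ncol(m))
  Fr %*% m %*% t(Fc)
}

#' Structural similarity index between two images
#'
#' Standard single-scale SSIM with an 11 x 11 Gaussian window (sigma = 1.5),
#' data range 1 and the usual stabilizing constants (K1 = 0.01, K2 = 0.03).
#' Symmetric in its arguments; 1 means identical structure, negative values
#' anti-correlated structure.
#'
#' @param a,b numeric matrices of identical shape with values in [0, 1].
#' @return Scalar in [-1, 1].
#' @examples
#' x <- matrix(runif(400), 20, 20)
#' ssim(x, x) # 1
#' @export
ssim <- function(a, b) {
  if (!all(dim(a) == dim(b))) .stopf("ssim: shape mismatch")
  C1 <- 0.01^2; C2 <- 0.03^2
  mua <- .gaussFilter(a); mub <- .gaussFilter(b)
  va <- .gaussFilter(a * a) - mua^2
  vb <- .gaussFilter(b * b) - mub^2
  cab <- .gaussFilter(a * b) - mua * mub
  num <- (2 * mua * mub + C1) * (2 * cab + C2)
  den <- (mua^2 + mub^2 + C1) * (va + vb + C2)
  mean(num / den)
}
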