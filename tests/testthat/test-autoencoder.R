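test_that("architectures follow the mirrored halving design", {
  ae64 <- buildAE(aeConfig(64))
  widths <- vapply(ae64@weights, function(l) ncol(l$W), 0L)
  expect_equal(c(35014L, widths),
               c(35014L, 512L, 256L, 128L, 64L, 128L, 256L, 512L, 35014L))
  ae256 <- buildAE(aeConfig(256))
  expect_identical(ae256@config@encoderWidths, 512L)
  expect_error(aeConfig(64, encoderWidths = c(256, 512)), "decreasing")
  ## encode length per architecture (tiny input for speed)
  for (ld in c(8L, 16L)) {
    m <- buildAE(aeConfig(ld, inputDim = 64L, encoderWidths = 32L))
    expect_length(encodeLatent(m, runif(64)), ld)
  }
})

test_that("parameter counts match the closed-form layer sum", {
  ## independent oracle: sum fanIn*fanOut + fanOut over the layer sequence
  closedForm <- function(widths)
    sum(widths[-length(widths)] * widths[-1] + widths[-1])
  expect_equal(countParams(buildAE(aeConfig(64)), "encoder"),
               closedForm(c(35014, 512, 256, 128, 64)))
  expect_equal(countParams(buildAE(aeConfig(128)), "encoder"),
               closedForm(c(35014, 512, 256, 128)))
  full <- c(35014, 512, 256, 128, 64, 128, 256, 512, 35014)
  expect_equal(countParams(buildAE(aeConfig(64)), "full"), closedForm(full))
})

test_that("training reduces loss, is seeded, and bounds reconstructions", {
  set.seed(12)
  ## compressible input: low-rank structure plus noise
  basis <- matrix(runif(5 * 300), 5, 300)
  X <- plogis(matrix(rnorm(120 * 5), 120, 5) %*% basis)
  cfg <- aeConfig(8L, inputDim = 300L, encoderWidths = 32L)
  m <- trainAE(buildAE(cfg, seed = 3), X, epochs = 30, batchSize = 16,
               seed = 3)
  h <- lossHistory(m)
  expect_equal(nrow(h), 30)
  expect_lt(tail(h$train, 1), head(h$train, 1))
  ## running minimum of the validation loss is non-increasing
  expect_true(all(diff(cummin(h$validation)) <= 0))
  m2 <- trainAE(buildAE(cfg, seed = 3), X, epochs = 30, batchSize = 16,
                seed = 3)
  expect_identical(tail(h$train, 1), tail(lossHistory(m2)$train, 1))
  R <- reconstruct(m, X[1:5, ])
  expect_true(all(R > 0 & R < 1)) # sigmoid output
  expect_identical(encodeLatent(m, X[1, ]), encodeLatent(m, X[1, ]))
  expect_error(trainAE(buildAE(cfg), X[1:10, ], epochs = 1), "batchSize")
  expect_error(encodeLatent(m, runif(10)), "columns")
})

test_that("a scaled autoencoder reconstructs held-out vessels with SSIM > 0.8", {
  ## Low-noise fixture: with the generator's default white pixel noise the
  ## index is capped near 0.72 for any reconstruction that cannot reproduce
  ## the exact noise realization (noise variance ~ the stabilizing constant
  ## C2), so the reconstruction-quality property is probed where structure,
  ## not unlearnable noise, dominates the comparison.
  co <- generateCohort(cohortSpec(nPatients = 15, imageRows = 120,
                                  noiseSd = 0.01, seed = 42))
  st <- buildROIStack(co, 107L)
  X <- aeInput(st)
  pid <- imageKeys(st)$patientId
  holdout <- unique(pid)[1:3]
  Xtr <- X[!pid %in% holdout, ]
  Xte <- X[pid %in% holdout, ][1:12, ]
  cfg <- aeConfig(64L, inputDim = ncol(X), encoderWidths = c(256L, 128L))
  m <- trainAE(buildAE(cfg, seed = 5), Xtr, epochs = 50, seed = 5)
  rec <- reconstruct(m, Xte)
  ss <- vapply(seq_len(nrow(Xte)), function(i)
    ssim(matrix(Xte[i, ], 107, byrow = TRUE),
         matrix(rec[i, ], 107, byrow = TRUE)), 0)
  expect_gt(mean(ss), 0.8)
})

test_that("latent space keeps vessel identity together", {
  st <- smallStack()
  X <- aeInput(st)
  cfg <- aeConfig(16L, inputDim = ncol(X), encoderWidths = c(128L, 64L))
  m <- trainAE(buildAE(cfg, seed = 6), X, epochs = 15, seed = 6)
  Z <- encodeLatent(m, X)
  keys <- imageKeys(st)
  vkey <- paste(keys$patientId, keys$vesselId)
  set.seed(2)
  same <- cross <- c()
  for (k in unique(vkey)) {
    idx <- which(vkey == k)
    if (length(idx) >= 2)
      same <- c(same, cor(Z[idx[1], ], Z[idx[2], ]))
  }
  while (length(cross) < 60) {
    i <- sample(nrow(Z), 2)
    if (keys$patientId[i[1]] != keys$patientId[i[2]])
      cross <- c(cross, cor(Z[i[1], ], Z[i[2], ]))
  }
  expect_gt(mean(same), mean(cross))
})

test_that("ssim behaves like a structural similarity index", {
  set.seed(44)
  x <- matrix(runif(40 * 40), 40, 40)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- matrix(runif(40 * 40), 40, 40)
  expect_equal(ssim(x, y), ssim(y, x)) # symmetric
  ## anti-correlated structure scores negative
  half <- cbind(matrix(0, 24, 12), matrix(1, 24, 12))
  expect_lt(ssim(half, 1 - half), 0)
  ## small perturbation beats a shuffle
  noisy <- pmin(pmax(x + rnorm(1600, 0, 0.02), 0), 1)
  shuf <- matrix(sample(as.vector(x)), 40, 40)
  expect_gt(ssim(x, noisy), ssim(x, shuf))
  expect_error(ssim(x, matrix(0, 3, 3)), "shape")
})

test_that("latent compression is real", {
  cfg <- aeConfig(64)
  expect_gt(cfg@inputDim / cfg@latentDim, 500) # ~547x for AE64
})
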