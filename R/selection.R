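## The three-step selection chain applied independently per cascade
## sub-task: (1) Spearman redundancy filter — of any pair with |rho| > 0.95
## keep the member with lower mean absolute correlation to all other
## features; (2) two-sided Wilcoxon rank-sum filter at alpha = 0.05,
## uncorrected; (3) L1-penalized logistic regression (LASSO) with seeded
## 5-fold cross-validation at one-standard-error parsimony. Scaling, the
## filters, the LASSO and SMOTE balancing all see training rows only.

#' Fit / apply a per-feature z-score scaler
#'
#' `fitScaler()` learns per-column mean and sd on training rows only;
#' `applyScaler()` standardizes any matrix with those statistics (no refit).
#' Zero-variance features are centered only (documented rule — no division
#' by zero).
#'
#' @param X numeric matrix, rows = images, named columns = features.
#' @param scaler a fitted scaler.
#' @return `fitScaler()` a list with `center`, `scale`; `applyScaler()` the
#'   standardized matrix.
#' @export
fitScaler <- function(X) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(center = ctr, scale = sds)
}

#' @rdname fitScaler
#' @export
applyScaler <- function(scaler, X) {
  scale(X, center = scaler$center[colnames(X)],
        scale = scaler$scale[colnames(X)])[, , drop = FALSE]
}

#' Spearman redundancy filter
#'
#' Pairs with absolute Spearman correlation above `rhoMax` are processed in
#' descending |rho| order (ties broken lexicographically by the pair's
#' feature names); from each pair still unresolved, the member with the
#' higher mean absolute Spearman correlation to all original features is
#' dropped (ties: the lexicographically later name). Deterministic.
#'
#' @param X numeric matrix with named columns (>= 2 rows).
#' @param rhoMax redundancy threshold (default 0.95).
#' @return Character vector of surviving feature names (original order).
#' @export
correlationFilter <- function(X, rhoMax = 0.95) {
  stopifnot(nrow(X) >= 2, !is.null(colnames(X)))
  ## Spearman via Pearson on ranks; constant columns yield NA -> treated as 0
  R <- suppressWarnings(cor(apply(X, 2, rank), method = "pearson"))
  R[!is.finite(R)] <- 0 # constant columns correlate with nothing
  diag(R) <- 0
  meanAbs <- rowMeans(abs(R)) * ncol(R) / (ncol(R) - 1)
  ut <- which(upper.tri(R) & abs(R) > rhoMax, arr.ind = TRUE)
  if (nrow(ut) == 0) return(colnames(X))
  nm1 <- colnames(X)[ut[, 1]]; nm2 <- colnames(X)[ut[, 2]]
  ord <- order(-abs(R[ut]), pmin(nm1, nm2), pmax(nm1, nm2))
  dropped <- character()
  for (k in ord) {
    a <- nm1[k]; b <- nm2[k]
    if (a %in% dropped || b %in% dropped) next
    drop <- if (meanAbs[a] > meanAbs[b]) a
            else if (meanAbs[a] < meanAbs[b]) b
            else max(a, b)
    dropped <- c(dropped, drop)
  }
  setdiff(colnames(X), dropped)
}

## Vectorized two-sided rank-sum p-values: exact enumeration (via
## stats::wilcox.test) when both groups have <= 20 samples and no ties,
## normal approximation with tie correction and continuity correction
## otherwise. Cross-checked against wilcox.test in the test suite.
.rankSumP <- function(x, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  r <- rank(x)
  W <- sum(r[g1]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of group 1
  hasTies <- anyDuplicated(x) > 0
  if (n1 <= 20 && n2 <= 20 && !hasTies)
    return(wilcox.test(x[g1], x[!g1], exact = TRUE)$p.value)
  n <- n1 + n2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum significance filter
#'
#' Two-sided rank-sum test per feature between the two groups; features with
#' p < alpha are kept (uncorrected, matching common radiomics practice; a
#' Benjamini-Hochberg variant is available via `adjust`).
#'
#' @param X numeric matrix with named columns.
#' @param y logical or two-level vector of group membership per row.
#' @param alpha significance threshold (default 0.05).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return List with `kept` (names) and `p` (named p-values for all
#'   features).
#' @export
wilcoxonFilter <- function(X, y, alpha = 0.05, adjust = "none") {
  g1 <- y == sort(unique(y))[1]
  if (min(sum(g1), sum(!g1)) < 3)
    .stopf("each group needs >= 3 samples (got %d / %d)", sum(g1), sum(!g1))
  p <- vapply(seq_len(ncol(X)), function(j) .rankSumP(X[, j], g1), 0)
  names(p) <- colnames(X)
  padj <- stats::p.adjust(p, method = adjust)
  list(kept = colnames(X)[padj < alpha], p = p)
}

#' LASSO feature selection
#'
#' L1-penalized logistic regression with seeded 5-fold cross-validation;
#' features with nonzero coefficients at the one-standard-error penalty are
#' selected. If that penalty keeps nothing, the minimum-deviance penalty is
#' used; if still empty, the single feature with the largest absolute
#' univariate rank-sum statistic is returned with a warning.
#'
#' @param X scaled numeric matrix with named columns.
#' @param y binary outcome (two levels).
#' @param seed fold-assignment seed.
#' @param nfolds cross-validation folds (default 5).
#' @return List with `selected` (ordered by |coefficient|) and
#'   `coefficients` (named, nonzero).
#' @export
lassoSelect <- function(X, y, seed = 1, nfolds = 5) {
  yb <- as.integer(factor(y)) - 1L
  if (ncol(X) < 2) # nothing to shrink: keep the lone survivor
    return(list(selected = colnames(X),
                coefficients = setNames(rep(0, ncol(X)), colnames(X))))
  .withSeed(seed, {
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(X)))
    cv <- glmnet::cv.glmnet(X, yb, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    for (lam in c(cv$lambda.1se, cv$lambda.min)) {
      beta <- as.matrix(coef(cv, s = lam))[-1, 1]
      nz <- beta[beta != 0]
      if (length(nz)) {
        ord <- order(-abs(nz))
        return(list(selected = names(nz)[ord], coefficients = nz[ord]))
      }
    }
    .warnf("LASSO kept no features; falling back to top univariate feature")
    p <- vapply(seq_len(ncol(X)), function(j) .rankSumP(X[, j], yb == 0), 0)
    best <- colnames(X)[which.min(p)]
    list(selected = best, coefficients = setNames(0, best))
  })
}

#' SMOTE minority oversampling
#'
#' Equalizes the two classes by interpolating synthetic minority rows: each
#' synthetic row is `x + u * (neighbor - x)` with `u ~ Uniform(0, 1)` and
#' `neighbor` one of the `k` nearest minority neighbors of a random minority
#' row. Original rows are preserved verbatim.
#'
#' @param X numeric matrix.
#' @param y class vector (two levels).
#' @param k neighbors (default 5; reduced with a warning when the minority
#'   class is too small, error below 2 minority rows).
#' @param seed seed.
#' @return List with `X`, `y` (balanced), and `synthetic` (logical flag per
#'   row).
#' @export
smoteBalance <- function(X, y, k = 5, seed = 1) {
  tab <- table(y)
  if (length(tab) != 2) .stopf("smoteBalance expects exactly 2 classes")
  minClass <- names(tab)[which.min(tab)]
  nMin <- min(tab); nMaj <- max(tab)
  if (nMin < 2) .stopf("minority class needs >= 2 samples")
  if (nMin == nMaj)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  if (nMin <= k) {
    k <- nMin - 1
    .warnf("minority class has %d samples; reducing SMOTE k to %d", nMin, k)
  }
  Xmin <- X[y == minClass, , drop = FALSE]
  D <- as.matrix(dist(Xmin))
  diag(D) <- Inf
  nn <- matrix(apply(D, 1, function(dr) order(dr)[seq_len(k)]),
               nrow = nrow(Xmin), ncol = k, byrow = TRUE)
  nNew <- nMaj - nMin
  .withSeed(seed, {
    seedIdx <- sample(rep(seq_len(nMin), length.out = nNew))
    nbIdx <- nn[cbind(seedIdx, sample.int(k, nNew, replace = TRUE))]
    u <- runif(nNew)
    Xnew <- Xmin[seedIdx, , drop = FALSE] +
      u * (Xmin[nbIdx, , drop = FALSE] - Xmin[seedIdx, , drop = FALSE])
    rownames(Xnew) <- sprintf("smote_%d", seq_len(nNew))
    list(X = rbind(X, Xnew),
         y = c(y, rep(minClass, nNew)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nNew)))
  })
}

#' Run the full selection chain for one sub-task
#'
#' Scaling -> Spearman redundancy filter -> rank-sum filter -> LASSO,
#' fitted on training rows only. Returns the [SelectionReport-class] plus
#' the fitted scaler.
#'
#' @param X training matrix (images x features, named columns).
#' @param y binary labels per row.
#' @param task `"a"` or `"b"` (bookkeeping tag).
#' @param rhoMax,alpha,seed chain parameters.
#' @return List with `report` ([SelectionReport-class]) and `scaler`.
#' @export
selectionChain <- function(X, y, task = "a", rhoMax = 0.95, alpha = 0.05,
                           seed = 1) {
  scaler <- fitScaler(X)
  Xs <- applyScaler(scaler, X)
  keptCor <- correlationFilter(Xs, rhoMax)
  wil <- wilcoxonFilter(Xs[, keptCor, drop = FALSE], y, alpha)
  if (!length(wil$kept)) {
    .warnf("rank-sum filter kept no features for task (%s); keeping the %d",
           task, 1L)
    wil$kept <- names(sort(wil$p))[1]
  }
  las <- lassoSelect(Xs[, wil$kept, drop = FALSE], y, seed = seed)
  report <- new("SelectionReport", task = task,
                keptAfterCorrelation = keptCor,
                keptAfterWilcoxon = wil$kept,
                wilcoxonP = wil$p,
                selected = las$selected,
                coefficients = las$coefficients,
                thresholds = c(rhoMax = rhoMax, alpha = alpha))
  list(report = report, scaler = scaler)
}
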