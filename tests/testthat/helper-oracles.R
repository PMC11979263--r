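## Independent brute-force oracles for the texture-matrix families.
## Deliberately naive (explicit loops / recursion) so they share no code
## with the package implementations they check. Intended for tiny images.

bfGLCMdir <- function(lev, nLevels, dr, dc) {
  M <- matrix(0, nLevels, nLevels)
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(lev) && c2 >= 1 && c2 <= ncol(lev)) {
      M[lev[r, c], lev[r2, c2]] <- M[lev[r, c], lev[r2, c2]] + 1
      M[lev[r2, c2], lev[r, c]] <- M[lev[r2, c2], lev[r, c]] + 1
    }
  }
  M
}

bfGLCM <- function(lev, nLevels) {
  dirs <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  acc <- matrix(0, nLevels, nLevels)
  for (d in dirs) {
    M <- bfGLCMdir(lev, nLevels, d[1], d[2])
    acc <- acc + M / sum(M)
  }
  acc / length(dirs)
}

## runs along an explicit list of index paths
bfRuns <- function(lev, paths, nLevels, maxRun) {
  P <- matrix(0, nLevels, maxRun)
  for (pth in paths) {
    vals <- lev[pth]
    i <- 1
    while (i <= length(vals)) {
      j <- i
      while (j < length(vals) && vals[j + 1] == vals[i]) j <- j + 1
      P[vals[i], j - i + 1] <- P[vals[i], j - i + 1] + 1
      i <- j + 1
    }
  }
  P
}

bfGLRLM <- function(lev, nLevels) {
  nr <- nrow(lev); nc <- ncol(lev)
  maxRun <- max(nr, nc)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  horiz <- lapply(seq_len(nr), function(r) idx[r, ])
  vert <- lapply(seq_len(nc), function(c) idx[, c])
  dr <- list(); dl <- list()
  for (s in (1 - nr):(nc - 1)) { # down-right diagonals, offset s = c - r
    cells <- which(col(lev) - row(lev) == s)
    dr[[length(dr) + 1]] <- cells[order(row(lev)[cells])]
  }
  for (s in 2:(nr + nc)) {       # down-left diagonals, s = c + r
    cells <- which(col(lev) + row(lev) == s)
    dl[[length(dl) + 1]] <- cells[order(col(lev)[cells])]
  }
  (bfRuns(lev, horiz, nLevels, maxRun) + bfRuns(lev, vert, nLevels, maxRun) +
     bfRuns(lev, dr, nLevels, maxRun) + bfRuns(lev, dl, nLevels, maxRun)) / 4
}

## 8-connected flood fill
bfGLSZM <- function(lev, nLevels) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        r <- cur[1] + dr; c <- cur[2] + dc
        if ((dr || dc) && r >= 1 && r <= nr && c >= 1 && c <= nc &&
            !seen[r, c] && lev[r, c] == lev[r0, c0]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev[r0, c0], size)
  }
  maxSize <- max(vapply(zones, `[`, 0, 2))
  P <- matrix(0, nLevels, maxSize)
  for (z in zones) P[z[1], z[2]] <- P[z[1], z[2]] + 1
  P
}

bfNGTDM <- function(lev, nLevels) {
  nr <- nrow(lev); nc <- ncol(lev)
  s <- numeric(nLevels); n <- numeric(nLevels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if ((dr || dc) && r + dr >= 1 && r + dr <= nr &&
          c + dc >= 1 && c + dc <= nc)
        nb <- c(nb, lev[r + dr, c + dc])
    }
    i <- lev[r, c]
    n[i] <- n[i] + 1
    s[i] <- s[i] + abs(i - mean(nb))
  }
  data.frame(level = seq_len(nLevels), n = n, s = s)
}

bfGLDM <- function(lev, nLevels) {
  nr <- nrow(lev); nc <- ncol(lev)
  deps <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if ((dr || dc) && r + dr >= 1 && r + dr <= nr &&
          c + dc >= 1 && c + dc <= nc && lev[r + dr, c + dc] == lev[r, c])
        d <- d + 1
    }
    deps[r, c] <- d
  }
  P <- matrix(0, nLevels, max(deps))
  for (k in seq_along(deps)) P[lev[k], deps[k]] <- P[lev[k], deps[k]] + 1
  P
}

## exact two-sided rank-sum p-value by full enumeration of group assignments
bfRankSumP <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(all), n1)
  r <- rank(all)
  obs <- sum(r[seq_len(n1)])
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}
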