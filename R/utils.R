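## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded package operations never perturb user-level randomness.
#' @noRd
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a master seed and a stage tag
#'
#' Keeps every stochastic stage independently reseedable from one global
#' seed. Result is always a valid 32-bit R integer.
#' @noRd
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.isCount <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x >= min && x == as.integer(x)
}

#' Largest-remainder apportionment of n into groups by fractional proportions
#' @noRd
.apportion <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Min-max normalization to [0, 1]; zero-range input maps to all zeros
#' @noRd
.minmax <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

## Class labels used throughout; order encodes increasing severity.
.CLASSES <- c("noCAD", "nonobstructive", "obstructive")

#' Map per-patient maximum stenosis fraction to the three-class label
#' @noRd
.classFromStenosis <- function(maxFraction) {
  ifelse(maxFraction <= 0, "noCAD",
         ifelse(maxFraction < 0.5, "nonobstructive", "obstructive"))
}
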