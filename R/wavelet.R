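## Single-level separable 2D wavelet decomposition, undecimated (stationary)
## with periodic boundary handling, so every band keeps the spatial shape of
## the input. The kernel is Coiflet-1, the common radiomics default. Filters
## are scaled by 1/sqrt(2) per dimension so the four band energies sum to
## the input energy exactly (Parseval identity for the orthonormal pair).

## Coiflet-1 decomposition filters (orthonormal: sum lo = sqrt(2), energy 1)
.COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578, 0.8525720202116004,
               0.3378976624574818, -0.07273261951252645)
.COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
               -0.8525720202116004, 0.3848648468648578,
               0.07273261951252645, -0.015655728135791993)

## Circulant convolution matrix: (Mx)_i = sum_k f[k] x[(i + k - 1) mod n + 1]
.circulant <- function(f, n) {
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(f)) {
    j <- ((i + k - 2L) %% n) + 1L
    M[cbind(i, j)] <- M[cbind(i, j)] + f[k]
  }
  M
}

#' Single-level 2D wavelet decomposition of an image
#'
#' Undecimated separable transform with the Coiflet-1 kernel and periodic
#' boundaries; each band has the spatial shape of the input. Band naming:
#' the first letter is the filter applied along rows (the vessel axis), the
#' second along columns, with "L" low-pass and "H" high-pass. Filters are
#' normalized so that the energies of LL + LH + HL + HH equal the input
#' energy.
#'
#' @param pixels numeric matrix (finite values).
#' @return Named list of matrices `LL`, `LH`, `HL`, `HH`.
#' @examples
#' b <- waveletDecompose(matrix(1, 8, 8))
#' max(abs(b$HH)) # ~0: high-pass of a constant
#' @export
waveletDecompose <- function(pixels) {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    .stopf("waveletDecompose expects a finite numeric matrix")
  lo <- .COIF1_LO / sqrt(2)
  hi <- .COIF1_HI / sqrt(2)
  Lr <- .circulant(lo, nrow(pixels)); Hr <- .circulant(hi, nrow(pixels))
  Lc <- .circulant(lo, ncol(pixels)); Hc <- .circulant(hi, ncol(pixels))
  LX <- Lr %*% pixels; HX <- Hr %*% pixels
  list(LL = LX %*% t(Lc), LH = LX %*% t(Hc),
       HL = HX %*% t(Lc), HH = HX %*% t(Hc))
}
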