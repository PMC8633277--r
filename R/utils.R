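#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

## Gaussian low-pass of a real or complex matrix, replicate-padded FFT
## convolution.  `sigma_px` in pixels; sigma 0 returns the input unchanged.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  pad <- ceiling(4 * sigma_px)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, pad), seq_len(nr), rep(nr, pad))
  ci <- c(rep(1L, pad), seq_len(nc), rep(nc, pad))
  mp <- m[ri, ci, drop = FALSE]
  nR <- nrow(mp); nC <- ncol(mp)
  g1 <- function(n) {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    exp(-2 * pi^2 * sigma_px^2 * f^2)  # FT of unit-area Gaussian
  }
  ker <- outer(g1(nR), g1(nC))
  out <- stats::fft(stats::fft(mp) * ker, inverse = TRUE) / (nR * nC)
  if (is.numeric(m)) out <- Re(out)
  out[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
}

## Bilinear interpolation of matrix `m` at fractional 1-based (row, col)
## positions.  Out-of-range positions return NA.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  r0 <- pmin(pmax(floor(row), 1), nr - 1)
  c0 <- pmin(pmax(floor(col), 1), nc - 1)
  fr <- row - r0
  fc <- col - c0
  v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
    fr * (1 - fc) * m[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * m[cbind(r0, c0 + 1)] +
    fr * fc * m[cbind(r0 + 1, c0 + 1)]
  v[!ok] <- NA_real_
  v
}

## squared-distance field |r - r0|^2 on a voxel grid, pixel centers at
## (index - 0.5) * pitch, index order (z, y, x)
dist2_grid <- function(dims, pitch, center) {
  z2 <- ((seq_len(dims[1]) - 0.5) * pitch[1] - center[1])^2
  y2 <- ((seq_len(dims[2]) - 0.5) * pitch[2] - center[2])^2
  x2 <- ((seq_len(dims[3]) - 0.5) * pitch[3] - center[3])^2
  outer(outer(z2, y2, `+`), x2, `+`)
}
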