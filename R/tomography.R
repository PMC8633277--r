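## Serial-section registration and tomographic volume assembly.
## Registration is phase correlation with upsampled sub-pixel refinement
## (matrix-multiply DFT in a small neighborhood of the coarse peak) and an
## optional small-angle rotation search.

#' Rigid 2-D transform
#'
#' Translation (sub-pixel) plus small rotation about the image center.
#' Applying the transform moves image content by (+dx, +dy) pixels after
#' rotating it by `rot_rad`.
#'
#' @param dx_px,dy_px translation in pixels.
#' @param rot_rad rotation in radians.
#' @param ok logical registration-confidence flag.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, rot_rad = 0, ok = TRUE) {
  structure(list(dx_px = dx_px, dy_px = dy_px, rot_rad = rot_rad, ok = ok),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx=%.3f dy=%.3f rot=%.4f rad%s\n",
              x$dx_px, x$dy_px, x$rot_rad,
              if (x$ok) "" else " [low confidence]"))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform equivalent to applying `b`
#' first, then `a` (small-angle composition: rotations add, translations
#' rotate).
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  ca <- cos(a$rot_rad); sa <- sin(a$rot_rad)
  rigid_transform(a$dx_px + ca * b$dx_px - sa * b$dy_px,
                  a$dy_px + sa * b$dx_px + ca * b$dy_px,
                  a$rot_rad + b$rot_rad, a$ok && b$ok)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @return the inverse transform.
#' @export
invert_transform <- function(tr) {
  ct <- cos(tr$rot_rad); st <- sin(tr$rot_rad)
  rigid_transform(-(ct * tr$dx_px + st * tr$dy_px),
                  -(-st * tr$dx_px + ct * tr$dy_px),
                  -tr$rot_rad, tr$ok)
}

#' Apply a rigid transform to an image
#'
#' Bilinear resampling; pixels sampled from outside the frame become NA.
#'
#' @param image numeric matrix.
#' @param tr a `rigid_transform`.
#' @return transformed matrix, same shape, NA outside the source frame.
#' @export
apply_transform <- function(image, tr) {
  ny <- nrow(image); nx <- ncol(image)
  cyx <- c((ny + 1) / 2, (nx + 1) / 2)
  yy <- matrix(seq_len(ny), ny, nx) - cyx[1] - tr$dy_px
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cyx[2] - tr$dx_px
  ct <- cos(tr$rot_rad); st <- sin(tr$rot_rad)
  sy <- ct * yy + st * xx + cyx[1]
  sx <- -st * yy + ct * xx + cyx[2]
  matrix(bilinear(image, as.vector(sy), as.vector(sx)), ny, nx)
}

## cross-correlation surface by matrix-multiply DFT on an upsampled grid
## around (dy0, dx0); CP is the cross-power spectrum (fft(fixed)*Conj(fft(mov)))
upsampled_xcorr <- function(CP, dy0, dx0, upsample, radius = 1.5) {
  ny <- nrow(CP); nx <- ncol(CP)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  dy <- dy0 + seq(-radius, radius, by = 1 / upsample)
  dx <- dx0 + seq(-radius, radius, by = 1 / upsample)
  Ey <- exp(2i * pi * outer(dy, fy))      # |dy| x ny
  Ex <- exp(2i * pi * outer(fx, dx))      # nx x |dx|
  cc <- Re(Ey %*% CP %*% Ex)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  list(dy = dy[pk[1]], dx = dx[pk[2]], value = max(cc))
}

register_translation <- function(fixed, moving, upsample = 10,
                                 confidence = 0.05) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  F1 <- stats::fft(fixed - mean(fixed))
  F2 <- stats::fft(moving - mean(moving))
  CP <- F1 * Conj(F2)
  den <- Mod(CP)
  if (max(den) == 0) return(NULL)      # blank against blank
  ## whitened correlation for the coarse integer peak
  r <- Re(stats::fft(CP / pmax(den, 1e-12 * max(den)), inverse = TRUE)) /
    (ny * nx)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy0 <- pk[1] - 1; if (dy0 > ny / 2) dy0 <- dy0 - ny
  dx0 <- pk[2] - 1; if (dx0 > nx / 2) dx0 <- dx0 - nx
  if (max(r) < confidence) return(NULL)
  ## sub-pixel refinement on the (unwhitened) cross-correlation
  fine <- upsampled_xcorr(CP, dy0, dx0, upsample)
  norm <- sqrt(sum(Mod(F1)^2) * sum(Mod(F2)^2))
  list(dy = fine$dy, dx = fine$dx, score = fine$value / norm)
}

#' Register one image pair
#'
#' Estimates the rigid transform mapping `moving` onto `fixed` by phase
#' correlation (whitened cross-power for the coarse peak, upsampled
#' cross-correlation for sub-pixel refinement; default upsampling factor
#' 10).  If `rotation = TRUE`, a coarse search over +/- `rot_range_deg`
#' in `rot_step_deg` steps precedes the translation estimate.
#'
#' On low correlation confidence the returned transform is the identity
#' flagged with `ok = FALSE`.
#'
#' @param fixed,moving numeric matrices of equal shape.
#' @param upsample sub-pixel upsampling factor.
#' @param rotation search for a small rotation as well.
#' @param rot_range_deg,rot_step_deg rotation search range and step.
#' @param confidence minimum whitened-correlation peak.
#' @return a `rigid_transform` such that
#'   `apply_transform(moving, tr)` is aligned with `fixed`.
#' @export
register_pair <- function(fixed, moving, upsample = 10, rotation = FALSE,
                          rot_range_deg = 3, rot_step_deg = 0.25,
                          confidence = 0.05) {
  if (!all(dim(fixed) == dim(moving)))
    stop_domain("images must share shape")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    return(rigid_transform(ok = FALSE))
  if (!rotation) {
    est <- register_translation(fixed, moving, upsample, confidence)
    if (is.null(est)) return(rigid_transform(ok = FALSE))
    return(rigid_transform(est$dx, est$dy, 0))
  }
  angles <- seq(-rot_range_deg, rot_range_deg, by = rot_step_deg) * pi / 180
  best <- NULL
  for (th in angles) {
    rot <- apply_transform(moving, rigid_transform(0, 0, th))
    rot[is.na(rot)] <- mean(moving)
    est <- register_translation(fixed, rot, upsample, confidence)
    if (!is.null(est) && (is.null(best) || est$score > best$score)) {
      best <- est
      best$th <- th
    }
  }
  if (is.null(best)) return(rigid_transform(ok = FALSE))
  rigid_transform(best$dx, best$dy, best$th)
}

#' Register an ordered stack of images
#'
#' Pairwise registration of consecutive sections accumulated into the
#' frame of the first image.  Low-confidence pairs are flagged and
#' contribute an identity increment.
#'
#' @param images list of numeric matrices (>= 2, equal shape).
#' @param ... passed to [register_pair()].
#' @return list of `rigid_transform` (first is the identity), each mapping
#'   its image into the frame of image 1.
#' @export
register_stack <- function(images, ...) {
  if (length(images) < 2) stop_domain("need at least 2 images")
  out <- vector("list", length(images))
  out[[1]] <- rigid_transform()
  acc <- rigid_transform()
  for (i in seq_along(images)[-1]) {
    tr <- register_pair(images[[i - 1]], images[[i]], ...)
    acc <- compose_transforms(acc,
                              if (tr$ok) tr else rigid_transform(ok = FALSE))
    acc$ok <- tr$ok
    out[[i]] <- acc
  }
  out
}

#' Assemble registered sections into a voxel volume
#'
#' Resamples each image under its transform into the common frame and
#' stacks them along z.  Out-of-frame voxels are NA and excluded from any
#' statistics.  Voxels are anisotropic:
#' (pixel_pitch, pixel_pitch, dz) nm.
#'
#' @param images list of numeric matrices (equal shape).
#' @param transforms list of `rigid_transform`, one per image.
#' @param dz_nm section thickness (voxel z-dimension), nm.
#' @param pixel_pitch_nm in-plane pixel pitch, nm.
#' @return a `voxel_volume`: `grid` (z, y, x array), `voxel_nm`
#'   (dx, dy, dz), `z_extent_nm`, per-slice `transforms`.
#' @export
assemble_tomogram <- function(images, transforms, dz_nm = 100,
                              pixel_pitch_nm = 20) {
  if (length(images) != length(transforms))
    stop_domain("images and transforms must have equal length")
  if (dz_nm <= 0) stop_domain("dz must be > 0")
  nz <- length(images)
  ny <- nrow(images[[1]]); nx <- ncol(images[[1]])
  grid <- array(NA_real_, dim = c(nz, ny, nx))
  for (i in seq_len(nz)) {
    tr <- transforms[[i]]
    grid[i, , ] <- if (tr$dx_px == 0 && tr$dy_px == 0 && tr$rot_rad == 0)
      images[[i]] else apply_transform(images[[i]], tr)
  }
  structure(
    list(grid = grid,
         voxel_nm = c(dx = pixel_pitch_nm, dy = pixel_pitch_nm,
                      dz = dz_nm),
         z_extent_nm = nz * dz_nm, transforms = transforms),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(paste0("<voxel_volume> %d slices of %d x %d px; voxel ",
                     "%g x %g x %g nm (%.3g L); z extent %g nm\n"),
              d[1], d[2], d[3], x$voxel_nm[1], x$voxel_nm[2],
              x$voxel_nm[3], voxel_volume_liters(x$voxel_nm),
              x$z_extent_nm))
  invisible(x)
}

#' Voxel volume in liters
#'
#' Product of the three voxel dimensions converted from nm^3 to liters
#' (1 nm^3 = 1e-24 L); e.g. a 20 x 20 x 1000 nm voxel is 4e-19 L (400 zL).
#'
#' @param dims_nm voxel dimensions (nm), length 3.
#' @return volume in liters.
#' @export
voxel_volume_liters <- function(dims_nm) {
  if (length(dims_nm) != 3 || any(dims_nm <= 0))
    stop_domain("dims must be three positive lengths")
  prod(as.numeric(dims_nm)) * 1e-24
}
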