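## Single-wavenumber raster imaging of a phantom section: simultaneous
## topography, near-field amplitude and phase maps, plus the profile-based
## measurements (10-90 edge width, feature FWHM, azimuthal peak counts).

#' Raster-scan a section at a single wavenumber
#'
#' Looks up the per-material complex demodulated near-field response,
#' paints it onto the section's label map, applies a lateral Gaussian
#' point-spread kernel (FWHM = apex diameter / sqrt(n): the n-th harmonic
#' samples the n-th power of the confined tip field), and samples the
#' blurred complex field at the requested pixel pitch.  Topography is a
#' configured per-material relief smoothed with the same kernel.  Phase is
#' referenced to the gold response so that absorbing materials appear at
#' positive phase.
#'
#' @param section a `phantom_section` (see [get_section()],
#'   [label_section()]).
#' @param wavenumber imaging wavenumber, cm^-1.
#' @param tip a [tip_model()].
#' @param n demodulation harmonic.
#' @param pixel_pitch_nm output pixel pitch (default 20); must be >= the
#'   section pitch.
#' @param noise_sd per-channel additive Gaussian noise, a named vector with
#'   any of `topography` (nm), `amplitude` (fraction of the gold
#'   amplitude), `phase` (rad); default all zero.
#' @param relief_nm named per-material height offsets (nm); unnamed
#'   materials default to +2 nm for cellular material over resin-like
#'   labels at 0.
#' @param seed integer seed for the noise draws.
#' @return a `scan_image` with matrices `topography_nm`, `amplitude`,
#'   `phase_rad` (wrapped to (-pi, pi]), shared `pixel_pitch_nm`, and
#'   provenance.
#' @export
raster_scan <- function(section, wavenumber, tip = tip_model(), n = 2L,
                        pixel_pitch_nm = 20, noise_sd = c(topography = 0,
                                                          amplitude = 0,
                                                          phase = 0),
                        relief_nm = NULL, seed = 1L) {
  stopifnot(inherits(section, "phantom_section"))
  if (pixel_pitch_nm < section$pitch_nm)
    stop_domain("pixel_pitch must be >= the section pitch")
  lab <- section$labels
  codes <- section$label_names
  present <- sort(unique(as.vector(lab)))

  resp <- vapply(present, function(cd) {
    nm <- names(codes)[match(cd, codes)]
    scattered_signal(section$material_table[[nm]], wavenumber, tip, n)$z
  }, complex(1))
  z_gold <- scattered_signal(gold_reference(), wavenumber, tip, n)$z

  if (is.null(relief_nm)) {
    relief_nm <- stats::setNames(rep(2, length(codes)), names(codes))
    relief_nm[names(relief_nm) %in% c("resin", "vacuole")] <- 0
  }
  relief <- vapply(present, function(cd) {
    nm <- names(codes)[match(cd, codes)]
    unname(relief_nm[nm] %||% 2)
  }, numeric(1))

  idx <- match(lab, present)
  F <- matrix(resp[idx], nrow(lab), ncol(lab))
  topo <- matrix(relief[idx], nrow(lab), ncol(lab))

  psf_fwhm <- 2 * tip$apex_radius_nm / sqrt(n)
  sigma_px <- psf_fwhm / (2 * sqrt(2 * log(2))) / section$pitch_nm
  F <- gaussian_blur(F, sigma_px)
  topo <- gaussian_blur(topo, sigma_px)

  ## sample at output pixel centers
  step <- pixel_pitch_nm / section$pitch_nm
  ny <- floor(nrow(lab) / step)
  nx <- floor(ncol(lab) / step)
  ry <- (seq_len(ny) - 0.5) * step + 0.5
  rx <- (seq_len(nx) - 0.5) * step + 0.5
  samp <- function(m) {
    rr <- matrix(ry, ny, nx)
    cc <- matrix(rx, ny, nx, byrow = TRUE)
    matrix(bilinear(m, as.vector(rr), as.vector(cc)), ny, nx)
  }
  Fz <- matrix(complex(real = samp(Re(F)), imaginary = samp(Im(F))), ny, nx)
  topo_s <- samp(topo)

  amp <- Mod(Fz)
  phs <- wrap_phase(Arg(Fz) - Arg(z_gold))

  ns <- c(topography = 0, amplitude = 0, phase = 0)
  ns[names(noise_sd)] <- noise_sd
  if (any(ns > 0)) {
    noise <- with_seed(seed, list(
      t = stats::rnorm(ny * nx, 0, max(ns[["topography"]], 1e-300)),
      a = stats::rnorm(ny * nx, 0, max(ns[["amplitude"]], 1e-300)),
      p = stats::rnorm(ny * nx, 0, max(ns[["phase"]], 1e-300))))
    if (ns[["topography"]] > 0) topo_s <- topo_s + noise$t
    if (ns[["amplitude"]] > 0) amp <- amp + noise$a * Mod(z_gold)
    if (ns[["phase"]] > 0) phs <- wrap_phase(phs + noise$p)
  }

  structure(
    list(wavenumber = wavenumber, harmonic = as.integer(n),
         pixel_pitch_nm = pixel_pitch_nm, topography_nm = topo_s,
         amplitude = amp, phase_rad = phs,
         provenance = list(section_index = section$section_index,
                           section_pitch_nm = section$pitch_nm,
                           tip = unclass(tip), psf_fwhm_nm = psf_fwhm,
                           noise_sd = ns, seed = seed)),
    class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf(paste0("<scan_image> %d x %d px at %g nm, nu = %g cm^-1,",
                     " n = %d\n"),
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_pitch_nm,
              x$wavenumber, x$harmonic))
  invisible(x)
}

#' @export
plot.scan_image <- function(x, channel = c("phase", "amplitude",
                                           "topography"), ...) {
  channel <- match.arg(channel)
  m <- scan_channel(x, channel)
  graphics::image(t(m)[, nrow(m):1], asp = nrow(m) / ncol(m),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE,
                  main = sprintf("%s @ %g cm^-1", channel, x$wavenumber),
                  ...)
  invisible(x)
}

scan_channel <- function(image, channel) {
  switch(channel,
         topography = image$topography_nm,
         amplitude = image$amplitude,
         phase = image$phase_rad,
         stop_domain("unknown channel: ", channel))
}

#' Line profile across a scan channel
#'
#' Samples the channel by bilinear interpolation along the segment from
#' `p0` to `p1` (pixel coordinates, (x, y), 1-based), averaging over
#' `width_px` parallel lines spaced one pixel apart perpendicular to the
#' segment.
#'
#' @param image a `scan_image`.
#' @param channel "topography", "amplitude" or "phase".
#' @param p0,p1 segment endpoints, c(x, y) in pixels.
#' @param width_px averaging width in pixels (odd).
#' @param step_px sampling step along the segment (default 0.25 px).
#' @return data.frame with `distance_nm` and `value`.
#' @export
line_profile <- function(image, channel, p0, p1, width_px = 1,
                         step_px = 0.25) {
  stopifnot(inherits(image, "scan_image"))
  m <- scan_channel(image, channel)
  if (min(p0, p1) < 1 || max(p0[1], p1[1]) > ncol(m) ||
      max(p0[2], p1[2]) > nrow(m))
    stop_domain("range error: endpoints outside image")
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop_domain("degenerate profile: p0 == p1")
  u <- (p1 - p0) / L
  v <- c(-u[2], u[1])
  s <- seq(0, L, by = step_px)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  acc <- 0
  for (o in offs) {
    px <- p0[1] + s * u[1] + o * v[1]
    py <- p0[2] + s * u[2] + o * v[2]
    acc <- acc + bilinear(m, py, px)
  }
  data.frame(distance_nm = s * image$pixel_pitch_nm,
             value = acc / width_px)
}

#' 10-90% edge width of a step profile
#'
#' Normalizes the profile between its two plateau levels (means of the
#' outer 10% of samples at each end), requires a monotone edge (single
#' mid-level crossing after light smoothing), and returns the distance
#' between the 10% and 90% crossings, linearly interpolated.
#'
#' @param profile data.frame from [line_profile()] (`distance_nm`,
#'   `value`).
#' @return edge width in nm.
#' @export
edge_width_10_90 <- function(profile) {
  x <- profile$distance_nm
  y <- profile$value
  n <- length(y)
  if (n < 8) stop_domain("profile too short for an edge fit")
  k <- max(2, floor(n * 0.1))
  lo <- mean(y[seq_len(k)])
  hi <- mean(y[seq(n - k + 1, n)])
  if (abs(hi - lo) < .Machine$double.eps^0.5)
    stop_domain("fit-failure: no step between profile ends")
  p <- (y - lo) / (hi - lo)
  ps <- stats::filter(p, rep(1 / 3, 3), sides = 2)
  ps[c(1, n)] <- p[c(1, n)]
  crossings <- which(diff(ps > 0.5) != 0)
  if (length(crossings) != 1)
    stop_domain("fit-failure: edge is not monotone (",
                length(crossings), " mid-level crossings)")
  cross_at <- function(level) {
    i <- which(diff(p > level) != 0)
    i <- i[which.min(abs(i - crossings))]
    x[i] + (level - p[i]) / (p[i + 1] - p[i]) * (x[i + 1] - x[i])
  }
  abs(cross_at(0.9) - cross_at(0.1))
}

#' Full width at half maximum of a single-peak profile
#'
#' Baseline is the median of the outer 10% of samples at both ends; the
#' dominant extremum above (or below) that baseline defines the peak, and
#' the FWHM is measured between linearly interpolated half-level crossings
#' on either side.
#'
#' @param profile data.frame from [line_profile()].
#' @return FWHM in nm.
#' @export
feature_fwhm <- function(profile) {
  x <- profile$distance_nm
  y <- profile$value
  n <- length(y)
  k <- max(2, floor(n * 0.1))
  base <- stats::median(c(y[seq_len(k)], y[seq(n - k + 1, n)]))
  dev <- y - base
  if (max(abs(dev)) < .Machine$double.eps^0.5)
    stop_domain("no extremum above baseline")
  if (abs(min(dev)) > abs(max(dev))) dev <- -dev  # allow dips
  ipk <- which.max(dev)
  half <- dev[ipk] / 2
  if (dev[ipk] <= 0) stop_domain("no extremum above baseline")
  il <- max(which(dev[seq_len(ipk)] < half))
  ir <- ipk - 1 + min(which(dev[seq(ipk, n)] < half))
  if (!is.finite(il) || !is.finite(ir) || il < 1 || ir > n)
    stop_domain("half-maximum crossings outside profile")
  xl <- x[il] + (half - dev[il]) / (dev[il + 1] - dev[il]) *
    (x[il + 1] - x[il])
  xr <- x[ir - 1] + (half - dev[ir - 1]) / (dev[ir] - dev[ir - 1]) *
    (x[ir] - x[ir - 1])
  xr - xl
}

#' Count azimuthal peaks on an annulus
#'
#' Unwraps an annulus of the channel to an angular profile (1 degree
#' sampling, radial averaging across the annulus width) and counts local
#' maxima above the annulus median, with circular boundary handling.  With
#' a period hint, maxima closer than half the expected angular period are
#' merged (greedy, highest first); otherwise a prominence threshold
#' relative to the profile range is applied.
#'
#' @param image a `scan_image`.
#' @param channel channel name.
#' @param center_px annulus center, c(x, y) in pixels.
#' @param radius_px annulus radius in pixels.
#' @param radial_width_px radial averaging width in pixels.
#' @param period_hint expected number of peaks (sets the minimum angular
#'   separation to half a period), or NULL.
#' @param prominence minimum peak prominence as a fraction of the profile
#'   range when no hint is given (default 0.2).
#' @return integer peak count.
#' @export
count_azimuthal_peaks <- function(image, channel, center_px, radius_px,
                                  radial_width_px = 2, period_hint = NULL,
                                  prominence = 0.2) {
  stopifnot(inherits(image, "scan_image"))
  m <- scan_channel(image, channel)
  if (center_px[1] - radius_px - radial_width_px < 1 ||
      center_px[1] + radius_px + radial_width_px > ncol(m) ||
      center_px[2] - radius_px - radial_width_px < 1 ||
      center_px[2] + radius_px + radial_width_px > nrow(m))
    stop_domain("range error: annulus outside image")
  ang <- (0:359) * pi / 180
  radii <- seq(radius_px - radial_width_px / 2,
               radius_px + radial_width_px / 2, length.out = 5)
  prof <- rowMeans(vapply(radii, function(r)
    bilinear(m, center_px[2] + r * sin(ang), center_px[1] + r * cos(ang)),
    numeric(length(ang))))
  med <- stats::median(prof)
  if (max(prof) - min(prof) < .Machine$double.eps^0.5) return(0L)
  nb <- length(prof)
  prev <- prof[c(nb, seq_len(nb - 1))]
  nxt <- prof[c(seq_len(nb - 1) + 1, 1)]
  cand <- which(prof > med & prof > prev & prof >= nxt)
  if (!length(cand)) return(0L)
  if (!is.null(period_hint)) {
    min_sep <- 360 / period_hint / 2
    ord <- cand[order(-prof[cand])]
    kept <- integer(0)
    for (i in ord) {
      d <- abs(i - kept)
      d <- pmin(d, nb - d)
      if (!length(kept) || all(d >= min_sep)) kept <- c(kept, i)
    }
    length(kept)
  } else {
    rng <- max(prof) - min(prof)
    sum(prof[cand] - med >= prominence * rng)
  }
}
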