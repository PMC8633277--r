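## Broadband nanoFTIR chain: interferogram synthesis on the reference-mirror
## axis, FFT retrieval of complex spectra, and gold-referenced near-field
## absorption.
##
## The interferogram axis is the reference-mirror displacement x (cm); the
## beam double-passes the reference arm, so the optical path difference is
## 2x and the spectral resolution is 1 / (2 * x_max).

#' Spectral grid
#'
#' Defines the wavenumber sampling of the nanoFTIR chain.  The
#' reference-mirror travel is `1 / (2 * resolution)` cm, giving a natural
#' FFT bin spacing equal to `resolution`; `zero_fill` interpolates the
#' retrieved spectrum by that factor.
#'
#' @param resolution spectral resolution in cm^-1 (default 16).
#' @param limits band limits in cm^-1 (default c(1000, 1800)).
#' @param nyquist Nyquist wavenumber of the OPD sampling (cm^-1); must be a
#'   multiple of `resolution` and exceed `limits[2]`.
#' @param zero_fill zero-filling factor for retrieval (default 4).
#' @return an object of class `spectral_grid`.
#' @export
spectral_grid <- function(resolution = 16, limits = c(1000, 1800),
                          nyquist = 3200, zero_fill = 4L) {
  if (resolution <= 0) stop_domain("resolution must be > 0")
  if (limits[1] <= 0 || limits[2] <= limits[1])
    stop_domain("band limits must be increasing and positive")
  if (nyquist <= limits[2])
    stop_domain("nyquist must exceed the upper band limit")
  nb <- nyquist / resolution
  if (abs(nb - round(nb)) > 1e-9)
    stop_domain("nyquist must be an integer multiple of resolution")
  mirror_max_cm <- 1 / (2 * resolution)
  n_samples <- as.integer(round(2 * nyquist / resolution))
  structure(
    list(resolution = resolution, limits = limits, nyquist = nyquist,
         zero_fill = as.integer(zero_fill),
         mirror_max_cm = mirror_max_cm,
         delta_x_cm = mirror_max_cm / n_samples,
         n_samples = n_samples),
    class = "spectral_grid")
}

#' Gaussian broadband source envelope
#'
#' @param center center wavenumber (cm^-1).
#' @param fwhm full width at half maximum (cm^-1).
#' @return a function of wavenumber returning the (real) source amplitude.
#' @export
source_envelope <- function(center = 1400, fwhm = 700) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  function(nu) exp(-(nu - center)^2 / (2 * s^2))
}

## complex demodulated tip response a_n(nu) for a vector of wavenumbers
material_response <- function(material, nu, tip = tip_model(), n = 2L) {
  beta <- surface_response(permittivity(material, nu))
  gap <- tapping_trace(tip)$gap_nm
  a <- tip$apex_radius_nm
  alpha <- 4 * pi * a^3
  img <- alpha / (16 * pi * (a + gap)^3)       # length N
  N <- length(gap)
  ph <- exp(-2i * pi * n * (seq_len(N) - 1) / N)
  vapply(beta, function(b)
    (2 / N) * sum(alpha * (1 + b) / (1 - b * img) * ph),
    complex(1))
}

#' Synthesize a nanoFTIR interferogram
#'
#' Computes the complex demodulated tip response of a material on the
#' grid's native wavenumber bins, weights it by the source envelope, and
#' inverse-transforms onto the mirror-displacement axis.  Gaussian detector
#' noise of standard deviation `noise_sd` is added independently to each
#' co-addition; the stored samples are the co-added mean.
#'
#' @param material an [optical_material()].
#' @param tip a [tip_model()].
#' @param n demodulation harmonic.
#' @param grid a [spectral_grid()].
#' @param envelope source envelope function (default [source_envelope()]).
#' @param noise_sd detector noise sd per co-addition (0 = noiseless),
#'   relative to the peak envelope-weighted response.
#' @param co_additions number of averaged scans (>= 1).
#' @param seed integer seed for the noise draws.
#' @return an `interferogram`: `opd_cm` (mirror axis), `samples`,
#'   `co_additions`, `harmonic`, `grid`, `seed`.
#' @export
synthesize_interferogram <- function(material, tip = tip_model(), n = 2L,
                                     grid = spectral_grid(),
                                     envelope = source_envelope(),
                                     noise_sd = 0, co_additions = 1L,
                                     seed = 1L) {
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (co_additions < 1) stop_domain("co_additions must be >= 1")
  N <- grid$n_samples
  nu_bins <- (seq_len(N / 2) - 1) * grid$resolution
  in_band <- nu_bins >= grid$limits[1] & nu_bins <= grid$limits[2]
  S <- complex(N / 2)
  S[in_band] <- material_response(material, nu_bins[in_band], tip, n) *
    envelope(nu_bins[in_band])
  j <- seq_len(N) - 1
  ## I_j = Re sum_k S_k exp(2 pi i nu_k * 2 x_j);  nu_k * 2 x_j = k j / N
  base <- Re(stats::fft(c(S, complex(N / 2)), inverse = TRUE))
  scale <- max(Mod(S))
  samples <- if (noise_sd > 0) {
    with_seed(seed, {
      acc <- numeric(N)
      for (i in seq_len(co_additions))
        acc <- acc + base + stats::rnorm(N, 0, noise_sd * scale)
      acc / co_additions
    })
  } else base
  structure(
    list(opd_cm = j * grid$delta_x_cm, samples = samples,
         co_additions = as.integer(co_additions), harmonic = as.integer(n),
         grid = grid, seed = seed),
    class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf(paste0("<interferogram> %d samples, mirror travel %.4g cm",
                     " (res %.3g cm^-1), n=%d, %d co-addition(s)\n"),
              length(x$samples), max(x$opd_cm) + x$grid$delta_x_cm,
              x$grid$resolution, x$harmonic, x$co_additions))
  invisible(x)
}

apod_window <- function(kind, N) {
  j <- seq_len(N) - 1
  switch(kind,
    none = rep(1, N),
    hann = cos(pi * j / (2 * (N - 1)))^2,   # one-sided: 1 at ZPD -> 0
    `blackman-harris` = {
      u <- pi * j / (N - 1)                  # one-sided 3-term
      0.42323 + 0.49755 * cos(u) + 0.07922 * cos(2 * u)
    },
    stop_domain("unknown apodization: ", kind))
}

#' Retrieve amplitude and phase spectra from an interferogram
#'
#' One-sided (asymmetric) Fourier transform of the real interferogram with
#' optional apodization and zero-filling.  The complex spectrum is retained
#' (no phase correction): amplitude and wrapped phase are returned on the
#' zero-filled wavenumber grid restricted to the band limits.
#'
#' @param ifg an `interferogram`.
#' @param apodization one of "hann" (default), "none", "blackman-harris".
#' @param is_reference mark the result as a reference spectrum.
#' @return a `nearfield_spectrum`: `wavenumber`, `s_n`, `phi_n`, complex
#'   `z`, `harmonic`, `grid`, `is_reference`.
#' @export
spectrum_from_interferogram <- function(ifg, apodization = "hann",
                                        is_reference = FALSE) {
  stopifnot(inherits(ifg, "interferogram"))
  dx <- diff(ifg$opd_cm)
  if (length(dx) && max(abs(dx - dx[1])) > 1e-12 * dx[1])
    stop_domain("resample error: OPD axis must be uniform")
  g <- ifg$grid
  N <- length(ifg$samples)
  w <- apod_window(apodization, N)
  padded <- c(ifg$samples * w, numeric(N * (g$zero_fill - 1)))
  Y <- stats::fft(padded) * 2 / sum(w)
  m <- seq_len(length(padded) / 2)  # positive-frequency bins, DC dropped
  nu <- (m - 1) * g$resolution / g$zero_fill
  keep <- nu >= g$limits[1] & nu <= g$limits[2]
  z <- Y[m][keep]
  structure(
    list(wavenumber = nu[keep], s_n = Mod(z),
         phi_n = wrap_phase(Arg(z)), z = z, harmonic = ifg$harmonic,
         grid = g, is_reference = is_reference),
    class = "nearfield_spectrum")
}

#' @export
print.nearfield_spectrum <- function(x, ...) {
  cat(sprintf("<nearfield_spectrum> n=%d, %d bins %g-%g cm^-1%s\n",
              x$harmonic, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber),
              if (x$is_reference) " [reference]" else ""))
  invisible(x)
}

#' Gold reference spectrum
#'
#' Noiseless reference run of the full interferogram chain on bare gold.
#'
#' @inheritParams synthesize_interferogram
#' @param apodization passed to [spectrum_from_interferogram()].
#' @return a `nearfield_spectrum` flagged as reference.
#' @export
gold_spectrum <- function(tip = tip_model(), n = 2L, grid = spectral_grid(),
                          envelope = source_envelope(),
                          apodization = "hann") {
  spectrum_from_interferogram(
    synthesize_interferogram(gold_reference(), tip, n, grid, envelope),
    apodization, is_reference = TRUE)
}

#' Referenced near-field absorption
#'
#' \deqn{A(\nu) = \frac{s_n(\nu)}{s_{n,ref}(\nu)}
#'   \sin(\varphi_n(\nu) - \varphi_{n,ref}(\nu))}
#' with the phase difference wrapped to (-pi, pi] before the sine.  The
#' reference is typically bare gold (non-absorbing, spectrally flat).
#'
#' @param sample a `nearfield_spectrum`.
#' @param reference a `nearfield_spectrum` with `is_reference = TRUE`.
#' @return an `absorption_spectrum`: `wavenumber`, `A`, `harmonic`, `grid`.
#' @export
near_field_absorption <- function(sample, reference) {
  stopifnot(inherits(sample, "nearfield_spectrum"),
            inherits(reference, "nearfield_spectrum"))
  if (!isTRUE(reference$is_reference))
    stop_domain("reference spectrum must be flagged is_reference")
  if (sample$harmonic != reference$harmonic)
    stop_domain("alignment error: harmonics differ")
  if (length(sample$wavenumber) != length(reference$wavenumber) ||
      max(abs(sample$wavenumber - reference$wavenumber)) > 1e-9)
    stop_domain("alignment error: wavenumber grids differ")
  bad <- which(reference$s_n <= 0)
  if (length(bad))
    stop_domain("division error: zero reference amplitude at bins ",
                paste(utils::head(bad, 5), collapse = ", "))
  A <- sample$s_n / reference$s_n *
    sin(wrap_phase(sample$phi_n - reference$phi_n))
  structure(
    list(wavenumber = sample$wavenumber, A = A, harmonic = sample$harmonic,
         grid = sample$grid),
    class = "absorption_spectrum")
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  pk <- find_peaks(x)
  cat(sprintf("<absorption_spectrum> n=%d, %d bins; top peak: %s\n",
              x$harmonic, length(x$wavenumber),
              if (nrow(pk)) sprintf("%.0f cm^-1 (A=%.3g)", pk$wavenumber[1],
                                    pk$height[1]) else "none"))
  invisible(x)
}

#' Locate absorption peaks
#'
#' Local maxima of A(nu) above a height threshold, separated by at least
#' `min_separation`, sorted by descending height (ties: lower wavenumber
#' first).
#'
#' @param A an `absorption_spectrum`, or a list/data.frame with
#'   `wavenumber` and values in `A`.
#' @param min_height minimum peak height (default 0).
#' @param min_separation minimum peak separation in cm^-1 (default: one
#'   resolution element).
#' @return data.frame with columns `wavenumber`, `height`.
#' @export
find_peaks <- function(A, min_height = 0, min_separation = NULL) {
  nu <- A$wavenumber
  v <- A$A
  min_separation <- min_separation %||%
    (if (!is.null(A$grid)) A$grid$resolution else diff(nu)[1])
  n <- length(v)
  cand <- which(v > min_height &
                  v > c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
  if (!length(cand))
    return(data.frame(wavenumber = numeric(0), height = numeric(0)))
  ord <- cand[order(-v[cand], nu[cand])]
  kept <- numeric(0)
  for (i in ord)
    if (!length(kept) || all(abs(nu[i] - nu[kept]) >= min_separation))
      kept <- c(kept, i)
  data.frame(wavenumber = nu[kept], height = v[kept])
}
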