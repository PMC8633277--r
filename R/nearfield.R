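## Tip-sample near-field model: quasi-electrostatic point dipole with a
## perfectly conducting spherical apex, harmonic demodulation of the
## scattered field over the tapping cycle, and pseudoheterodyne sideband
## detection/extraction.

#' Tip model
#'
#' Geometry and tapping parameters of the metallic AFM probe.  The tapping
#' frequency Omega is symbolic (default 1 cycle per unit time); only
#' frequency ratios enter the simulation.
#'
#' @param apex_radius_nm tip apex radius (default 10 nm).
#' @param tapping_amplitude_nm tapping amplitude (default 50 nm).
#' @param min_gap_nm closest tip-sample approach (default 1 nm).
#' @param tapping_frequency tapping frequency Omega in cycles per unit time.
#' @param samples_per_cycle samples of one tapping cycle (>= 64).
#' @return an object of class `tip_model`.
#' @export
tip_model <- function(apex_radius_nm = 10, tapping_amplitude_nm = 50,
                      min_gap_nm = 1, tapping_frequency = 1,
                      samples_per_cycle = 256L) {
  if (apex_radius_nm <= 0 || tapping_amplitude_nm <= 0)
    stop_domain("apex_radius and tapping_amplitude must be > 0")
  if (min_gap_nm < 0) stop_domain("min_gap must be >= 0")
  if (samples_per_cycle < 64) stop_domain("samples_per_cycle must be >= 64")
  structure(
    list(apex_radius_nm = apex_radius_nm,
         tapping_amplitude_nm = tapping_amplitude_nm,
         min_gap_nm = min_gap_nm, tapping_frequency = tapping_frequency,
         samples_per_cycle = as.integer(samples_per_cycle)),
    class = "tip_model")
}

#' Quasi-electrostatic surface response
#'
#' beta = (epsilon - 1) / (epsilon + 1), the image-dipole strength of a
#' half space with relative permittivity epsilon.
#'
#' @param epsilon complex permittivity (vectorized).
#' @return complex beta.
#' @export
surface_response <- function(epsilon) {
  epsilon <- as.complex(epsilon)
  if (any(Mod(epsilon + 1) < 1e-12))
    stop_domain("pole error: epsilon = -1")
  (epsilon - 1) / (epsilon + 1)
}

#' Effective polarizability of the coupled tip-sample system
#'
#' Point-dipole model with a perfectly conducting spherical apex of radius
#' a: bare polarizability alpha = 4 pi a^3, dressed by the image dipole at
#' tip-sample gap g,
#' \deqn{\alpha_{eff} = \frac{\alpha (1 + \beta)}
#'   {1 - \alpha \beta / (16 \pi (a + g)^3)}.}
#'
#' @param beta complex surface response.
#' @param gap_nm tip-sample gap(s), nm (>= 0); vectorized.
#' @param tip a [tip_model()].
#' @return complex effective polarizability (nm^3 units).
#' @export
effective_polarizability <- function(beta, gap_nm, tip = tip_model()) {
  if (any(gap_nm < 0)) stop_domain("gap must be >= 0")
  a <- tip$apex_radius_nm
  alpha <- 4 * pi * a^3
  den <- 1 - alpha * beta / (16 * pi * (a + gap_nm)^3)
  if (any(Mod(den) < 1e-12))
    stop_domain("resonance error: dipole denominator vanishes")
  alpha * (1 + beta) / den
}

#' Tip-sample gap over one tapping cycle
#'
#' gap(t) = min_gap + A (1 + cos(2 pi Omega t)), sampled uniformly over one
#' cycle starting at t = 0 (maximum gap).
#'
#' @param tip a [tip_model()].
#' @param n_cycles number of tapping cycles to sample.
#' @return list with `t` (time samples) and `gap_nm`.
#' @export
tapping_trace <- function(tip = tip_model(), n_cycles = 1L) {
  N <- tip$samples_per_cycle
  t <- (seq_len(N * n_cycles) - 1) / (N * tip$tapping_frequency)
  gap <- tip$min_gap_nm + tip$tapping_amplitude_nm *
    (1 + cos(2 * pi * tip$tapping_frequency * t))
  list(t = t, gap_nm = gap)
}

#' Harmonic demodulation of a sampled trace
#'
#' One-sided Fourier coefficient of a trace sampled on a uniform grid:
#' (2/N) sum_k trace_k exp(-2 pi i n k / samples_per_cycle), where n is the
#' harmonic with respect to the cycle defined by `samples_per_cycle`.
#' Fractional n is allowed (sideband demodulation) provided it lands on an
#' exact frequency bin of the full trace.
#'
#' @param trace complex or real samples.
#' @param n harmonic order (>= accessible resolution; n >= 1 for integer
#'   harmonics).
#' @param samples_per_cycle samples in one fundamental cycle (defaults to
#'   the trace length, i.e. the trace spans one cycle).
#' @return a single complex coefficient.
#' @export
demodulate <- function(trace, n, samples_per_cycle = length(trace)) {
  N <- length(trace)
  if (n < 1 / (N / samples_per_cycle) || n <= 0)
    stop_domain("harmonic must be >= 1 trace-resolution unit (DC excluded)")
  if (N < 2 * n + 2)
    stop_domain("trace too short for harmonic ", n)
  bin <- n * N / samples_per_cycle
  if (abs(bin - round(bin)) > 1e-9)
    stop_domain("harmonic does not land on an exact frequency bin")
  k <- seq_len(N) - 1
  (2 / N) * sum(trace * exp(-2i * pi * n * k / samples_per_cycle))
}

## complex near-field trace over n_cycles tapping cycles (plus optional
## gap-independent far-field background added before demodulation)
nearfield_trace <- function(material, wavenumber, tip = tip_model(),
                            n_cycles = 1L, background = 0 + 0i) {
  eps <- permittivity(material, wavenumber)
  beta <- surface_response(eps)
  tt <- tapping_trace(tip, n_cycles)
  effective_polarizability(beta, tt$gap_nm, tip) + background
}

new_nf_signal <- function(z, n) {
  structure(list(harmonic = n, s_n = Mod(z), phi_n = wrap_phase(Arg(z)),
                 z = z),
            class = "nearfield_signal")
}

#' @export
print.nearfield_signal <- function(x, ...) {
  cat(sprintf("<nearfield_signal> n=%d  s_n=%.6g  phi_n=%.4f rad\n",
              x$harmonic, x$s_n, x$phi_n))
  invisible(x)
}

#' Demodulated near-field signal of a material
#'
#' Composes permittivity -> surface response -> effective polarizability
#' over one tapping cycle and demodulates at harmonic n of the tapping
#' frequency.  A gap-independent additive far-field background contributes
#' exactly zero at n >= 1.
#'
#' @param material an [optical_material()].
#' @param wavenumber cm^-1.
#' @param tip a [tip_model()].
#' @param n demodulation harmonic (>= 1).
#' @param background complex far-field background added to the scattered
#'   field before demodulation.
#' @return a `nearfield_signal` with amplitude `s_n`, phase `phi_n` in
#'   (-pi, pi], and the raw complex coefficient `z`.
#' @export
scattered_signal <- function(material, wavenumber, tip = tip_model(),
                             n = 2L, background = 0 + 0i) {
  if (n < 1) stop_domain("harmonic n must be >= 1")
  tr <- nearfield_trace(material, wavenumber, tip, 1L, background)
  new_nf_signal(demodulate(tr, n), n)
}

#' Pseudoheterodyne configuration
#'
#' Reference-arm phase modulation: a piezo-driven mirror vibrating at
#' frequency M phase-modulates the reference beam so that near-field
#' amplitude and phase separate into sidebands at n Omega +/- m M.
#'
#' @param mirror_ratio M / Omega (default 1/16, an exact-bin choice).
#' @param modulation_depth peak phase modulation, rad (default 2.63).
#' @param reference_amplitude reference-beam amplitude rho.
#' @param sideband_orders sideband orders m used for extraction.
#' @return an object of class `psh_config`.
#' @export
psh_config <- function(mirror_ratio = 1 / 16, modulation_depth = 2.63,
                       reference_amplitude = 1, sideband_orders = c(1L, 2L)) {
  if (modulation_depth < 0) stop_domain("modulation_depth must be >= 0")
  if (mirror_ratio <= 0 || mirror_ratio >= 1)
    stop_domain("mirror_ratio must be in (0, 1)")
  inv <- 1 / mirror_ratio
  if (abs(inv - round(inv)) > 1e-9)
    stop_domain("mirror_ratio must be 1/k for integer k (exact common period)")
  structure(
    list(mirror_ratio = mirror_ratio, modulation_depth = modulation_depth,
         reference_amplitude = reference_amplitude,
         sideband_orders = as.integer(sideband_orders),
         cycles_per_period = as.integer(round(inv))),
    class = "psh_config")
}

#' Pseudoheterodyne detector intensity
#'
#' Interferes a complex scattered-field trace with the phase-modulated
#' reference beam: I(t) = |E_s(t) + rho exp(i gamma sin(2 pi M t))|^2.
#' The trace must span exactly one common period of the tapping and mirror
#' frequencies (`cfg$cycles_per_period` tapping cycles).
#'
#' @param nf_trace complex scattered-field samples over the common period.
#' @param cfg a [psh_config()].
#' @param tip a [tip_model()] (provides samples_per_cycle).
#' @return real non-negative detector intensity samples.
#' @export
pseudoheterodyne_detect <- function(nf_trace, cfg = psh_config(),
                                    tip = tip_model()) {
  N <- length(nf_trace)
  expected <- tip$samples_per_cycle * cfg$cycles_per_period
  if (N != expected)
    stop_domain("aliasing error: trace must span one common period (",
                expected, " samples)")
  t <- (seq_len(N) - 1) / tip$samples_per_cycle  # in tapping cycles
  ref <- cfg$reference_amplitude *
    exp(1i * cfg$modulation_depth * sin(2 * pi * cfg$mirror_ratio * t))
  Mod(nf_trace + ref)^2
}

#' Recover the complex near-field signal from sideband coefficients
#'
#' Demodulates the detector intensity at the first and second upper
#' sidebands n Omega + M and n Omega + 2 M and combines them, weighted by
#' Bessel functions of the modulation depth, into the complex harmonic
#' coefficient.  An optional complex calibration factor (determined on the
#' gold reference via [psh_calibration()]) fixes the global phase/scale.
#'
#' @param intensity real detector samples from
#'   [pseudoheterodyne_detect()].
#' @param n tapping harmonic (>= 1).
#' @param cfg a [psh_config()].
#' @param tip a [tip_model()].
#' @param calibration complex factor applied to the raw extraction
#'   (default 1).
#' @return a `nearfield_signal`.
#' @export
extract_sn_phin <- function(intensity, n, cfg = psh_config(),
                            tip = tip_model(), calibration = 1 + 0i) {
  if (n < 1) stop_domain("harmonic n must be >= 1")
  if (!all(c(1L, 2L) %in% cfg$sideband_orders))
    stop_domain("extraction needs sideband orders 1 and 2")
  g <- cfg$modulation_depth
  J1 <- besselJ(g, 1)
  J2 <- besselJ(g, 2)
  if (min(abs(J1), abs(J2)) < 1e-3)
    stop_domain("ill-conditioned: modulation depth at a Bessel zero")
  M <- cfg$mirror_ratio
  spc <- tip$samples_per_cycle
  u1 <- demodulate(intensity, n + 1 * M, spc)
  u2 <- demodulate(intensity, n + 2 * M, spc)
  rho <- cfg$reference_amplitude
  ## cross-term sideband algebra for E_s(t) = sum_n a_n cos(2 pi n t):
  ## coefficient at nO + mM is (rho J_m / 2) ((-1)^m a_n + a_n*), so
  ## Re a_n = u2 / (2 rho J2) and Im a_n = i u1 / (2 rho J1).
  z <- u2 / (2 * rho * J2) + 1i * (1i * u1 / (2 * rho * J1))
  new_nf_signal(calibration * z, n)
}

#' Pseudoheterodyne gold calibration factor
#'
#' Runs the full detection/extraction chain on the gold reference and
#' compares with direct harmonic demodulation of the underlying field,
#' returning the complex ratio that maps extracted onto direct values.
#'
#' @param n tapping harmonic.
#' @param cfg a [psh_config()].
#' @param tip a [tip_model()].
#' @param wavenumber wavenumber used for the calibration (the gold
#'   reference is spectrally flat; default 1600 cm^-1).
#' @return a complex calibration factor.
#' @export
psh_calibration <- function(n = 2L, cfg = psh_config(), tip = tip_model(),
                            wavenumber = 1600) {
  au <- gold_reference()
  tr <- nearfield_trace(au, wavenumber, tip, cfg$cycles_per_period)
  direct <- demodulate(tr[seq_len(tip$samples_per_cycle)], n)
  raw <- extract_sn_phin(pseudoheterodyne_detect(tr, cfg, tip), n, cfg, tip)
  direct / raw$z
}
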