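#' Lorentz oscillator
#'
#' A single damped-oscillator contribution to a complex dielectric function,
#' parameterised by its resonance position, dimensionless strength, and
#' damping (full linewidth scale).
#'
#' @param center_wavenumber resonance position in cm^-1 (> 0).
#' @param strength dimensionless oscillator strength (>= 0).
#' @param damping damping constant in cm^-1 (> 0).
#' @return an object of class `lorentz_oscillator`.
#' @export
lorentz_oscillator <- function(center_wavenumber, strength, damping = 30) {
  if (!is.numeric(center_wavenumber) || center_wavenumber <= 0)
    stop_domain("center_wavenumber must be > 0")
  if (!is.numeric(strength) || strength < 0)
    stop_domain("strength must be >= 0")
  if (!is.numeric(damping) || damping <= 0)
    stop_domain("damping must be > 0")
  structure(
    list(center_wavenumber = center_wavenumber,
         strength = strength, damping = damping),
    class = "lorentz_oscillator")
}

#' Optical material
#'
#' Named complex dielectric function built from a high-frequency constant and
#' a sum of Lorentz oscillators.  A fixed complex permittivity can be supplied
#' via `epsilon_const` for metallic references (the gold reference mirror is
#' modelled this way).
#'
#' @param name material label.
#' @param epsilon_infinity real high-frequency dielectric constant (>= 1).
#' @param oscillators list of [lorentz_oscillator()] objects.
#' @param epsilon_const optional fixed complex permittivity overriding the
#'   oscillator model (e.g. a near-perfect mid-IR reflector).
#' @return an object of class `optical_material`.
#' @export
optical_material <- function(name, epsilon_infinity = 2,
                             oscillators = list(), epsilon_const = NULL) {
  if (is.null(epsilon_const)) {
    if (!is.numeric(epsilon_infinity) || epsilon_infinity < 1)
      stop_domain("epsilon_infinity must be a real number >= 1")
    ok <- vapply(oscillators, inherits, logical(1), "lorentz_oscillator")
    if (!all(ok)) stop_domain("oscillators must be lorentz_oscillator objects")
  } else {
    if (Im(as.complex(epsilon_const)) < 0)
      stop_domain("epsilon_const must be passive (Im >= 0)")
  }
  structure(
    list(name = name, epsilon_infinity = epsilon_infinity,
         oscillators = oscillators, epsilon_const = epsilon_const),
    class = "optical_material")
}

#' @export
print.optical_material <- function(x, ...) {
  cat("<optical_material>", x$name, "\n")
  if (!is.null(x$epsilon_const)) {
    cat("  fixed epsilon =", format(x$epsilon_const), "\n")
  } else {
    cat("  epsilon_inf =", x$epsilon_infinity, "|",
        length(x$oscillators), "oscillator(s) at",
        paste(vapply(x$oscillators, `[[`, numeric(1), "center_wavenumber"),
              collapse = ", "), "cm^-1\n")
  }
  invisible(x)
}

#' Complex permittivity of a material
#'
#' Evaluates the Lorentz-oscillator dielectric function
#' \deqn{\varepsilon(\nu) = \varepsilon_\infty + \sum_j
#'   \frac{S_j \nu_j^2}{\nu_j^2 - \nu^2 - i \gamma_j \nu}}
#' at the requested wavenumbers.  The model is passive: the imaginary part is
#' non-negative for every positive wavenumber.
#'
#' @param material an [optical_material()].
#' @param wavenumber numeric vector of wavenumbers in cm^-1 (> 0).
#' @return complex vector of relative permittivities.
#' @export
permittivity <- function(material, wavenumber) {
  stopifnot(inherits(material, "optical_material"))
  if (!is.numeric(wavenumber) || any(wavenumber <= 0))
    stop_domain("wavenumber must be positive")
  if (!is.null(material$epsilon_const))
    return(rep(as.complex(material$epsilon_const), length(wavenumber)))
  eps <- rep(complex(real = material$epsilon_infinity), length(wavenumber))
  for (o in material$oscillators) {
    eps <- eps + o$strength * o$center_wavenumber^2 /
      (o$center_wavenumber^2 - wavenumber^2 -
         1i * o$damping * wavenumber)
  }
  eps
}

#' Default material palette
#'
#' Chemically motivated dielectric models for the compartments of a
#' resin-embedded cell section.  Band positions follow common mid-IR
#' assignments: embedding-resin carbonyl (C=O) at 1738 cm^-1, protein amide I
#' at 1655 cm^-1 and amide II at 1540 cm^-1, nucleic-acid asymmetric P-O
#' (phosphate) at 1238 cm^-1, and carbohydrate C-O-C at 1155 cm^-1.
#' Oscillator strengths are free parameters chosen so that peak Im(epsilon)
#' lies in roughly 0.2-0.9; the gold reference is a fixed near-perfect
#' reflector.
#'
#' @return named list of [optical_material()] objects:
#'   `resin`, `protein`, `carbohydrate`, `nucleic`, `cell_wall`, `cytoplasm`,
#'   `nucleus`, `nucleolus`, `nuclear_body`, `pyrenoid`, `starch`,
#'   `thylakoid`, `vacuole`, `matrix`, `gold`.
#' @export
material_palette <- function() {
  osc <- function(nu, S, g = 30) lorentz_oscillator(nu, S, g)
  list(
    resin = optical_material("resin", 2.0, list(osc(1738, 0.014))),
    protein = optical_material("protein", 2.1,
      list(osc(1655, 0.015), osc(1540, 0.009))),
    carbohydrate = optical_material("carbohydrate", 2.1,
      list(osc(1155, 0.013))),
    nucleic = optical_material("nucleic", 2.1, list(osc(1238, 0.012))),
    cell_wall = optical_material("cell_wall", 2.1,
      list(osc(1655, 0.008), osc(1540, 0.005), osc(1155, 0.006))),
    # resin-penetrated cytoplasmic ground mass
    cytoplasm = optical_material("cytoplasm", 2.0,
      list(osc(1738, 0.010), osc(1655, 0.004), osc(1540, 0.002))),
    nucleus = optical_material("nucleus", 2.1,
      list(osc(1655, 0.010), osc(1540, 0.006), osc(1238, 0.004))),
    nucleolus = optical_material("nucleolus", 2.1,
      list(osc(1655, 0.013), osc(1540, 0.008), osc(1238, 0.006))),
    nuclear_body = optical_material("nuclear_body", 2.1,
      list(osc(1655, 0.016), osc(1540, 0.009))),
    pyrenoid = optical_material("pyrenoid", 2.1,
      list(osc(1655, 0.015), osc(1540, 0.009))),
    starch = optical_material("starch", 2.1, list(osc(1155, 0.014))),
    thylakoid = optical_material("thylakoid", 2.1,
      list(osc(1655, 0.013), osc(1540, 0.008), osc(1238, 0.005),
           osc(1155, 0.004))),
    vacuole = optical_material("vacuole", 2.0, list(osc(1738, 0.014))),
    # flagellar matrix: moderate, homogeneous protein content
    matrix = optical_material("matrix", 2.1,
      list(osc(1655, 0.010), osc(1540, 0.006))),
    gold = gold_reference()
  )
}

#' Gold reference material
#'
#' The spectrally flat, non-absorbing reference surface used for near-field
#' referencing, modelled as a fixed large negative permittivity
#' (near-perfect mid-IR reflector).
#'
#' @return an [optical_material()].
#' @export
gold_reference <- function() {
  optical_material("gold", epsilon_const = complex(real = -5000,
                                                   imaginary = 1000))
}
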