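## Synthetic dielectric cell phantoms: 3-D labeled voxel grids whose labels
## map to optical materials, plus serial sectioning with known misalignment.
## Coordinates are (z, y, x), 0-based physical positions with voxel centers
## at (index - 0.5) * pitch; y increases downward in images.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Geometry configuration for the default cell phantom
#'
#' All lengths in nm.  The default is a desk-scale eukaryotic cell:
#' a 2 um cell body with an 80 nm wall, nucleus with nucleolus and a 200 nm
#' spherical nuclear body, a pyrenoid wrapped in starch plates with
#' azimuthal gaps ("fingers"), parallel thylakoid lamellae, and resin-filled
#' vacuoles, embedded in resin.  Offsets are (z, y, x) relative to the cell
#' center.
#'
#' @param grid_extent_nm phantom extent (z, y, x).
#' @param voxel_pitch_nm voxel pitch per axis (z, y, x).
#' @param cell_diameter_nm,wall_thickness_nm cell body size and wall shell.
#' @param nucleus_radius_nm,nucleus_offset_nm nucleus size/placement.
#' @param nucleolus_radius_nm,nucleolus_offset_nm nucleolus inside nucleus.
#' @param nuclear_body_diameter_nm,nuclear_body_offset_nm spherical nuclear
#'   body inside the nucleus (default diameter 200 nm).
#' @param pyrenoid_radius_nm,pyrenoid_offset_nm pyrenoid placement.
#' @param starch_thickness_nm,starch_fingers starch shell around the
#'   pyrenoid and number of azimuthal plates.
#' @param thylakoid_center_nm,thylakoid_half_extent_nm,thylakoid_period_nm,thylakoid_lamella_nm
#'   thylakoid stack region and lamella spacing/thickness.
#' @param n_vacuoles,vacuole_radius_nm resin-filled vacuoles.
#' @return a list of class `cell_geometry`.
#' @export
cell_geometry <- function(grid_extent_nm = c(1300, 2560, 2560),
                          voxel_pitch_nm = c(10, 10, 10),
                          cell_diameter_nm = 2000,
                          wall_thickness_nm = 80,
                          nucleus_radius_nm = 350,
                          nucleus_offset_nm = c(0, -300, -300),
                          nucleolus_radius_nm = 150,
                          nucleolus_offset_nm = c(0, 80, 80),
                          nuclear_body_diameter_nm = 200,
                          nuclear_body_offset_nm = c(0, -150, -120),
                          pyrenoid_radius_nm = 300,
                          pyrenoid_offset_nm = c(0, 350, 350),
                          starch_thickness_nm = 60,
                          starch_fingers = 6,
                          thylakoid_center_nm = c(0, 400, -450),
                          thylakoid_half_extent_nm = c(250, 300, 220),
                          thylakoid_period_nm = 90,
                          thylakoid_lamella_nm = 30,
                          n_vacuoles = 3,
                          vacuole_radius_nm = 150) {
  g <- as.list(environment())
  if (any(g$grid_extent_nm <= 0) || any(g$voxel_pitch_nm <= 0))
    stop_domain("grid extent and voxel pitch must be positive")
  structure(g, class = "cell_geometry")
}

cell_labels <- c(resin = 0L, cell_wall = 1L, cytoplasm = 2L, nucleus = 3L,
                 nucleolus = 4L, nuclear_body = 5L, pyrenoid = 6L,
                 starch = 7L, thylakoid = 8L, vacuole = 9L)

new_cell_phantom <- function(label_grid, voxel_pitch, label_names,
                             material_table, provenance) {
  stopifnot(all(label_grid %in% label_names))
  structure(
    list(label_grid = label_grid, voxel_pitch_nm = voxel_pitch,
         label_names = label_names, material_table = material_table,
         provenance = provenance),
    class = "cell_phantom")
}

#' @export
print.cell_phantom <- function(x, ...) {
  d <- dim(x$label_grid)
  cat("<cell_phantom> grid", paste(d, collapse = " x "),
      "voxels (z, y, x) at", paste(x$voxel_pitch_nm, collapse = "/"),
      "nm pitch\n")
  tb <- table(factor(x$label_grid, levels = x$label_names,
                     labels = names(x$label_names)))
  cat("  compartments:", paste(names(tb)[tb > 0], collapse = ", "), "\n")
  invisible(x)
}

paint_sphere <- function(lab, dims, pitch, center, radius, code,
                         over = NULL) {
  d2 <- dist2_grid(dims, pitch, center)
  sel <- d2 <= radius^2
  if (!is.null(over)) sel <- sel & (lab %in% over)
  lab[sel] <- code
  lab
}

#' Build the default cell phantom
#'
#' Constructs a 3-D labeled voxel phantom of a resin-embedded cell cross
#' section stack: resin background, 80 nm cell-wall shell, resin-penetrated
#' cytoplasm, nucleus/nucleolus with a 200 nm spherical nuclear body,
#' pyrenoid with starch plates, thylakoid lamellae, and resin-filled
#' vacuoles.  Deterministic for a fixed seed.
#'
#' @param geometry a [cell_geometry()] configuration.
#' @param seed integer seed controlling vacuole placement.
#' @return a `cell_phantom`: fields `label_grid` (integer (z, y, x) array),
#'   `voxel_pitch_nm`, `label_names`, `material_table`, `provenance`.
#' @export
build_cell_phantom <- function(geometry = cell_geometry(), seed = 1L) {
  g <- geometry
  stopifnot(inherits(g, "cell_geometry"))
  pitch <- g$voxel_pitch_nm
  dims <- as.integer(round(g$grid_extent_nm / pitch))
  R <- g$cell_diameter_nm / 2
  cc <- g$grid_extent_nm / 2  # cell center (z, y, x)
  inner <- R - g$wall_thickness_nm

  ## compartment-overflow checks
  fit <- function(offset, radius, within, what)
    if (sqrt(sum(offset^2)) + radius > within)
      stop_domain("compartment does not fit: ", what)
  fit(g$nucleus_offset_nm, g$nucleus_radius_nm, inner, "nucleus")
  fit(g$nucleolus_offset_nm, g$nucleolus_radius_nm, g$nucleus_radius_nm,
      "nucleolus")
  fit(g$nuclear_body_offset_nm, g$nuclear_body_diameter_nm / 2,
      g$nucleus_radius_nm, "nuclear_body")
  fit(g$pyrenoid_offset_nm, g$pyrenoid_radius_nm + g$starch_thickness_nm,
      inner, "pyrenoid")
  fit(g$thylakoid_center_nm, 0, inner, "thylakoid")  # box is clipped below
  if (any(g$grid_extent_nm / 2 < c(0, R, R)))
    stop_domain("compartment does not fit: cell body exceeds grid")

  L <- cell_labels
  lab <- array(L[["resin"]], dim = dims)
  d2c <- dist2_grid(dims, pitch, cc)
  lab[d2c <= R^2] <- L[["cell_wall"]]
  lab[d2c <= inner^2] <- L[["cytoplasm"]]

  ## thylakoid lamellae: y-periodic plates inside a box, cytoplasm only
  tc <- cc + g$thylakoid_center_nm
  h <- g$thylakoid_half_extent_nm
  zc <- (seq_len(dims[1]) - 0.5) * pitch[1]
  yc <- (seq_len(dims[2]) - 0.5) * pitch[2]
  xc <- (seq_len(dims[3]) - 0.5) * pitch[3]
  inz <- abs(zc - tc[1]) <= h[1]
  iny <- abs(yc - tc[2]) <= h[2]
  inx <- abs(xc - tc[3]) <= h[3]
  lam <- ((yc - (tc[2] - h[2])) %% g$thylakoid_period_nm) <
    g$thylakoid_lamella_nm
  box <- outer(outer(inz, iny & lam, `&`), inx, `&`)
  sel <- box & (lab == L[["cytoplasm"]]) & d2c < (inner - 20)^2
  lab[sel] <- L[["thylakoid"]]

  ## pyrenoid + starch plates with azimuthal gaps
  pc <- cc + g$pyrenoid_offset_nm
  d2p <- dist2_grid(dims, pitch, pc)
  shell <- d2p > g$pyrenoid_radius_nm^2 &
    d2p <= (g$pyrenoid_radius_nm + g$starch_thickness_nm)^2
  ang <- atan2(rep(xc - pc[3], each = dims[2]), yc - pc[2])  # (y, x) plane
  wedge <- (ang %% (2 * pi / g$starch_fingers)) < (pi / g$starch_fingers)
  wedge3 <- aperm(array(wedge, dim = c(dims[2], dims[3], dims[1])),
                  c(3, 1, 2))
  lab[shell & wedge3 & lab == L[["cytoplasm"]]] <- L[["starch"]]
  lab[d2p <= g$pyrenoid_radius_nm^2] <- L[["pyrenoid"]]

  ## nucleus, nucleolus, nuclear body
  nc <- cc + g$nucleus_offset_nm
  lab <- paint_sphere(lab, dims, pitch, nc, g$nucleus_radius_nm,
                      L[["nucleus"]])
  lab <- paint_sphere(lab, dims, pitch, nc + g$nucleolus_offset_nm,
                      g$nucleolus_radius_nm, L[["nucleolus"]])
  nbc <- nc + g$nuclear_body_offset_nm
  lab <- paint_sphere(lab, dims, pitch, nbc,
                      g$nuclear_body_diameter_nm / 2, L[["nuclear_body"]])

  ## seeded resin-filled vacuoles, painted over cytoplasm only
  vac_centers <- with_seed(seed, {
    out <- list()
    tries <- 0
    while (length(out) < g$n_vacuoles && tries < 500) {
      tries <- tries + 1
      u <- stats::runif(2, -1, 1) * (inner - g$vacuole_radius_nm - 20)
      cand <- cc + c(0, u)
      clear <- sqrt(sum(u^2)) + g$vacuole_radius_nm < inner - 20 &&
        sqrt(sum((cand - nc)^2)) >
          g$nucleus_radius_nm + g$vacuole_radius_nm + 20 &&
        sqrt(sum((cand - pc)^2)) >
          g$pyrenoid_radius_nm + g$starch_thickness_nm +
            g$vacuole_radius_nm + 20 &&
        !all(abs(cand - tc) < h + g$vacuole_radius_nm + 20) &&
        all(vapply(out, function(p)
          sqrt(sum((cand - p)^2)) > 2 * g$vacuole_radius_nm + 20,
          logical(1)))
      if (clear) out[[length(out) + 1L]] <- cand
    }
    out
  })
  for (vc in vac_centers)
    lab <- paint_sphere(lab, dims, pitch, vc, g$vacuole_radius_nm,
                        L[["vacuole"]], over = L[["cytoplasm"]])

  pal <- material_palette()
  mt <- list(resin = pal$resin, cell_wall = pal$cell_wall,
             cytoplasm = pal$cytoplasm, nucleus = pal$nucleus,
             nucleolus = pal$nucleolus, nuclear_body = pal$nuclear_body,
             pyrenoid = pal$pyrenoid, starch = pal$starch,
             thylakoid = pal$thylakoid, vacuole = pal$vacuole)
  prov <- list(kind = "cell", geometry = unclass(g), seed = seed,
               cell_center_nm = cc, cell_radius_nm = R,
               nucleus_center_nm = nc,
               nuclear_body_center_nm = nbc,
               nuclear_body_diameter_nm = g$nuclear_body_diameter_nm,
               pyrenoid_center_nm = pc,
               wall_thickness_nm = g$wall_thickness_nm,
               vacuole_centers_nm = vac_centers)
  new_cell_phantom(lab, pitch, L, mt, prov)
}

#' Geometry configuration for the axoneme phantom
#'
#' Canonical eukaryotic "9+2" flagellar cross section: a ring of outer
#' doublet microtubules with radial spokes, a central microtubule pair and
#' inner sheath, surrounded by the flagellar membrane/cell-wall ring and
#' resin.  Lengths in nm.
#'
#' @param grid_extent_nm extent (z, y, x).
#' @param voxel_pitch_nm pitch per axis.
#' @param n_doublets number of outer doublets (canonical 9).
#' @param doublet_ring_radius_nm radius of the doublet ring.
#' @param tubule_radius_nm radius of each microtubule circle.
#' @param doublet_separation_nm center separation of the two tubules of a
#'   doublet (must overlap: < 2 * tubule_radius).
#' @param spoke_width_nm,spoke_inner_nm,spoke_outer_nm radial spokes.
#' @param central_pair_offset_nm half-separation of the central pair.
#' @param sheath_radii_nm inner sheath ring (inner, outer).
#' @param membrane_radii_nm membrane/wall ring (inner, outer).
#' @return a list of class `axoneme_geometry`.
#' @export
axoneme_geometry <- function(grid_extent_nm = c(100, 600, 600),
                             voxel_pitch_nm = c(10, 2, 2),
                             n_doublets = 9,
                             doublet_ring_radius_nm = 80,
                             tubule_radius_nm = 12.5,
                             doublet_separation_nm = 21,
                             spoke_width_nm = 8,
                             spoke_inner_nm = 38,
                             spoke_outer_nm = 65,
                             central_pair_offset_nm = 14,
                             sheath_radii_nm = c(30, 36),
                             membrane_radii_nm = c(110, 130)) {
  g <- as.list(environment())
  if (g$n_doublets < 1) stop_domain("n_doublets must be >= 1")
  structure(g, class = "axoneme_geometry")
}

axoneme_labels <- c(resin = 0L, cell_wall = 1L, matrix = 2L, doublet = 3L,
                    radial_spoke = 4L, central_pair = 5L, inner_sheath = 6L)

#' Build an axoneme cross-section phantom
#'
#' @param geometry an [axoneme_geometry()].
#' @param seed integer seed (kept for provenance; the build is
#'   deterministic).
#' @return a `cell_phantom` whose in-plane geometry is the axoneme cross
#'   section, extruded along z.  Doublet 1 lies at azimuth 0 (+y axis down).
#' @export
build_axoneme_phantom <- function(geometry = axoneme_geometry(), seed = 1L) {
  g <- geometry
  stopifnot(inherits(g, "axoneme_geometry"))
  if (g$doublet_separation_nm >= 2 * g$tubule_radius_nm)
    stop_domain("geometry overlap: doublet tubules must overlap ",
                "(separation < 2 * tubule radius)")
  gap <- 2 * g$doublet_ring_radius_nm * sin(pi / g$n_doublets)
  if (g$n_doublets > 1 &&
      gap <= g$doublet_separation_nm + 2 * g$tubule_radius_nm)
    stop_domain("geometry overlap: adjacent doublets touch")
  if (g$spoke_outer_nm >= g$doublet_ring_radius_nm - g$tubule_radius_nm)
    stop_domain("geometry overlap: spokes reach into doublets")

  pitch <- g$voxel_pitch_nm
  dims <- as.integer(round(g$grid_extent_nm / pitch))
  cy <- g$grid_extent_nm[2] / 2
  cx <- g$grid_extent_nm[3] / 2
  yc <- (seq_len(dims[2]) - 0.5) * pitch[2] - cy
  xc <- (seq_len(dims[3]) - 0.5) * pitch[3] - cx
  Y <- matrix(yc, dims[2], dims[3])
  X <- matrix(xc, dims[2], dims[3], byrow = TRUE)
  r <- sqrt(Y^2 + X^2)

  L <- axoneme_labels
  sl <- matrix(L[["resin"]], dims[2], dims[3])
  sl[r <= g$membrane_radii_nm[2]] <- L[["cell_wall"]]
  sl[r < g$membrane_radii_nm[1]] <- L[["matrix"]]
  sl[r >= g$sheath_radii_nm[1] & r <= g$sheath_radii_nm[2]] <-
    L[["inner_sheath"]]

  ## central pair along x
  for (s in c(-1, 1)) {
    d2 <- Y^2 + (X - s * g$central_pair_offset_nm)^2
    sl[d2 <= g$tubule_radius_nm^2] <- L[["central_pair"]]
  }

  th <- 2 * pi * (seq_len(g$n_doublets) - 1) / g$n_doublets
  for (k in seq_len(g$n_doublets)) {
    ## radial spoke (angle th[k], azimuth 0 = +y)
    ur <- c(cos(th[k]), sin(th[k]))          # radial unit (y, x)
    proj <- Y * ur[1] + X * ur[2]
    perp <- -Y * ur[2] + X * ur[1]
    spoke <- proj >= g$spoke_inner_nm & proj <= g$spoke_outer_nm &
      abs(perp) <= g$spoke_width_nm / 2
    sl[spoke & sl == L[["matrix"]]] <- L[["radial_spoke"]]
    ## doublet: two overlapping tubules offset tangentially
    dc <- g$doublet_ring_radius_nm * ur
    for (s in c(-1, 1)) {
      ctr <- dc + s * (g$doublet_separation_nm / 2) * c(-ur[2], ur[1])
      d2 <- (Y - ctr[1])^2 + (X - ctr[2])^2
      sl[d2 <= g$tubule_radius_nm^2] <- L[["doublet"]]
    }
  }

  lab <- array(rep(sl, each = dims[1]), dim = dims)
  pal <- material_palette()
  mt <- list(resin = pal$resin, cell_wall = pal$cell_wall,
             matrix = pal$matrix, doublet = pal$protein,
             radial_spoke = pal$protein, central_pair = pal$protein,
             inner_sheath = pal$protein)
  prov <- list(kind = "axoneme", geometry = unclass(g), seed = seed,
               center_nm = c(g$grid_extent_nm[1] / 2, cy, cx),
               doublet_ring_radius_nm = g$doublet_ring_radius_nm,
               n_doublets = g$n_doublets)
  new_cell_phantom(lab, pitch, L, mt, prov)
}

#' Slice a phantom into serial cross sections
#'
#' Partitions the phantom's z-range into consecutive slabs of the given
#' thickness and projects each slab to a 2-D label map by per-column
#' majority vote (ties broken toward the lowest label index).  Optional
#' misalignment jitter emulates microtome ribbon placement: per-section
#' translations (quantized to the in-plane voxel grid and recorded exactly)
#' and small rotations.  Section 1 is never jittered.
#'
#' @param phantom a `cell_phantom`.
#' @param thickness_nm section thickness (default 100); must be a multiple
#'   of the z voxel pitch.
#' @param n_sections number of consecutive sections.
#' @param misalign list with `shift_sd_px` (Gaussian sd of the per-section
#'   translation, in in-plane pixels) and `rot_sd_deg` (sd of the rotation,
#'   degrees).  Zero (default) gives exactly zero offsets.
#' @param seed integer seed for the jitter draws.
#' @return a `section_stack`: `sections` (list of label matrices),
#'   `true_offsets` (n x 3 matrix: dx_px, dy_px, rot_rad),
#'   `thickness_nm`, `pitch_nm`, `label_names`, `material_table`,
#'   `z_extent_nm`, `slab_bounds_nm`, `provenance`.
#' @export
section_phantom <- function(phantom, thickness_nm = 100, n_sections = 10,
                            misalign = list(shift_sd_px = 0,
                                            rot_sd_deg = 0),
                            seed = 1L) {
  stopifnot(inherits(phantom, "cell_phantom"))
  pz <- phantom$voxel_pitch_nm[1]
  if (abs(thickness_nm / pz - round(thickness_nm / pz)) > 1e-9)
    stop_domain("thickness must be a multiple of the z voxel pitch")
  nz <- dim(phantom$label_grid)[1]
  vox_per <- as.integer(round(thickness_nm / pz))
  if (n_sections * vox_per > nz)
    stop_domain("range error: sections exceed phantom z-extent")

  shift_sd <- misalign$shift_sd_px %||% 0
  rot_sd <- misalign$rot_sd_deg %||% 0
  off <- matrix(0, n_sections, 3,
                dimnames = list(NULL, c("dx_px", "dy_px", "rot_rad")))
  if (n_sections > 1 && (shift_sd > 0 || rot_sd > 0)) {
    off[-1, ] <- with_seed(seed, cbind(
      round(stats::rnorm(n_sections - 1, 0, shift_sd)),
      round(stats::rnorm(n_sections - 1, 0, shift_sd)),
      stats::rnorm(n_sections - 1, 0, rot_sd) * pi / 180))
  }

  codes <- sort(unname(phantom$label_names))
  secs <- vector("list", n_sections)
  bounds <- matrix(0, n_sections, 2,
                   dimnames = list(NULL, c("z0_nm", "z1_nm")))
  for (s in seq_len(n_sections)) {
    zi <- ((s - 1) * vox_per + 1):(s * vox_per)
    bounds[s, ] <- c((s - 1) * thickness_nm, s * thickness_nm)
    slab <- phantom$label_grid[zi, , , drop = FALSE]
    best <- matrix(codes[1], dim(slab)[2], dim(slab)[3])
    bestc <- matrix(-1L, dim(slab)[2], dim(slab)[3])
    for (cd in codes) {
      cnt <- colSums(slab == cd, dims = 1)
      sel <- cnt > bestc
      best[sel] <- cd
      bestc[sel] <- cnt[sel]
    }
    secs[[s]] <- jitter_labels(best, off[s, 1], off[s, 2], off[s, 3],
                               fill = codes[1])
  }
  structure(
    list(sections = secs, true_offsets = off, thickness_nm = thickness_nm,
         pitch_nm = phantom$voxel_pitch_nm[2],
         label_names = phantom$label_names,
         material_table = phantom$material_table,
         z_extent_nm = n_sections * thickness_nm,
         slab_bounds_nm = bounds, seed = seed,
         provenance = c(phantom$provenance,
                        list(misalign = list(shift_sd_px = shift_sd,
                                             rot_sd_deg = rot_sd)))),
    class = "section_stack")
}

## shift content by (+dx, +dy) pixels and rotate by rot about the center;
## nearest-neighbor, out-of-frame filled with `fill`
jitter_labels <- function(m, dx, dy, rot, fill = 0L) {
  if (dx == 0 && dy == 0 && rot == 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  cyx <- c((ny + 1) / 2, (nx + 1) / 2)
  yy <- matrix(seq_len(ny), ny, nx) - cyx[1] - dy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cyx[2] - dx
  sy <- round(cos(rot) * yy + sin(rot) * xx + cyx[1])
  sx <- round(-sin(rot) * yy + cos(rot) * xx + cyx[2])
  ok <- sy >= 1 & sy <= ny & sx >= 1 & sx <= nx
  out <- matrix(fill, ny, nx)
  out[ok] <- m[cbind(sy[ok], sx[ok])]
  out
}

#' @export
print.section_stack <- function(x, ...) {
  cat("<section_stack>", length(x$sections), "sections of",
      x$thickness_nm, "nm (z extent", x$z_extent_nm, "nm),",
      nrow(x$sections[[1]]), "x", ncol(x$sections[[1]]), "px at",
      x$pitch_nm, "nm\n")
  invisible(x)
}

#' Extract one section as a standalone object
#'
#' @param stack a `section_stack`.
#' @param i section index.
#' @return a `phantom_section` suitable for [raster_scan()].
#' @export
get_section <- function(stack, i) {
  stopifnot(inherits(stack, "section_stack"),
            i >= 1, i <= length(stack$sections))
  structure(
    list(labels = stack$sections[[i]], pitch_nm = stack$pitch_nm,
         label_names = stack$label_names,
         material_table = stack$material_table,
         thickness_nm = stack$thickness_nm, section_index = i),
    class = "phantom_section")
}

#' Construct a section from an explicit label map
#'
#' Convenience constructor for synthetic test sections (half planes, steps,
#' uniform fields) that behave like phantom-derived sections.
#'
#' @param labels integer matrix (y, x) of label codes.
#' @param pitch_nm in-plane pixel pitch.
#' @param material_table named list mapping label names to
#'   [optical_material()] objects.
#' @param label_names named integer vector mapping label names to codes;
#'   defaults to codes 0..k-1 in `material_table` order.
#' @param thickness_nm nominal thickness.
#' @return a `phantom_section`.
#' @export
label_section <- function(labels, pitch_nm, material_table,
                          label_names = NULL, thickness_nm = 100) {
  if (is.null(label_names))
    label_names <- stats::setNames(seq_along(material_table) - 1L,
                                   names(material_table))
  if (!all(labels %in% label_names))
    stop_domain("labels contain codes missing from label_names")
  if (!all(names(label_names) %in% names(material_table)))
    stop_domain("every label needs a material_table entry")
  structure(
    list(labels = labels, pitch_nm = pitch_nm, label_names = label_names,
         material_table = material_table, thickness_nm = thickness_nm,
         section_index = NA_integer_),
    class = "phantom_section")
}
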