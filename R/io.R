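## Readers and writers binding the pipeline stages together.  All raster
## data go to multi-page TIFF plus a JSON metadata sidecar; spectra and
## profiles go to CSV plus JSON.  Matrices are stored normalized to [0, 1]
## (TIFF container convention) with the affine scale recorded in the
## sidecar, so every file round-trips through its reader.

material_to_list <- function(m) {
  list(name = m$name, epsilon_infinity = m$epsilon_infinity,
       oscillators = lapply(m$oscillators, function(o)
         list(center_wavenumber = o$center_wavenumber,
              strength = o$strength, damping = o$damping)),
       epsilon_const = if (is.null(m$epsilon_const)) NULL else
         c(Re(m$epsilon_const), Im(m$epsilon_const)))
}

material_from_list <- function(l) {
  optical_material(
    l$name, l$epsilon_infinity %||% 2,
    lapply(l$oscillators, function(o)
      lorentz_oscillator(o$center_wavenumber, o$strength, o$damping)),
    epsilon_const = if (is.null(l$epsilon_const)) NULL else
      complex(real = l$epsilon_const[1], imaginary = l$epsilon_const[2]))
}

write_json_meta <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

## normalized multi-page TIFF with affine scale; NA encoded as 0 with a
## mask page appended per data page when any NA is present
write_pages <- function(pages, path, bits = 32) {
  rng <- range(unlist(lapply(pages, function(p) range(p, na.rm = TRUE)),
                      use.names = FALSE), finite = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  if (rng[2] == rng[1]) rng[2] <- rng[1] + 1
  has_na <- any(vapply(pages, anyNA, logical(1)))
  norm <- lapply(pages, function(p) {
    q <- (p - rng[1]) / (rng[2] - rng[1])
    q[is.na(q)] <- 0
    q
  })
  if (has_na)
    norm <- c(norm, lapply(pages, function(p) (!is.na(p)) * 1))
  tiff::writeTIFF(norm, path, bits.per.sample = bits)
  list(offset = rng[1], scale = rng[2] - rng[1], n_pages = length(pages),
       has_mask = has_na)
}

read_pages <- function(path, enc) {
  pg <- tiff::readTIFF(path, all = TRUE)
  n <- enc$n_pages
  out <- lapply(pg[seq_len(n)], function(p)
    p * enc$scale + enc$offset)
  if (isTRUE(enc$has_mask))
    for (i in seq_len(n)) out[[i]][pg[[n + i]][, ] < 0.5] <- NA_real_
  out
}

#' Write a section stack to disk
#'
#' Emits `<name>.tif` (one 16-bit page per section, raw label codes) and
#' `<name>.json` (pitch, thickness, labels, material palette, true
#' offsets, seed, provenance summary).
#'
#' @param stack a `section_stack`.
#' @param dir output directory (created if missing).
#' @param name file basename (default "stack").
#' @return invisibly, the paths written.
#' @export
write_section_stack <- function(stack, dir, name = "stack") {
  stopifnot(inherits(stack, "section_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  jsn <- file.path(dir, paste0(name, ".json"))
  tiff::writeTIFF(lapply(stack$sections, function(s) s / 65535),
                  tif, bits.per.sample = 16)
  meta <- list(
    kind = "section_stack",
    thickness_nm = stack$thickness_nm, pitch_nm = stack$pitch_nm,
    z_extent_nm = stack$z_extent_nm, seed = stack$seed,
    label_names = as.list(stack$label_names),
    true_offsets = unname(apply(stack$true_offsets, 1, as.list)),
    slab_bounds_nm = unname(apply(stack$slab_bounds_nm, 1, as.list)),
    materials = lapply(stack$material_table, material_to_list))
  write_json_meta(meta, jsn)
  invisible(c(tif, jsn))
}

#' Read a section stack written by [write_section_stack()]
#'
#' @param dir directory containing the files.
#' @param name file basename.
#' @return a `section_stack`.
#' @export
read_section_stack <- function(dir, name = "stack") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")))
  if (!identical(meta$kind, "section_stack"))
    stop_domain("not a section_stack sidecar")
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  secs <- lapply(pages, function(p) {
    m <- as.integer(round(p * 65535))
    matrix(m, nrow(p), ncol(p))
  })
  off <- do.call(rbind, lapply(meta$true_offsets, function(r)
    unlist(r, use.names = FALSE)))
  colnames(off) <- c("dx_px", "dy_px", "rot_rad")
  bounds <- do.call(rbind, lapply(meta$slab_bounds_nm, function(r)
    unlist(r, use.names = FALSE)))
  colnames(bounds) <- c("z0_nm", "z1_nm")
  structure(
    list(sections = secs, true_offsets = off,
         thickness_nm = meta$thickness_nm, pitch_nm = meta$pitch_nm,
         label_names = unlist(meta$label_names),
         material_table = lapply(meta$materials, material_from_list),
         z_extent_nm = meta$z_extent_nm, slab_bounds_nm = bounds,
         seed = meta$seed, provenance = list(restored_from = dir)),
    class = "section_stack")
}

#' Write a scan image (topography/amplitude/phase) to disk
#'
#' One multi-channel float TIFF (pages: topography, amplitude, phase) and
#' a JSON sidecar with the pixel pitch, wavenumber, harmonic, channel
#' scaling and provenance.
#'
#' @param image a `scan_image`.
#' @param dir output directory.
#' @param name file basename.
#' @return invisibly, the paths written.
#' @export
write_scan_image <- function(image, dir, name = "scan") {
  stopifnot(inherits(image, "scan_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  jsn <- file.path(dir, paste0(name, ".json"))
  enc <- write_pages(list(image$topography_nm, image$amplitude,
                          image$phase_rad), tif)
  meta <- list(kind = "scan_image", wavenumber = image$wavenumber,
               harmonic = image$harmonic,
               pixel_pitch_nm = image$pixel_pitch_nm,
               channels = c("topography_nm", "amplitude", "phase_rad"),
               encoding = enc,
               provenance = image$provenance[c("section_index",
                                               "section_pitch_nm",
                                               "psf_fwhm_nm", "seed")])
  write_json_meta(meta, jsn)
  invisible(c(tif, jsn))
}

#' Read a scan image written by [write_scan_image()]
#' @param dir directory.
#' @param name file basename.
#' @return a `scan_image`.
#' @export
read_scan_image <- function(dir, name = "scan") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")))
  if (!identical(meta$kind, "scan_image"))
    stop_domain("not a scan_image sidecar")
  ch <- read_pages(file.path(dir, paste0(name, ".tif")), meta$encoding)
  structure(
    list(wavenumber = meta$wavenumber, harmonic = meta$harmonic,
         pixel_pitch_nm = meta$pixel_pitch_nm,
         topography_nm = ch[[1]], amplitude = ch[[2]], phase_rad = ch[[3]],
         provenance = meta$provenance),
    class = "scan_image")
}

#' Write a near-field or absorption spectrum to CSV + JSON
#'
#' Column order is part of the contract: `wavenumber_cm1, amplitude,
#' phase_rad` for near-field spectra; `wavenumber_cm1, absorption` for
#' absorption spectra.
#'
#' @param spectrum a `nearfield_spectrum` or `absorption_spectrum`.
#' @param dir output directory.
#' @param name file basename.
#' @return invisibly, the paths written.
#' @export
write_spectrum_csv <- function(spectrum, dir, name = "spectrum") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  jsn <- file.path(dir, paste0(name, ".json"))
  if (inherits(spectrum, "nearfield_spectrum")) {
    utils::write.csv(
      data.frame(wavenumber_cm1 = spectrum$wavenumber,
                 amplitude = spectrum$s_n, phase_rad = spectrum$phi_n),
      csv, row.names = FALSE)
    kind <- "nearfield_spectrum"
  } else if (inherits(spectrum, "absorption_spectrum")) {
    utils::write.csv(
      data.frame(wavenumber_cm1 = spectrum$wavenumber,
                 absorption = spectrum$A),
      csv, row.names = FALSE)
    kind <- "absorption_spectrum"
  } else stop_domain("unsupported spectrum class")
  g <- spectrum$grid
  write_json_meta(
    list(kind = kind, harmonic = spectrum$harmonic,
         is_reference = isTRUE(spectrum$is_reference),
         grid = list(resolution = g$resolution, limits = g$limits,
                     nyquist = g$nyquist, zero_fill = g$zero_fill)),
    jsn)
  invisible(c(csv, jsn))
}

#' Read a spectrum written by [write_spectrum_csv()]
#' @param dir directory.
#' @param name file basename.
#' @return a `nearfield_spectrum` or `absorption_spectrum`.
#' @export
read_spectrum_csv <- function(dir, name = "spectrum") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")))
  d <- utils::read.csv(file.path(dir, paste0(name, ".csv")))
  g <- spectral_grid(meta$grid$resolution, unlist(meta$grid$limits),
                     meta$grid$nyquist, meta$grid$zero_fill)
  if (identical(meta$kind, "nearfield_spectrum")) {
    z <- d$amplitude * exp(1i * d$phase_rad)
    structure(list(wavenumber = d$wavenumber_cm1, s_n = d$amplitude,
                   phi_n = d$phase_rad, z = z, harmonic = meta$harmonic,
                   grid = g, is_reference = isTRUE(meta$is_reference)),
              class = "nearfield_spectrum")
  } else if (identical(meta$kind, "absorption_spectrum")) {
    structure(list(wavenumber = d$wavenumber_cm1, A = d$absorption,
                   harmonic = meta$harmonic, grid = g),
              class = "absorption_spectrum")
  } else stop_domain("unknown spectrum kind: ", meta$kind)
}

#' Write a voxel volume to disk
#'
#' Multi-page float TIFF (one page per z-slice, NA-masked) plus JSON
#' metadata with voxel dimensions, per-slice transforms, and the voxel
#' volume in liters.
#'
#' @param volume a `voxel_volume`.
#' @param dir output directory.
#' @param name file basename.
#' @return invisibly, the paths written.
#' @export
write_volume <- function(volume, dir, name = "volume") {
  stopifnot(inherits(volume, "voxel_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  jsn <- file.path(dir, paste0(name, ".json"))
  nz <- dim(volume$grid)[1]
  enc <- write_pages(lapply(seq_len(nz), function(i)
    volume$grid[i, , ]), tif)
  write_json_meta(
    list(kind = "voxel_volume", voxel_nm = as.list(volume$voxel_nm),
         z_extent_nm = volume$z_extent_nm,
         voxel_volume_liters = voxel_volume_liters(volume$voxel_nm),
         encoding = enc,
         transforms = lapply(volume$transforms, function(t)
           list(dx_px = t$dx_px, dy_px = t$dy_px, rot_rad = t$rot_rad,
                ok = t$ok))),
    jsn)
  invisible(c(tif, jsn))
}

#' Read a voxel volume written by [write_volume()]
#' @param dir directory.
#' @param name file basename.
#' @return a `voxel_volume`.
#' @export
read_volume <- function(dir, name = "volume") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")))
  if (!identical(meta$kind, "voxel_volume"))
    stop_domain("not a voxel_volume sidecar")
  pages <- read_pages(file.path(dir, paste0(name, ".tif")), meta$encoding)
  grid <- array(NA_real_, dim = c(length(pages), nrow(pages[[1]]),
                                  ncol(pages[[1]])))
  for (i in seq_along(pages)) grid[i, , ] <- pages[[i]]
  structure(
    list(grid = grid, voxel_nm = unlist(meta$voxel_nm),
         z_extent_nm = meta$z_extent_nm,
         transforms = lapply(meta$transforms, function(t)
           rigid_transform(t$dx_px, t$dy_px, t$rot_rad, isTRUE(t$ok)))),
    class = "voxel_volume")
}

#' Write a line profile to CSV
#' @param profile data.frame from [line_profile()].
#' @param path output CSV path (`distance_nm,value`).
#' @return invisibly, the path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile[, c("distance_nm", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Content manifest of an output directory
#'
#' @param dir directory to index.
#' @return data.frame with `file` (relative path) and `md5`, sorted by
#'   file name; byte-identical reruns yield identical manifests.
#' @export
output_manifest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(dir, files))),
             row.names = NULL)
}
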