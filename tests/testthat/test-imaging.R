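half_plane <- function(pitch_nm = 5, size_px = 240,
                       materials = c("resin", "protein")) {
  pal <- fixture_palette()
  lab <- matrix(0L, size_px, size_px)
  lab[, (size_px / 2 + 1):size_px] <- 1L
  label_section(lab, pitch_nm,
                stats::setNames(pal[materials], materials))
}

cell_scan <- function(wavenumber) {
  memo(paste0("cell_scan_", wavenumber), function() {
    prov <- fixture_cell_phantom()$provenance
    si <- ceiling(prov$nuclear_body_center_nm[1] / 100)
    raster_scan(get_section(fixture_cell_stack(), si), wavenumber,
                fixture_tip(), 2, pixel_pitch_nm = 20)
  })
}

test_that("a uniform section yields spatially constant co-registered maps", {
  pal <- fixture_palette()
  sec <- label_section(matrix(0L, 60, 60), 10, list(resin = pal$resin))
  img <- raster_scan(sec, 1655, pixel_pitch_nm = 20)
  expect_equal(dim(img$amplitude), dim(img$phase_rad))
  expect_equal(dim(img$amplitude), dim(img$topography_nm))
  expect_lt(diff(range(img$amplitude)) / mean(img$amplitude), 1e-12)
  expect_lt(diff(range(img$phase_rad)), 1e-12)
})

test_that("noiseless scans are bitwise deterministic", {
  sec <- half_plane()
  a <- raster_scan(sec, 1655, pixel_pitch_nm = 20)
  b <- raster_scan(sec, 1655, pixel_pitch_nm = 20)
  expect_identical(a, b)
})

test_that("phase contrast inverts between the resin and amide bands", {
  stk <- fixture_cell_stack()
  prov <- fixture_cell_phantom()$provenance
  si <- ceiling(prov$nuclear_body_center_nm[1] / 100)
  lab <- get_section(stk, si)$labels
  step <- 2  # 20 nm pixels over the 10 nm section grid
  ly <- round((seq_len(nrow(cell_scan(1738)$phase_rad)) - 0.5) * step + 0.5)
  lab20 <- lab[ly, ly]
  resin <- lab20 == stk$label_names[["resin"]]
  prot <- lab20 %in% stk$label_names[c("nucleus", "nucleolus",
                                       "nuclear_body", "pyrenoid")]
  d1738 <- mean(cell_scan(1738)$phase_rad[resin]) -
    mean(cell_scan(1738)$phase_rad[prot])
  d1655 <- mean(cell_scan(1655)$phase_rad[resin]) -
    mean(cell_scan(1655)$phase_rad[prot])
  expect_gt(d1738, 0)
  expect_lt(d1655, 0)
})

test_that("phase edge width grows monotonically with apex radius", {
  sec <- half_plane()
  widths <- vapply(c(10, 20, 40), function(a) {
    img <- raster_scan(sec, 1655, tip_model(apex_radius_nm = a),
                       pixel_pitch_nm = 20)
    mid <- nrow(img$phase_rad) / 2
    edge_width_10_90(line_profile(img, "phase", c(5, mid), c(55, mid)))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_lte(widths[1], 20)  # default tip resolves ~20 nm
})

test_that("line profiles interpolate correctly on constructed images", {
  pal <- fixture_palette()
  sec <- label_section(matrix(0L, 40, 40), 20, list(resin = pal$resin))
  img <- raster_scan(sec, 1655, pixel_pitch_nm = 20)
  ## constant image -> constant profile
  pr <- line_profile(img, "amplitude", c(2, 20), c(38, 20))
  expect_lt(diff(range(pr$value)), 1e-9 * mean(pr$value))
  ## one-pixel step, noiseless synthetic channel: mid-crossing at boundary
  img$phase_rad <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  prs <- line_profile(img, "phase", c(15, 20), c(26, 20), step_px = 0.05)
  mid <- prs$distance_nm[which.min(abs(prs$value - 0.5))]
  ## boundary between pixel 20 and 21 sits 5.5 px from x = 15
  expect_equal(mid, 5.5 * 20, tolerance = 0.02)
  expect_error(line_profile(img, "phase", c(0, 5), c(10, 5)), "range")
})

test_that("edge width matches the analytic erf and ideal-step limits", {
  x <- seq(-100, 100, 1)
  sigma <- 8
  erf_edge <- data.frame(distance_nm = x + 100,
                         value = pnorm(x / sigma))
  expect_equal(edge_width_10_90(erf_edge), 2 * qnorm(0.9) * sigma,
               tolerance = 0.02)
  step <- data.frame(distance_nm = x + 100, value = as.numeric(x > 0))
  expect_lte(edge_width_10_90(step), 2)
  ramp <- data.frame(distance_nm = seq(0, 100, 1),
                     value = sin(seq(0, 6 * pi, length.out = 101)))
  expect_error(edge_width_10_90(ramp), "monotone")
})

test_that("feature FWHM matches triangle and Gaussian closed forms", {
  x <- seq(0, 400, 1)
  tri <- data.frame(distance_nm = x,
                    value = pmax(0, 1 - abs(x - 200) / 50))
  expect_equal(feature_fwhm(tri), 50, tolerance = 0.02)
  gauss <- data.frame(distance_nm = x,
                      value = exp(-(x - 200)^2 / (2 * 30^2)))
  expect_equal(feature_fwhm(gauss), 2.3548 * 30, tolerance = 0.01)
  ## inverted features are measured the same way
  dip <- data.frame(distance_nm = x, value = 1 - tri$value)
  expect_equal(feature_fwhm(dip), 50, tolerance = 0.02)
  flat <- data.frame(distance_nm = x, value = rep(1, length(x)))
  expect_error(feature_fwhm(flat), "extremum")
})

test_that("nuclear body and cell wall sizes are recovered from phase images", {
  prov <- fixture_cell_phantom()$provenance
  img <- cell_scan(1655)
  nb <- prov$nuclear_body_center_nm
  off <- nb[2:3] - prov$nucleus_center_nm[2:3]
  up <- c(-off[2], off[1]) / sqrt(sum(off^2))  # stay inside the nucleus
  p0 <- c(nb[3] - 260 * up[2], nb[2] - 260 * up[1]) / 20
  p1 <- c(nb[3] + 260 * up[2], nb[2] + 260 * up[1]) / 20
  fw <- feature_fwhm(line_profile(img, "phase", p0, p1))
  expect_equal(fw, 200, tolerance = 20 / 200)  # one pixel pitch
  cc <- prov$cell_center_nm
  u <- c(1, -1) / sqrt(2)  # radial direction clear of organelles
  q0 <- (cc[c(3, 2)] + u * (prov$cell_radius_nm - 300)) / 20
  q1 <- (cc[c(3, 2)] + u * (prov$cell_radius_nm + 300)) / 20
  fw_wall <- feature_fwhm(line_profile(img, "phase", q0, q1))
  expect_equal(fw_wall, 80, tolerance = 20 / 80)
})

test_that("azimuthal peak counting matches constructed cosine rings", {
  pal <- fixture_palette()
  sec <- label_section(matrix(0L, 101, 101), 20, list(resin = pal$resin))
  img <- raster_scan(sec, 1655, pixel_pitch_nm = 20)
  yy <- matrix(seq_len(101), 101, 101)
  xx <- t(yy)
  theta <- atan2(yy - 51, xx - 51)
  for (k in c(3, 9, 12)) {
    img$phase_rad <- cos(k * theta)
    expect_equal(count_azimuthal_peaks(img, "phase", c(51, 51), 30, 4,
                                       period_hint = k), k)
    expect_equal(count_azimuthal_peaks(img, "phase", c(51, 51), 30, 4), k)
  }
  img$phase_rad <- matrix(0.5, 101, 101)
  expect_equal(count_azimuthal_peaks(img, "phase", c(51, 51), 30, 4), 0L)
  expect_error(count_azimuthal_peaks(img, "phase", c(51, 51), 60, 4),
               "range")
})

test_that("axoneme amplitude image shows one peak per doublet", {
  ax <- build_axoneme_phantom()
  stk <- section_phantom(ax, 100, 1)
  img <- raster_scan(get_section(stk, 1), 1655, fixture_tip(), 2,
                     pixel_pitch_nm = 4)
  ctr <- c(ncol(img$amplitude), nrow(img$amplitude)) / 2 + 0.5
  r <- ax$provenance$doublet_ring_radius_nm / 4
  expect_equal(count_azimuthal_peaks(img, "amplitude", ctr, r, 3,
                                     period_hint = 9), 9L)
})

test_that("channel noise is seeded and applied per channel", {
  sec <- half_plane(pitch_nm = 10, size_px = 60)
  a <- raster_scan(sec, 1655, pixel_pitch_nm = 20,
                   noise_sd = c(amplitude = 0.01, phase = 0.02,
                                topography = 0.5), seed = 3L)
  b <- raster_scan(sec, 1655, pixel_pitch_nm = 20,
                   noise_sd = c(amplitude = 0.01, phase = 0.02,
                                topography = 0.5), seed = 3L)
  clean <- raster_scan(sec, 1655, pixel_pitch_nm = 20)
  expect_identical(a, b)
  expect_gt(sd(a$phase_rad - clean$phase_rad), 0.01)
  expect_gt(sd(a$topography_nm - clean$topography_nm), 0.2)
})
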