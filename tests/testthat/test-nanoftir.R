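make_line_ifg <- function(bins, amps = rep(1, length(bins)),
                          grid = spectral_grid()) {
  ## interferogram of synthetic spectral lines at native-bin wavenumbers
  N <- grid$n_samples
  j <- 0:(N - 1)
  samples <- 0
  for (i in seq_along(bins))
    samples <- samples +
      amps[i] * cos(2 * pi * (bins[i] / grid$resolution) * j / N)
  structure(list(opd_cm = j * grid$delta_x_cm, samples = samples,
                 co_additions = 1L, harmonic = 2L, grid = grid,
                 seed = 0L),
            class = "interferogram")
}

test_that("grid resolution equals 1 / (2 * max mirror OPD)", {
  g <- spectral_grid()
  expect_equal(g$resolution, 16)
  expect_equal(g$resolution, 1 / (2 * g$mirror_max_cm))
  ifg <- synthesize_interferogram(fixture_palette()$resin, grid = g)
  opd_max <- max(ifg$opd_cm) + g$delta_x_cm  # axis spans [0, mirror_max)
  expect_equal(1 / (2 * opd_max), g$resolution)
})

test_that("a delta interferogram gives a flat amplitude, zero phase spectrum", {
  g <- spectral_grid()
  ifg <- make_line_ifg(numeric(0))
  ifg$samples <- c(1, numeric(g$n_samples - 1))
  sp <- spectrum_from_interferogram(ifg)
  expect_lt(diff(range(sp$s_n)) / mean(sp$s_n), 1e-9)
  expect_lt(max(abs(sp$phi_n)), 1e-9)
})

test_that("two synthetic lines 16 cm^-1 apart are resolved at the default grid", {
  sp <- spectrum_from_interferogram(make_line_ifg(c(1600, 1616)))
  sub <- sp$wavenumber >= 1520 & sp$wavenumber <= 1700
  pk <- find_peaks(list(wavenumber = sp$wavenumber[sub], A = sp$s_n[sub],
                        grid = sp$grid),
                   min_height = 0.5 * max(sp$s_n[sub]))
  expect_equal(sort(pk$wavenumber), c(1600, 1616))
})

test_that("halving the OPD halves the two-line resolving power", {
  ## 32 cm^-1 grid (half the mirror travel) must merge lines 16 apart
  ## but still resolve 32 apart
  g32 <- spectral_grid(resolution = 32)
  sp <- spectrum_from_interferogram(make_line_ifg(c(1600, 1616), grid = g32))
  sub <- sp$wavenumber >= 1500 & sp$wavenumber <= 1720
  pk <- find_peaks(list(wavenumber = sp$wavenumber[sub], A = sp$s_n[sub],
                        grid = g32),
                   min_height = 0.5 * max(sp$s_n[sub]))
  expect_equal(nrow(pk), 1L)
  sp2 <- spectrum_from_interferogram(make_line_ifg(c(1600, 1632),
                                                   grid = g32))
  sub2 <- sp2$wavenumber >= 1500 & sp2$wavenumber <= 1720
  pk2 <- find_peaks(list(wavenumber = sp2$wavenumber[sub2],
                         A = sp2$s_n[sub2], grid = g32),
                    min_height = 0.5 * max(sp2$s_n[sub2]))
  expect_equal(nrow(pk2), 2L)
})

test_that("an off-bin line is located within one resolution element", {
  g <- spectral_grid()
  N <- g$n_samples
  j <- 0:(N - 1)
  ifg <- make_line_ifg(numeric(0))
  ifg$samples <- cos(2 * pi * (1655 / g$resolution) * j / N)
  sp <- spectrum_from_interferogram(ifg)
  expect_lte(abs(sp$wavenumber[which.max(sp$s_n)] - 1655), g$resolution)
})

test_that("noiseless synthesis round-trips through the FFT retrieval", {
  g <- spectral_grid()
  tip <- fixture_tip()
  pal <- fixture_palette()
  env <- source_envelope()
  for (m in c("resin", "protein")) {
    sp <- spectrum_from_interferogram(
      synthesize_interferogram(pal[[m]], tip, 2, g, env),
      apodization = "none")
    nat <- abs(sp$wavenumber %% g$resolution) < 1e-9
    truth <- nanosnom:::material_response(pal[[m]], sp$wavenumber[nat],
                                          tip, 2) * env(sp$wavenumber[nat])
    expect_lt(max(Mod(sp$z[nat] - truth) / Mod(truth)), 1e-3)
  }
})

test_that("co-added noise falls as one over root N", {
  g <- spectral_grid()
  pal <- fixture_palette()
  clean <- synthesize_interferogram(pal$resin, grid = g)$samples
  ratio <- vapply(1:20, function(r) {
    n1 <- synthesize_interferogram(pal$resin, grid = g, noise_sd = 0.05,
                                   co_additions = 1, seed = 100 + r)
    n50 <- synthesize_interferogram(pal$resin, grid = g, noise_sd = 0.05,
                                    co_additions = 50, seed = 200 + r)
    sd(n1$samples - clean) / sd(n50$samples - clean)
  }, numeric(1))
  expect_equal(mean(ratio), sqrt(50), tolerance = 0.2)
})

test_that("absorption of a spectrum against itself is exactly zero", {
  for (m in c("resin", "protein", "starch")) {
    sp <- spectrum_from_interferogram(
      synthesize_interferogram(fixture_palette()[[m]]))
    ref <- sp
    ref$is_reference <- TRUE
    A <- near_field_absorption(sp, ref)
    expect_equal(A$A, rep(0, length(A$A)))
  }
})

test_that("a quadrature bin with equal amplitudes gives absorption one", {
  g <- spectral_grid()
  mk <- function(phi) structure(
    list(wavenumber = c(1500, 1600), s_n = c(1, 1), phi_n = c(0, phi),
         z = exp(1i * c(0, phi)), harmonic = 2L, grid = g,
         is_reference = FALSE),
    class = "nearfield_spectrum")
  ref <- mk(0)
  ref$is_reference <- TRUE
  A <- near_field_absorption(mk(pi / 2), ref)
  expect_equal(A$A, c(0, 1))
})

test_that("absorption referencing validates its inputs", {
  sp <- spectrum_from_interferogram(
    synthesize_interferogram(fixture_palette()$resin))
  expect_error(near_field_absorption(sp, sp), "is_reference")
  ref <- fixture_gold_spectrum()
  bad <- sp
  bad$harmonic <- 3L
  expect_error(near_field_absorption(bad, ref), "harmonics")
  zero <- ref
  zero$s_n[5] <- 0
  expect_error(near_field_absorption(sp, zero), "bins 5")
})

test_that("resin absorption peaks at the carbonyl band through the full chain", {
  A <- fixture_absorption("resin")
  pk <- find_peaks(A)
  expect_lte(abs(pk$wavenumber[1] - 1738), A$grid$resolution)
})

test_that("protein absorption shows amide I over amide II at their positions", {
  A <- fixture_absorption("protein")
  pk <- find_peaks(A, min_height = 0.3 * max(A$A), min_separation = 48)
  expect_lte(abs(pk$wavenumber[1] - 1655), A$grid$resolution)
  expect_lte(abs(pk$wavenumber[2] - 1540), A$grid$resolution)
  expect_gt(pk$height[1], pk$height[2])
})

test_that("peak absorption scales linearly in the weak-contrast limit", {
  pal <- fixture_palette()
  half <- optical_material("protein_half", pal$protein$epsilon_infinity,
    lapply(pal$protein$oscillators, function(o)
      lorentz_oscillator(o$center_wavenumber, o$strength / 2, o$damping)))
  A1 <- fixture_absorption("protein")
  sp <- spectrum_from_interferogram(synthesize_interferogram(half))
  Ah <- near_field_absorption(sp, fixture_gold_spectrum())
  expect_equal(max(Ah$A) / max(A1$A), 0.5, tolerance = 0.15)
})

test_that("find_peaks handles flat input, ordering and separation merging", {
  g <- spectral_grid()
  flat <- list(wavenumber = seq(1000, 1800, 4), A = numeric(201), grid = g)
  expect_equal(nrow(find_peaks(flat)), 0L)
  nu <- seq(1000, 1800, 4)
  for (sep in c(24, 48, 96)) {
    two <- exp(-(nu - 1400)^2 / 50) + exp(-(nu - 1400 - sep)^2 / 50)
    n_found <- nrow(find_peaks(list(wavenumber = nu, A = two, grid = g),
                               min_height = 0.5, min_separation = 48))
    expect_equal(n_found, if (sep >= 48) 2L else 1L)
  }
  ## descending height, tie broken toward lower wavenumber
  v <- numeric(201)
  v[c(26, 101, 176)] <- c(0.5, 1, 1)
  pk <- find_peaks(list(wavenumber = nu, A = v, grid = g))
  expect_equal(pk$wavenumber, c(nu[101], nu[176], nu[26]))
})
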