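## Shared fixtures, memoized so expensive phantoms build once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixture_env)) assign(key, build(), .fixture_env)
  get(key, .fixture_env)
}

fixture_palette <- function() memo("palette", material_palette)

fixture_tip <- function() tip_model()

## small fast cell geometry for determinism/structure tests
small_cell_geometry <- function() {
  cell_geometry(grid_extent_nm = c(700, 1600, 1600),
                cell_diameter_nm = 1200, nucleus_radius_nm = 220,
                nucleus_offset_nm = c(0, -180, -180),
                nucleolus_radius_nm = 90,
                nucleolus_offset_nm = c(0, 60, 60),
                nuclear_body_offset_nm = c(0, -90, -60),
                pyrenoid_radius_nm = 180,
                pyrenoid_offset_nm = c(0, 200, 200),
                starch_thickness_nm = 40,
                thylakoid_center_nm = c(0, 250, -280),
                thylakoid_half_extent_nm = c(150, 180, 140),
                n_vacuoles = 2, vacuole_radius_nm = 90)
}

fixture_small_phantom <- function()
  memo("small_phantom", function() build_cell_phantom(small_cell_geometry(),
                                                      seed = 7L))

fixture_cell_phantom <- function()
  memo("cell_phantom", function() build_cell_phantom(seed = 42L))

fixture_cell_stack <- function()
  memo("cell_stack", function() section_phantom(fixture_cell_phantom(),
                                                100, 10))

fixture_gold_spectrum <- function()
  memo("gold_spectrum", function() gold_spectrum(tip_model(), 2L,
                                                 spectral_grid()))

fixture_absorption <- function(material_name) {
  memo(paste0("abs_", material_name), function() {
    sp <- spectrum_from_interferogram(
      synthesize_interferogram(fixture_palette()[[material_name]],
                               tip_model(), 2L, spectral_grid()))
    near_field_absorption(sp, fixture_gold_spectrum())
  })
}

## independent 4-connected component counter (breadth-first flood fill)
count_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  nc <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && !seen[i, j]) {
      nc <- nc + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          y <- p[1] + d[1]; x <- p[2] + d[2]
          if (y >= 1 && y <= nrow(mask) && x >= 1 && x <= ncol(mask) &&
              mask[y, x] && !seen[y, x]) {
            seen[y, x] <- TRUE
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  nc
}

## smooth random test image for registration tests
smooth_random_image <- function(n = 96, seed = 1, sigma = 2) {
  set.seed(seed)
  nanosnom:::gaussian_blur(matrix(rnorm(n * n), n, n), sigma)
}
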