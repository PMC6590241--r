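# Fixtures are generated in code: small phantoms on a narrow m/z axis keep
# unit tests fast; acceptance checks use larger geometries.

# Two-region phantom spec on a short axis (600-1200 Th) with the two marker
# peptides and one shared analyte.
test_spec <- function(n_cols = 20, n_rows = 20, ...) {
  phantom_spec(
    n_cols = n_cols, n_rows = n_rows,
    analytes = data.frame(mz = c(944.6, 1105.6, 842.51),
                          intensity = c(100, 100, 40),
                          region = c("villi", "muscle", "all")),
    mz_range = c(600, 1200), ...)
}

# Flat synthetic spectrum with Gaussian peaks of fixed width planted at
# known centres; `heights` are apex heights above the baseline.
planted_spectrum <- function(centers, heights, axis = seq(600, 1000, 0.1),
                             baseline = 0, noise_sd = 0, sigma = 0.05,
                             seed = NULL) {
  y <- rep(baseline, length(axis))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(axis), 0, noise_sd)
  }
  for (k in seq_along(centers))
    y <- y + heights[k] * exp(-(axis - centers[k])^2 / (2 * sigma^2))
  mass_spectrum(axis, pmax(y, 0))
}

# A tiny continuous dataset built from explicit per-pixel peak heights:
# one row of pixels, peaks at fixed centres.
grid_dataset <- function(height_list, centers, axis = seq(600, 1000, 0.1),
                         sigma = 0.05) {
  spectra <- lapply(seq_along(height_list), function(i) {
    s <- planted_spectrum(centers, height_list[[i]], axis, sigma = sigma)
    mass_spectrum(s$mz, s$intensity, pixel = c(i - 1L, 0L))
  })
  msi_dataset(spectra, n_rows = 1L)
}

full_mask <- function(dataset) {
  tissue_mask(matrix(TRUE, dataset$n_rows, dataset$n_cols))
}
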