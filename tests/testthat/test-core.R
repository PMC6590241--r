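# MSI data model, TIC normalization, ion images, masks, imzML round trips.

test_that("mass_spectrum enforces its invariants", {
  expect_error(mass_spectrum(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(mass_spectrum(c(1, 3, 2), c(1, 1, 1)), "strictly increasing")
  expect_error(mass_spectrum(c(1, 2), c(1, -1)), "negative")
  s <- mass_spectrum(c(600, 601), c(0, 2), pixel = c(3, 4))
  expect_identical(s$pixel, c(3L, 4L))
})

test_that("TIC normalization divides by the total ion current", {
  s <- mass_spectrum(c(600, 601, 602), c(2, 2, 4))
  expect_equal(tic_normalize(s)$intensity, c(0.25, 0.25, 0.5))
  # idempotence
  n1 <- tic_normalize(s)
  expect_equal(tic_normalize(n1)$intensity, n1$intensity, tolerance = 1e-12)
  # property: sums to one and is scale invariant, over random spectra
  for (i in 1:20) {
    set.seed(i)
    x <- mass_spectrum(sort(runif(50, 600, 3200)), runif(50, 0.01, 10))
    nx <- tic_normalize(x)
    expect_equal(sum(nx$intensity), 1, tolerance = 1e-9)
    scaled <- mass_spectrum(x$mz, x$intensity * (1 + i))
    expect_equal(tic_normalize(scaled)$intensity, nx$intensity,
                 tolerance = 1e-12)
  }
  expect_error(tic_normalize(mass_spectrum(1:3, c(0, 0, 0))), "zero total")
})

test_that("msi_dataset validates grid placement and detects modes", {
  s <- function(px, mz = c(600, 601, 602)) mass_spectrum(mz, c(1, 2, 3), px)
  expect_error(msi_dataset(list(s(c(0, 0)), s(c(0, 0)))), "more than one")
  expect_error(msi_dataset(list(s(c(5, 0))), n_cols = 2, n_rows = 1),
               "outside")
  d <- msi_dataset(list(s(c(0, 0)), s(c(1, 0)), s(c(0, 1))))
  expect_identical(d$mode, "continuous")
  expect_identical(n_pixels(d), 3L)
  expect_equal(spectrum_at(d, 2)$intensity, c(1, 2, 3))
  # heterogeneous axes force processed mode
  p <- msi_dataset(list(s(c(0, 0)), s(c(1, 0), mz = c(700, 701, 702))))
  expect_identical(p$mode, "processed")
  expect_error(msi_dataset(list(s(c(0, 0)),
                                s(c(1, 0), mz = c(700, 701, 702))),
                           mode = "continuous"), "identical m/z axis")
})

test_that("ion image extraction reduces closed windows per pixel", {
  ds <- grid_dataset(list(c(10, 0), c(0, 20), c(5, 5)),
                     centers = c(620, 680))
  img <- extract_ion_image(ds, 620, 0.5, reducer = "sum")
  expect_true(all(img$valid))
  expect_gt(img$values[1, 1], img$values[1, 2])
  # sum == mean * k on a window of k points
  k <- sum(ds$mz_axis >= 620 - 0.5 & ds$mz_axis <= 620 + 0.5)
  m_img <- extract_ion_image(ds, 620, 0.5, reducer = "mean")
  expect_equal(img$values[1, ], m_img$values[1, ] * k, tolerance = 1e-12)
  # empty window (between grid points) warns and returns zeros
  expect_warning(z <- extract_ion_image(ds, 650.05, 0.0001), "no data points")
  expect_true(all(z$values[z$valid] == 0))
  # window outside the mass range errors
  expect_error(extract_ion_image(ds, 2000, 0.25), "does not intersect")
})

test_that("ion image extraction commutes with pixel reordering", {
  ds <- grid_dataset(list(c(10, 1), c(2, 20), c(5, 5), c(7, 0)),
                     centers = c(620, 680))
  spectra <- lapply(seq_len(n_pixels(ds)), function(i) spectrum_at(ds, i))
  ds_rev <- msi_dataset(rev(spectra), n_cols = ds$n_cols, n_rows = ds$n_rows)
  a <- extract_ion_image(ds, 680, 0.5)
  b <- extract_ion_image(ds_rev, 680, 0.5)
  expect_equal(a$values, b$values)
  expect_identical(a$valid, b$valid)
})

test_that("unmeasured pixels are flagged invalid, not zero", {
  s <- function(px) mass_spectrum(c(600, 601), c(1, 1), px)
  d <- msi_dataset(list(s(c(0, 0)), s(c(1, 1))), n_cols = 2, n_rows = 2)
  img <- extract_ion_image(d, 600.5, 1)
  expect_identical(img$valid, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_true(all(is.na(img$values[!img$valid])))
})

test_that("TIC-derived masks follow the quantile rule and its tie-break", {
  ds <- grid_dataset(list(c(1, 0), c(10, 0), c(100, 0), c(1000, 0)),
                     centers = c(620, 680))
  m0 <- mask_from_tic(ds, 0)
  expect_true(all(m0$grid))                     # threshold 0: all measured
  m5 <- mask_from_tic(ds, 0.5)
  expect_identical(sum(m5$grid), 2L)            # strictly above the median
  expect_error(mask_from_tic(ds, 1), "quantile_threshold")
  expect_error(mask_from_tic(ds, -0.1), "quantile_threshold")
  # uniform TIC with positive threshold: all-off mask with a warning
  du <- grid_dataset(list(c(5, 5), c(5, 5), c(5, 5)), centers = c(620, 680))
  expect_warning(mu <- mask_from_tic(du, 0.3), "empty")
  expect_false(any(mu$grid))
})

test_that("TIC mask recovers the phantom tissue footprint", {
  # footprint with ~19% off-tissue margin, below the 0.2 quantile threshold;
  # no delocalization so the geometric footprint is the truth being recovered
  ph <- generate_phantom(test_spec(n_cols = 40, n_rows = 40,
                                   margin_frac = 0.05, blur_sigma_px = 0,
                                   seed = 5))
  mask <- mask_from_tic(ph$dataset, 0.2)
  agreement <- mean(mask$grid == ph$truth$mask$grid)
  expect_gte(agreement, 0.95)
})

test_that("masks round-trip through PNG and run-length text", {
  set.seed(3)
  m <- tissue_mask(matrix(runif(35) > 0.4, 5, 7))
  p1 <- file.path(tempdir(), "m.png")
  p2 <- file.path(tempdir(), "m.rle")
  write_mask(m, p1); write_mask(m, p2)
  expect_identical(read_mask(p1)$grid, m$grid)
  expect_identical(read_mask(p2)$grid, m$grid)
  expect_error(read_mask(file.path(tempdir(), "nope.rle")), "not found")
})

test_that("imzML continuous round trip is exact with float64 intensities", {
  ph <- generate_phantom(test_spec(n_cols = 6, n_rows = 5, seed = 2))
  f <- file.path(tempdir(), "c.imzML")
  write_imzml(ph$dataset, f, intensity_dtype = "float64")
  rt <- read_imzml(f)
  expect_identical(rt$mode, "continuous")
  expect_identical(rt$mz_axis, ph$dataset$mz_axis)
  expect_identical(rt$intensities, ph$dataset$intensities)
  expect_identical(rt$coords, ph$dataset$coords)
  expect_equal(rt$pixel_size_um, ph$dataset$pixel_size_um)
})

test_that("default float32 intensities round-trip within float tolerance", {
  ph <- generate_phantom(test_spec(n_cols = 4, n_rows = 4, seed = 9))
  f <- file.path(tempdir(), "c32.imzML")
  write_imzml(ph$dataset, f)
  rt <- read_imzml(f)
  rel <- abs(rt$intensities - ph$dataset$intensities) /
    pmax(ph$dataset$intensities, 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("a 1-pixel file and processed-mode axes survive the round trip", {
  one <- msi_dataset(list(mass_spectrum(c(600, 700, 800), c(1, 2, 3),
                                        c(0, 0))))
  f1 <- file.path(tempdir(), "one.imzML")
  write_imzml(one, f1, intensity_dtype = "float64")
  r1 <- read_imzml(f1)
  expect_identical(r1$n_cols, 1L)
  expect_identical(r1$n_rows, 1L)
  expect_equal(spectrum_at(r1, 1)$intensity, c(1, 2, 3))

  proc <- msi_dataset(list(
    mass_spectrum(c(600, 601, 602), c(1, 2, 3), c(0, 0)),
    mass_spectrum(c(700.5, 702.25), c(4, 5), c(1, 0))))
  f2 <- file.path(tempdir(), "p.imzML")
  write_imzml(proc, f2, intensity_dtype = "float64")
  r2 <- read_imzml(f2)
  expect_identical(r2$mode, "processed")
  for (i in 1:2) {
    expect_identical(spectrum_at(r2, i)$mz, spectrum_at(proc, i)$mz)
    expect_identical(spectrum_at(r2, i)$intensity,
                     spectrum_at(proc, i)$intensity)
  }
})

test_that("imzML reader reports missing files and corrupt axes", {
  expect_error(read_imzml(file.path(tempdir(), "absent.imzML")), "not found")
  ds <- msi_dataset(list(mass_spectrum(c(600, 601, 602), c(1, 1, 1),
                                       c(0, 0))))
  f <- file.path(tempdir(), "corrupt.imzML")
  write_imzml(ds, f, intensity_dtype = "float64")
  # overwrite the stored m/z axis with a non-monotone one
  con <- file(sub("imzML$", "ibd", f), "r+b")
  seek(con, 16, rw = "write")
  writeBin(c(700, 650, 600), con, size = 8, endian = "little")
  close(con)
  expect_error(read_imzml(f), "non-monotone.*pixel \\(0,0\\)")
})

test_that("written imzML is readable by an independent parser", {
  ph <- generate_phantom(test_spec(n_cols = 8, n_rows = 6, seed = 6))
  f <- file.path(tempdir(), "xval.imzML")
  write_imzml(ph$dataset, f)
  script <- file.path(tempdir(), "readback.py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, it = p.getspectrum(0)",
    "print(len(p.coordinates), len(mz), round(float(sum(it)), 3))"),
    script)
  out <- system2("python", c(script, f), stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_identical(as.integer(parts[1]), n_pixels(ph$dataset))
  expect_identical(as.integer(parts[2]), length(ph$dataset$mz_axis))
  expect_equal(as.double(parts[3]), sum(ph$dataset$intensities[, 1]),
               tolerance = 1e-4)
})
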