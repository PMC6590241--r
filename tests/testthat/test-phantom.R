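# Phantom generator: determinism, geometry, blur, droplets, cohorts.

test_that("generation is bitwise reproducible from the seed", {
  spec <- test_spec(n_cols = 12, n_rows = 12, seed = 19)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth$analyte_maps, b$truth$analyte_maps)
  # a different seed changes the realization
  c_ <- generate_phantom(test_spec(n_cols = 12, n_rows = 12, seed = 20))
  expect_false(identical(a$dataset$intensities, c_$dataset$intensities))
})

test_that("a clean phantom's marker image is proportional to its region", {
  spec <- test_spec(baseline_sd = 0, jitter_sigma_ln = 0, blur_sigma_px = 0,
                    seed = 1)
  ph <- generate_phantom(spec)
  img <- extract_ion_image(ph$dataset, 944.6, 0.25)
  villi <- ph$truth$region_labels == 2L
  v <- img$values
  expect_true(all(v[villi] > 0))
  expect_equal(max(abs(v[!villi])), 0)
  expect_lt(diff(range(v[villi])) / max(v[villi]), 1e-9)  # constant inside
  # TIC is strictly positive on tissue even without noise
  tics <- pixel_tic(ph$dataset)
  on <- ph$truth$mask$grid[cbind(ph$dataset$coords[, 2] + 1,
                                 ph$dataset$coords[, 1] + 1)]
  expect_true(all(tics[on] > 0))
})

test_that("blurred boundaries follow the error-function profile", {
  spec <- test_spec(n_cols = 40, n_rows = 40, baseline_sd = 0,
                    jitter_sigma_ln = 0, blur_sigma_px = 2, seed = 1)
  truth <- phantom_truth(spec)
  map <- truth$analyte_maps[["944.6000"]]
  # horizontal profile through the grid centre crosses the villi edge
  prof <- map[20, ]
  prof <- prof / max(prof)
  # 10-90% rise distance of a Gaussian-blurred step is 2 * 1.2816 * sigma
  rise_expected <- 2 * qnorm(0.9) * 2
  left <- which(prof >= 0.1)[1]
  right <- which(prof >= 0.9)[1]
  expect_lt(abs((right - left) - rise_expected), 1)
  # erf oracle on the full left edge: locate the step position, then compare
  edge <- which(diff(truth$region_labels[20, ] == 2L) == 1)[1] + 0.5
  oracle <- pnorm((seq_len(40) - edge) / 2)
  # compare on the rising flank only (the opposite edge interferes far away)
  flank <- (edge - 6):(edge + 6)
  expect_lt(max(abs(prof[flank] - oracle[flank])), 0.05)
})

test_that("droplets homogenize analytes locally and only there", {
  spec <- test_spec(n_cols = 24, n_rows = 24, blur_sigma_px = 0, seed = 2)
  truth <- phantom_truth(spec)
  # disc in the off-tissue margin: all maps are zero there, nothing changes
  t_margin <- apply_droplet_artifact(truth, center = c(0, 0), radius_px = 1.5)
  expect_identical(t_margin$analyte_maps, truth$analyte_maps)
  # smear 0: the disc becomes piecewise-constant at the disc mean
  t0 <- apply_droplet_artifact(truth, center = c(12, 12), radius_px = 3,
                               smear_sigma = 0)
  map <- truth$analyte_maps[["944.6000"]]
  cols <- matrix(rep(0:23, each = 24), 24, 24)
  rows <- matrix(rep(0:23, times = 24), 24, 24)
  disc <- (cols - 12)^2 + (rows - 12)^2 <= 9
  expect_true(all(t0$analyte_maps[["944.6000"]][disc] == mean(map[disc])))
  expect_identical(t0$analyte_maps[["944.6000"]][!disc], map[!disc])
  expect_error(apply_droplet_artifact(truth, c(-50, -50), 2), "off the")
  expect_error(apply_droplet_artifact(truth, c(5, 5), 0), "radius")
})

test_that("a boundary-straddling droplet creates yellow pixels", {
  spec <- test_spec(n_cols = 40, n_rows = 40, seed = 3)
  truth <- phantom_truth(spec)
  # villi left edge: margin 4 + band 3, boundary between cols 6 and 7
  t_drop <- apply_droplet_artifact(truth, center = c(6.5, 20),
                                   radius_px = 4, smear_sigma = 1)
  ds_clean <- phantom_dataset(truth, spec$seed)
  ds_drop <- phantom_dataset(t_drop, spec$seed)
  r_clean <- spatial_resolution_score(ds_clean, truth$mask)
  r_drop <- spatial_resolution_score(ds_drop, t_drop$mask)
  expect_gt(r_drop$counts[["YELLOW"]], r_clean$counts[["YELLOW"]])
  expect_gt(r_drop$score_percent, r_clean$score_percent)
  # droplet pixels inside tissue are yellow in the corrupted image
  drop_zone <- analyte_overlap(t_drop, 944.6, 1105.6, threshold = 1) &
    truth$mask$grid
  frac_yellow <- mean(r_drop$labels[drop_zone] == 3L)
  expect_gt(frac_yellow, mean(r_clean$labels[drop_zone] == 3L))
})

test_that("cohort site effects scale the TIC and vanish after normalization", {
  spec <- test_spec(n_cols = 12, n_rows = 12, seed = 4)
  runs <- replicate_cohort(spec, 3, site_effects = c(1, 2, 1), seed = 4)
  tic_means <- vapply(runs, function(r) mean(pixel_tic(r$dataset)),
                      numeric(1))
  expect_equal(tic_means[2] / tic_means[1], 2, tolerance = 0.1)
  avg <- lapply(runs, function(r)
    average_spectrum(r$dataset, r$truth$mask, tic_norm = TRUE))
  # after TIC normalization the doubled run is statistically indistinguishable
  expect_equal(sum(avg[[2]]$intensity), sum(avg[[1]]$intensity),
               tolerance = 1e-9)
  expect_equal(mean(avg[[2]]$intensity) / mean(avg[[3]]$intensity), 1,
               tolerance = 0.05)
  expect_error(replicate_cohort(spec, 3, site_effects = c(1, 2)), "length")
})

test_that("replicate runs with equal site effects are exchangeable", {
  # paired mini-cohorts: a rank test between two same-condition runs should
  # reject at about the nominal rate
  rejections <- 0
  for (k in 1:20) {
    spec <- test_spec(n_cols = 10, n_rows = 10, seed = 100 + k)
    runs <- replicate_cohort(spec, 2, seed = 100 + k)
    counts <- lapply(runs, function(r) {
      sp <- sample_spectra(r$dataset, r$truth$mask, 15, seed = k)
      vapply(sp, function(s) nrow(pick_peaks(s, min_snr = 3)), integer(1))
    })
    p <- suppressWarnings(wilcox.test(counts[[1]], counts[[2]])$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})
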