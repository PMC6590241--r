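# Spectrum sampling, quality metrics, bootstrap CIs, intensity CV.

test_that("spectrum sampling is uniform, seeded and bounded", {
  ds <- grid_dataset(list(c(1, 1), c(2, 1), c(3, 1), c(4, 1)),
                     centers = c(620, 680))
  mask <- full_mask(ds)
  a <- sample_spectra(ds, mask, 2, seed = 11)
  b <- sample_spectra(ds, mask, 2, seed = 11)
  expect_identical(attr(a, "pixel_indices"), attr(b, "pixel_indices"))
  full <- sample_spectra(ds, mask, 4, seed = 99)
  expect_setequal(attr(full, "pixel_indices"), 1:4)
  expect_error(sample_spectra(ds, mask, 5, seed = 1), "5.*4")
  # uniformity over many single draws
  hits <- integer(4)
  for (i in 1:10000) {
    idx <- attr(sample_spectra(ds, mask, 1, seed = i), "pixel_indices")
    hits[idx] <- hits[idx] + 1L
  }
  expect_true(all(hits / 10000 >= 0.22 & hits / 10000 <= 0.28))
})

test_that("bootstrap median CI is seeded, degenerate-safe and shrinking", {
  expect_equal(unname(bootstrap_median_ci(c(5, 5, 5, 5), 500, seed = 1)),
               c(5, 5))
  a <- bootstrap_median_ci(rnorm(30), 1000, seed = 3)
  b <- bootstrap_median_ci(withr::with_seed(123, rnorm(30)), 1000, seed = 3)
  expect_identical(bootstrap_median_ci(1:30, 1000, seed = 5),
                   bootstrap_median_ci(1:30, 1000, seed = 5))
  expect_warning(bootstrap_median_ci(1:10, 50, seed = 1), "unstable")
  expect_error(bootstrap_median_ci(3, 1000), "at least 2")
  # CI width decreases with sample size for a continuous distribution
  x_small <- withr::with_seed(7, rnorm(50))
  x_big <- withr::with_seed(8, rnorm(1000))
  w_small <- diff(bootstrap_median_ci(x_small, 1000, seed = 2))
  w_big <- diff(bootstrap_median_ci(x_big, 1000, seed = 2))
  expect_lt(w_big, w_small)
})

test_that("quality metrics compute the four counts and their medians", {
  mk <- function(mzs, snrs) peak_list(mzs, rep(1, length(mzs)), snrs)
  # every spectrum: 7 peaks, snr 5, all below m/z 1500
  pls <- replicate(9, mk(seq(700, 1300, 100), rep(5, 7)), simplify = FALSE)
  rep_q <- quality_metrics(pls, seed = 1)
  expect_equal(rep_q$metrics$median, c(7, 7, 0, 0))
  expect_equal(rep_q$metrics$lo, rep_q$metrics$median)
  expect_equal(rep_q$metrics$hi, rep_q$metrics$median)
  # counts 1..5 give median 3; strict ">" on every cutoff
  pls2 <- lapply(1:5, function(k) mk(seq(1500, by = 250,
                                         length.out = k), rep(3, k)))
  rep2 <- quality_metrics(pls2, seed = 1)
  m <- rep2$metrics
  expect_equal(m$median[m$metric == "peaks_per_spectrum"], 3)
  expect_equal(m$median[m$metric == "peaks_snr_gt3"], 0)   # snr == 3 not counted
  # the m/z 1500 peak itself is not "over 1500"
  expect_equal(rep2$counts$peaks_mz_gt1500, c(0, 1, 2, 3, 4))
  expect_error(quality_metrics(list()), "empty")
})

test_that("counts are anti-monotone in their thresholds", {
  set.seed(21)
  pls <- replicate(20, {
    n <- sample(5:50, 1)
    peak_list(sort(runif(n, 600, 3200)), runif(n, 1, 10), runif(n, 0, 8))
  }, simplify = FALSE)
  r_lo <- quality_metrics(pls, snr_threshold = 2, mz_cutoffs = 1000, seed = 1)
  r_hi <- quality_metrics(pls, snr_threshold = 4, mz_cutoffs = 2500, seed = 1)
  expect_true(all(r_hi$counts[[2]] <= r_lo$counts[[2]]))
  expect_true(all(r_hi$counts[[3]] <= r_lo$counts[[3]]))
})

test_that("the reported median tracks a known Poisson count cohort", {
  set.seed(31)
  counts <- rpois(100, 40)
  pls <- lapply(counts, function(k) {
    if (k == 0) return(peak_list(numeric(0), numeric(0), numeric(0)))
    peak_list(sort(600 + cumsum(runif(k, 0.5, 2))), runif(k, 1, 5),
              runif(k, 3.5, 8))
  })
  rep_q <- quality_metrics(pls, seed = 2)
  observed <- rep_q$metrics$median[1]
  # central 95% range of the sampling distribution, by direct simulation
  sim <- replicate(2000, median(rpois(100, 40)))
  band <- quantile(sim, c(0.025, 0.975))
  expect_gte(observed, band[[1]])
  expect_lte(observed, band[[2]])
  expect_equal(observed, median(counts))
})

test_that("intensity CV reproduces hand-computed values", {
  # three runs with constant TIC: anchor 50, target 8/10/12, balance 22-t,
  # so the TIC-normalized target intensities stay proportional to 8/10/12
  runs <- lapply(c(8, 10, 12), function(t)
    planted_spectrum(c(700, 800, 900), c(50, t, 22 - t)))
  tab <- intensity_cv(runs, target_mzs = c(700, 800), tol = 0.25,
                      min_snr = 3)
  expect_equal(tab$cv_percent[tab$target_mz == 800],
               100 * sd(c(8, 10, 12)) / 10, tolerance = 1e-6)
  expect_equal(tab$cv_percent[tab$target_mz == 700], 0, tolerance = 1e-9)
  expect_true(all(tab$complete))
  # identical runs give CV 0 for every target
  same <- replicate(3, planted_spectrum(c(700, 900), c(30, 10)),
                    simplify = FALSE)
  tab0 <- intensity_cv(same, c(700, 900))
  expect_equal(tab0$cv_percent, c(0, 0), tolerance = 1e-9)
  # unmatched target: zero intensity, flagged, not dropped
  tabu <- intensity_cv(same, c(700, 1000))
  expect_identical(tabu$n_matched[2], 0)
  expect_false(tabu$complete[2])
  expect_equal(tabu$mean[2], 0)
  expect_error(intensity_cv(same[1], c(700)), "at least 2")
})

test_that("ambiguous target matches raise an error naming candidates", {
  runs <- replicate(2, planted_spectrum(c(800, 800.3), c(30, 28)),
                    simplify = FALSE)
  expect_error(intensity_cv(runs, 800.15, tol = 0.25), "matches 2 peaks")
})

test_that("intensity CV is invariant to a common run scale factor", {
  runs <- lapply(c(8, 10, 12), function(t)
    planted_spectrum(c(700, 800, 900), c(50, t, 22 - t)))
  scaled <- lapply(seq_along(runs), function(i)
    mass_spectrum(runs[[i]]$mz, runs[[i]]$intensity * c(2, 5, 9)[i]))
  t1 <- intensity_cv(runs, c(800))
  t2 <- intensity_cv(scaled, c(800))
  expect_equal(t1$cv_percent, t2$cv_percent, tolerance = 1e-9)
})
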