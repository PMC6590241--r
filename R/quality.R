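# Spectral-quality metrics and cross-run peak-intensity comparison.
#
# The QC workflow samples a fixed number of on-tissue spectra, picks peaks
# permissively (S/N >= 1, up to 10000 peaks), and summarises four counts per
# spectrum — all peaks, peaks above S/N 3, peaks over m/z 1500, peaks over
# m/z 2000 — by their medians with percentile-bootstrap 95% confidence
# intervals. Both m/z cutoffs and the S/N cutoff are strict ">" comparisons
# (a literal reading of "above"/"over"; boundary peaks are measure-zero in
# practice).

#' Sample spectra uniformly from on-tissue pixels
#'
#' Uniform sample without replacement from measured on-tissue pixels,
#' reproducible given the seed.
#'
#' @param dataset An [msi_dataset()].
#' @param mask A [tissue_mask()].
#' @param n Number of spectra (default 100).
#' @param seed RNG seed.
#' @return List of [mass_spectrum()] objects; the chosen pixel indices
#'   (storage order) are attached as attribute `pixel_indices`.
#' @export
sample_spectra <- function(dataset, mask, n = 100, seed = 1) {
  stopifnot(inherits(dataset, "msi_dataset"))
  pop <- which(mask_select(mask, dataset))
  if (!is_count(n)) stopf("n must be a positive integer")
  if (n > length(pop))
    stopf("requested %d spectra but only %d on-tissue pixels are measured",
          n, length(pop))
  idx <- with_seed(seed, sample(pop, n, replace = FALSE))
  out <- lapply(idx, function(i) spectrum_at(dataset, i))
  attr(out, "pixel_indices") <- idx
  out
}

#' Percentile-bootstrap confidence interval for the median
#'
#' Draws `n_boot` resamples with replacement, takes the median of each, and
#' returns the `(1-level)/2` and `1-(1-level)/2` percentiles of the
#' bootstrap medians.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap replicates (default 1000; fewer than
#'   100 triggers a warning).
#' @param level Confidence level in `(0, 1)` (default 0.95).
#' @param seed RNG seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000, level = 0.95,
                                seed = 1) {
  if (length(values) < 2L) stopf("need at least 2 values, got %d",
                                 length(values))
  if (!(level > 0 && level < 1)) stopf("level must lie in (0, 1)")
  if (!is_count(n_boot)) stopf("n_boot must be a positive integer")
  if (n_boot < 100) warnf("n_boot = %d is small; the CI will be unstable",
                          n_boot)
  n <- length(values)
  meds <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    apply(matrix(values[idx], nrow = n), 2L, stats::median)
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(meds, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(lo = ci[1L], hi = ci[2L])
}

#' Spectral-quality report from per-spectrum peak lists
#'
#' For every spectrum, four counts are computed: total picked peaks, peaks
#' with S/N strictly above `snr_threshold`, and peaks with m/z strictly over
#' each cutoff. Each count is summarised by its median across spectra with a
#' percentile-bootstrap confidence interval of the median.
#'
#' @param peaklists Non-empty list of [peak_list()] objects (one per sampled
#'   spectrum).
#' @param snr_threshold S/N cutoff for the second metric (default 3).
#' @param mz_cutoffs Numeric vector of m/z cutoffs (default `c(1500, 2000)`).
#' @param n_boot,level,seed Passed to [bootstrap_median_ci()]; per-metric
#'   seeds are derived from `seed` with [derive_seed()].
#' @return A `spectral_quality_report`: `$metrics` is a data frame with one
#'   row per metric (`median`, `lo`, `hi`).
#' @export
quality_metrics <- function(peaklists, snr_threshold = 3,
                            mz_cutoffs = c(1500, 2000), n_boot = 1000,
                            level = 0.95, seed = 1) {
  if (!length(peaklists)) stopf("peaklists is empty")
  if (!all(vapply(peaklists, inherits, TRUE, "peak_list")))
    stopf("peaklists must be a list of peak_list objects")
  counts <- list(peaks_per_spectrum =
                   vapply(peaklists, nrow, integer(1L)))
  counts[[sprintf("peaks_snr_gt%g", snr_threshold)]] <-
    vapply(peaklists, function(pl) sum(pl$snr > snr_threshold), integer(1L))
  for (cut in mz_cutoffs)
    counts[[sprintf("peaks_mz_gt%g", cut)]] <-
      vapply(peaklists, function(pl) sum(pl$mz > cut), integer(1L))

  metrics <- do.call(rbind, lapply(seq_along(counts), function(k) {
    v <- counts[[k]]
    ci <- if (length(v) >= 2L)
      bootstrap_median_ci(v, n_boot, level, derive_seed(seed, k))
    else c(lo = as.double(v), hi = as.double(v))
    data.frame(metric = names(counts)[k], median = stats::median(v),
               lo = ci[["lo"]], hi = ci[["hi"]])
  }))
  rownames(metrics) <- NULL
  structure(list(n_sampled = length(peaklists), metrics = metrics,
                 counts = counts, snr_threshold = snr_threshold,
                 mz_cutoffs = mz_cutoffs, n_boot = n_boot, level = level,
                 seed = seed),
            class = "spectral_quality_report")
}

#' @export
print.spectral_quality_report <- function(x, ...) {
  cat(sprintf(
    "<spectral_quality_report> %d spectra, %g%% bootstrap CI of the median (%d resamples)\n",
    x$n_sampled, 100 * x$level, x$n_boot))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-22s median %g  [%g, %g]\n", m$metric[i], m$median[i],
                m$lo[i], m$hi[i]))
  invisible(x)
}

#' Cross-run peak-intensity coefficient of variation
#'
#' For each run's TIC-normalized average spectrum, peaks are picked at
#' `min_snr`; each target m/z is matched to at most one picked peak within
#' `tol` (several matches raise an ambiguity error; no match contributes
#' intensity 0 and clears the completeness flag rather than being dropped,
#' which would bias the CV downward). Across runs the table reports the
#' mean, sample standard deviation (n-1 denominator, appropriate for small
#' run counts) and `cv_percent = 100 * sd / mean` per target.
#'
#' @param average_spectra List (>= 2) of [mass_spectrum()] average spectra,
#'   one per run.
#' @param target_mzs Numeric vector of target m/z values (Th).
#' @param tol Match tolerance in Th (default 0.25).
#' @param min_snr Picking threshold on the average spectra (default 3).
#' @param ... Further arguments passed to [pick_peaks()].
#' @return An `intensity_cv_table` data frame with columns `target_mz`,
#'   `mean`, `sd`, `cv_percent`, `n_matched`, `complete`; the per-run
#'   matched-intensity matrix is attached as attribute `intensities`.
#' @export
intensity_cv <- function(average_spectra, target_mzs, tol = 0.25,
                         min_snr = 3, ...) {
  if (length(average_spectra) < 2L)
    stopf("need at least 2 average spectra, got %d", length(average_spectra))
  if (!all(vapply(average_spectra, inherits, TRUE, "mass_spectrum")))
    stopf("average_spectra must be a list of mass_spectrum objects")
  if (!length(target_mzs)) stopf("no target m/z values given")

  n_runs <- length(average_spectra)
  peaks <- lapply(average_spectra, function(s)
    pick_peaks(tic_normalize(s), min_snr = min_snr, ...))
  inten <- matrix(0, nrow = length(target_mzs), ncol = n_runs)
  matched <- matrix(FALSE, nrow = length(target_mzs), ncol = n_runs)
  for (r in seq_len(n_runs)) {
    pl <- peaks[[r]]
    for (t in seq_along(target_mzs)) {
      hit <- which(abs(pl$mz - target_mzs[t]) <= tol)
      if (length(hit) > 1L)
        stopf("target m/z %.4f matches %d peaks in run %d within %.3g Th: %s",
              target_mzs[t], length(hit), r, tol,
              paste(sprintf("%.4f", pl$mz[hit]), collapse = ", "))
      if (length(hit) == 1L) {
        inten[t, r] <- pl$intensity[hit]
        matched[t, r] <- TRUE
      }
    }
  }
  means <- rowMeans(inten)
  sds <- apply(inten, 1L, stats::sd)
  tab <- data.frame(target_mz = target_mzs, mean = means, sd = sds,
                    cv_percent = ifelse(means > 0, 100 * sds / means,
                                        NA_real_),
                    n_matched = rowSums(matched),
                    complete = rowSums(matched) == n_runs)
  structure(tab, intensities = inten, n_runs = n_runs, tol = tol,
            min_snr = min_snr, class = c("intensity_cv_table", "data.frame"))
}

#' @export
print.intensity_cv_table <- function(x, ...) {
  cat(sprintf("<intensity_cv_table> %d targets across %d runs (S/N >= %g)\n",
              nrow(x), attr(x, "n_runs"), attr(x, "min_snr")))
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}
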