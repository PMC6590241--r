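# Noise estimation and monoisotopic peak picking.
#
# The picker approximates the vendor "SNAP" behaviour it stands in for:
# local maxima above a signal-to-noise threshold, with isotope chains
# (charge 1, ~1.00235 Th spacing) that match an averagine-model envelope
# collapsed to their monoisotopic member. Noise is a robust (MAD-based)
# running estimate, so S/N values are comparable within this implementation
# only.

ISOTOPE_SPACING <- 1.00235   # Th, charge-1 peptide isotope spacing

# Running local statistics shared by the noise estimator and the picker:
# the running median is the local baseline, and 1.4826 x the running median
# of absolute deviations from it is the local noise scale.
local_stats <- function(spectrum, window_width) {
  if (window_width <= 0) stopf("window_width must be positive")
  n <- length(spectrum$mz)
  if (n < 3L) stopf("spectrum too short for noise estimation (%d points)", n)
  spacing <- stats::median(diff(spectrum$mz))
  k <- odd_window(window_width, spacing, n)
  med <- stats::runmed(spectrum$intensity, k, endrule = "median")
  noise <- 1.4826 * stats::runmed(abs(spectrum$intensity - med), k,
                                  endrule = "median")
  floor_val <- max(.Machine$double.eps * max(spectrum$intensity),
                   .Machine$double.xmin)
  list(baseline = med, noise = pmax(noise, floor_val))
}

#' Estimate per-point noise of a spectrum
#'
#' Robust running noise estimate: for each point, 1.4826 times the running
#' median of absolute deviations from the running median, both taken over a
#' sliding m/z window. The factor 1.4826 scales the MAD to the standard
#' deviation of Gaussian noise. The estimate is floored at a
#' machine-epsilon-scaled multiple of the maximum intensity so it is always
#' strictly positive.
#'
#' @param spectrum A [mass_spectrum()] with at least 3 points.
#' @param window_width Sliding window width in Th (default 50).
#' @return Numeric vector of noise levels, one per point.
#' @export
estimate_noise <- function(spectrum, window_width = 50) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  local_stats(spectrum, window_width)$noise
}

#' Pick peaks in a spectrum
#'
#' Local intensity maxima whose apex signal-to-noise ratio reaches `min_snr`
#' are selected, duplicate maxima within `merge_tol` are merged to the most
#' intense, isotope chains are collapsed to their monoisotopic member by
#' [snap_reduce()] (disable with `snap = FALSE`), and the list is truncated
#' to the `max_peaks` most intense peaks.
#'
#' The S/N of an apex is its height above the local running-median baseline
#' divided by the local [estimate_noise()] level. Correcting for the
#' baseline keeps the ratio meaningful on spectra with a chemical-background
#' offset (an uncorrected ratio would pass every point of an elevated
#' baseline); the reported `intensity` stays the raw apex height.
#'
#' The defaults `min_snr = 1`, `max_peaks = 10000` reproduce the permissive
#' listing stage of the spectral-quality workflow; downstream metrics apply
#' stricter thresholds via [filter_by_snr()].
#'
#' @param spectrum A [mass_spectrum()].
#' @param min_snr Minimal signal-to-noise ratio (default 1).
#' @param max_peaks Maximum number of peaks kept (default 10000).
#' @param noise_window Window width in Th for [estimate_noise()].
#' @param merge_tol Duplicate-maximum merge tolerance in Th (default 0.1).
#' @param snap Collapse isotope chains to monoisotopic peaks (default TRUE).
#' @param envelope_tol Envelope-correlation tolerance passed to
#'   [snap_reduce()].
#' @return A `peak_list`: a data frame with columns `mz`, `intensity`, `snr`
#'   sorted by `mz`, carrying the picking parameters as attributes.
#' @export
pick_peaks <- function(spectrum, min_snr = 1, max_peaks = 10000,
                       noise_window = 50, merge_tol = 0.1, snap = TRUE,
                       envelope_tol = 0.1) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (min_snr < 0) stopf("min_snr must be >= 0")
  if (!is_count(max_peaks)) stopf("max_peaks must be a positive integer")
  y <- spectrum$intensity
  n <- length(y)
  params <- list(min_snr = min_snr, max_peaks = max_peaks,
                 noise_window = noise_window, merge_tol = merge_tol,
                 snap = snap, envelope_tol = envelope_tol)
  if (n < 3L)
    return(peak_list(numeric(0), numeric(0), numeric(0),
                     source_pixel = spectrum$pixel, params = params))
  ls <- local_stats(spectrum, noise_window)
  # local maxima: strictly above the previous point, at least the next point
  # (so only the first point of a plateau is kept); endpoints excluded
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] > 0
  idx <- i[is_max]
  snr <- pmax(y[idx] - ls$baseline[idx], 0) / ls$noise[idx]
  keep <- snr >= min_snr
  idx <- idx[keep]; snr <- snr[keep]

  mz <- spectrum$mz[idx]; int <- y[idx]
  # merge duplicate maxima closer than merge_tol: keep the most intense
  if (length(mz) > 1L) {
    grp <- cumsum(c(TRUE, diff(mz) >= merge_tol))
    best <- tapply(seq_along(mz), grp, function(j) j[which.max(int[j])])
    best <- sort(as.integer(best))
    mz <- mz[best]; int <- int[best]; snr <- snr[best]
  }

  pl <- peak_list(mz, int, snr, source_pixel = spectrum$pixel, params = params)
  if (snap) pl <- snap_reduce(pl, envelope_tol = envelope_tol)
  if (nrow(pl) > max_peaks) {
    ord <- order(pl$intensity, decreasing = TRUE)[seq_len(max_peaks)]
    pl <- pl[sort(ord), , drop = FALSE]
    pl <- peak_list(pl$mz, pl$intensity, pl$snr,
                    source_pixel = spectrum$pixel, params = params)
  }
  pl
}

#' Construct a peak list
#'
#' @param mz,intensity,snr Equal-length numeric vectors; `mz` ascending,
#'   `intensity > 0`, `snr >= 0`.
#' @param source_pixel Optional 0-based `c(col, row)` origin.
#' @param params Optional list of picking parameters.
#' @return A data frame of class `peak_list`.
#' @export
peak_list <- function(mz, intensity, snr, source_pixel = NULL, params = NULL) {
  if (length(mz) != length(intensity) || length(mz) != length(snr))
    stopf("mz, intensity, snr must have equal length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stopf("peak list must be sorted by ascending m/z without duplicates")
  if (any(intensity <= 0)) stopf("peak intensities must be positive")
  if (any(snr < 0)) stopf("peak snr must be non-negative")
  structure(data.frame(mz = as.double(mz), intensity = as.double(intensity),
                       snr = as.double(snr)),
            source_pixel = source_pixel, params = params,
            class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks%s\n", nrow(x),
              if (nrow(x)) sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz))
              else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Averagine isotope envelope
#'
#' Relative isotopologue abundances of a hypothetical average peptide of the
#' given monoisotopic mass, using the averagine composition
#' C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da. The elemental
#' isotope distributions are convolved (polynomial expansion) and truncated.
#'
#' @param mass Monoisotopic mass in Da.
#' @param n_iso Number of isotopologues returned (default 5).
#' @return Numeric vector of abundances normalized to the most abundant
#'   isotopologue.
#' @export
averagine_envelope <- function(mass, n_iso = 5L) {
  if (mass <= 0) stopf("mass must be positive")
  units <- mass / 111.1254
  counts <- round(units * c(C = 4.9384, H = 7.7583, N = 1.3577,
                            O = 1.4773, S = 0.0417))
  iso <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001))
  conv_trunc <- function(a, b, n) {
    out <- numeric(min(n, length(a) + length(b) - 1L))
    for (j in seq_along(b)) {
      hi <- min(length(a), length(out) - j + 1L)
      if (hi >= 1L)
        out[j:(j + hi - 1L)] <- out[j:(j + hi - 1L)] + a[seq_len(hi)] * b[j]
    }
    out
  }
  poly_pow <- function(p, k, n) {
    out <- 1
    base <- p
    while (k > 0L) {
      if (k %% 2L == 1L) out <- conv_trunc(out, base, n)
      base <- conv_trunc(base, base, n)
      k <- k %/% 2L
    }
    out
  }
  env <- 1
  for (el in names(counts))
    if (counts[[el]] > 0L)
      env <- conv_trunc(env, poly_pow(iso[[el]], as.integer(counts[[el]]),
                                      n_iso), n_iso)
  env <- c(env, numeric(max(0L, n_iso - length(env))))[seq_len(n_iso)]
  env / max(env)
}

#' Collapse isotope chains to monoisotopic peaks
#'
#' Peaks forming chains spaced by the charge-1 isotope spacing (~1.00235 Th)
#' whose intensity profile correlates with the averagine-model envelope of
#' the chain's monoisotopic mass (Pearson r >= 1 - `envelope_tol`) are
#' collapsed to the chain's lowest-mass member. Unchained peaks and chains
#' that do not match the envelope pass through unchanged. Never increases
#' the number of peaks.
#'
#' @param candidates A [peak_list()] sorted by m/z.
#' @param isotope_spacing Expected spacing in Th (default 1.00235).
#' @param envelope_tol Correlation tolerance (default 0.1: chains with
#'   Pearson r >= 0.9 against the averagine envelope are collapsed).
#' @param spacing_tol Allowed deviation from the expected spacing in Th
#'   (default 0.05).
#' @return A [peak_list()].
#' @export
snap_reduce <- function(candidates, isotope_spacing = ISOTOPE_SPACING,
                        envelope_tol = 0.1, spacing_tol = 0.05) {
  stopifnot(inherits(candidates, "peak_list"))
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  mz <- candidates$mz; int <- candidates$intensity
  used <- logical(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (used[i]) next
    chain <- i
    repeat {
      last <- chain[length(chain)]
      target <- mz[last] + isotope_spacing
      cand <- which(!used & abs(mz - target) <= spacing_tol)
      cand <- setdiff(cand, chain)
      if (!length(cand)) break
      nxt <- cand[which.min(abs(mz[cand] - target))]
      chain <- c(chain, nxt)
    }
    if (length(chain) >= 2L) {
      m <- min(length(chain), 5L)
      env <- averagine_envelope(mz[chain[1L]], m)
      prof <- int[chain[seq_len(m)]]
      r <- if (stats::sd(prof) == 0 || stats::sd(env) == 0) 0
           else stats::cor(prof, env)
      if (!is.na(r) && r >= 1 - envelope_tol) {
        used[chain] <- TRUE
        keep[chain[1L]] <- TRUE       # collapse to monoisotopic member
        next
      }
    }
    used[i] <- TRUE
    keep[i] <- TRUE
  }
  out <- candidates[keep, , drop = FALSE]
  peak_list(out$mz, out$intensity, out$snr,
            source_pixel = attr(candidates, "source_pixel"),
            params = attr(candidates, "params"))
}

#' Filter a peak list by signal-to-noise ratio
#'
#' @param peaklist A [peak_list()].
#' @param threshold Keep peaks with `snr >= threshold`; order preserved.
#' @return A [peak_list()].
#' @export
filter_by_snr <- function(peaklist, threshold) {
  stopifnot(inherits(peaklist, "peak_list"))
  out <- peaklist[peaklist$snr >= threshold, , drop = FALSE]
  peak_list(out$mz, out$intensity, out$snr,
            source_pixel = attr(peaklist, "source_pixel"),
            params = attr(peaklist, "params"))
}

#' Export a collection of peak lists as CSV
#'
#' Columns `spectrum_id`, `mz`, `intensity`, `snr`, mirroring the collated
#' per-spectrum peak list of the spectral-quality workflow.
#'
#' @param peaklists List of [peak_list()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(peaklists, path) {
  rows <- lapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    if (!nrow(pl)) return(NULL)
    data.frame(spectrum_id = i, mz = pl$mz, intensity = pl$intensity,
               snr = pl$snr)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(spectrum_id = integer(0), mz = numeric(0),
                      intensity = numeric(0), snr = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
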