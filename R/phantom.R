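# Synthetic two-region MSI phantom with ground truth.
#
# The phantom emulates a transverse small-intestine geometry at 50 um
# pitch: an off-tissue margin, an outer "muscle" band and an inner "villi"
# area, with one marker analyte per region (m/z 944.6 in villi, 1105.6 in
# muscle) plus shared analytes present across the whole tissue (defaults:
# trypsin-autolysis peptides). Failure modes are controllable: Gaussian
# delocalization of the analyte maps (wet-step analyte spread) and
# condensation-droplet artifacts that homogenize analytes locally without
# deleting signal. Everything is reproducible from the seed, and the truth
# (region labels, pre-noise analyte maps, mask) is returned alongside the
# dataset so scores can be validated against known ground truth.

#' Specify a synthetic MSI phantom
#'
#' @param n_cols,n_rows Grid extents (default 100 x 100, the smallest
#'   geometry with enough boundary pixels for stable mixed-pixel scores).
#' @param pixel_size_um Pixel pitch (default 50).
#' @param margin_frac Off-tissue margin per side, as a fraction of each grid
#'   dimension (default 0.10).
#' @param band_frac Width of the outer muscle band relative to the tissue
#'   extent (default 0.20; the band thickness is half of this per side).
#' @param analytes Data frame with columns `mz` (Th), `intensity` (mean
#'   apex height) and `region` (`"villi"`, `"muscle"` or `"all"`). The
#'   default places m/z 944.6 in villi, m/z 1105.6 in muscle, and two
#'   trypsin-autolysis peptides (m/z 842.51, 2211.10) across all tissue.
#' @param isotopes Add averagine isotope envelopes to every analyte
#'   (default `TRUE`).
#' @param baseline_sd Additive baseline noise scale (folded-Gaussian
#'   magnitude noise, emulating detector noise after baseline subtraction;
#'   default 1).
#' @param jitter_sigma_ln Log-normal sigma of the per-analyte, per-image
#'   intensity jitter (preparation-level extraction variability; one factor
#'   per analyte per generated image, default 0.2).
#' @param blur_sigma_px Gaussian delocalization of the analyte maps, in
#'   pixels (default 1).
#' @param droplets List of condensation artifacts, each
#'   `list(center = c(col, row), radius_px = , smear_sigma = )`.
#' @param mz_range,mz_step Shared m/z axis (defaults 600-3200 Th at 0.1 Th).
#' @param resolving_power TOF resolving power setting the m/z-proportional
#'   Gaussian peak width (FWHM = mz / R; default 10000).
#' @param seed Master seed for [generate_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cols = 100, n_rows = 100, pixel_size_um = 50,
                         margin_frac = 0.10, band_frac = 0.20,
                         analytes = NULL, isotopes = TRUE, baseline_sd = 1,
                         jitter_sigma_ln = 0.2, blur_sigma_px = 1,
                         droplets = list(), mz_range = c(600, 3200),
                         mz_step = 0.1, resolving_power = 10000, seed = 1) {
  if (is.null(analytes))
    analytes <- data.frame(
      mz = c(944.6, 1105.6, 842.51, 2211.10),
      intensity = c(100, 100, 40, 25),
      region = c("villi", "muscle", "all", "all"))
  if (!all(c("mz", "intensity", "region") %in% names(analytes)))
    stopf("analytes needs columns mz, intensity, region")
  if (!all(analytes$region %in% c("villi", "muscle", "all")))
    stopf("analyte regions must be 'villi', 'muscle' or 'all'")
  if (any(analytes$mz < mz_range[1L] | analytes$mz > mz_range[2L]))
    stopf("analyte m/z outside the phantom m/z range")
  if (any(analytes$intensity <= 0)) stopf("analyte intensities must be > 0")
  if (blur_sigma_px < 0 || baseline_sd < 0 || jitter_sigma_ln < 0)
    stopf("noise and blur parameters must be non-negative")
  for (d in droplets)
    if (!all(c("center", "radius_px", "smear_sigma") %in% names(d)))
      stopf("each droplet needs center, radius_px, smear_sigma")
  spec <- structure(list(
    n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
    pixel_size_um = pixel_size_um, margin_frac = margin_frac,
    band_frac = band_frac, analytes = analytes, isotopes = isotopes,
    baseline_sd = baseline_sd, jitter_sigma_ln = jitter_sigma_ln,
    blur_sigma_px = blur_sigma_px, droplets = droplets,
    mz_range = mz_range, mz_step = mz_step,
    resolving_power = resolving_power, seed = as.integer(seed)),
    class = "phantom_spec")
  geom <- phantom_geometry(spec)          # validates that villi is non-empty
  if (!any(geom == 2L)) stopf("geometry leaves no villi pixels; enlarge grid")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d grid (%g um), %d analytes, blur %g px, baseline sd %g, jitter sigma %g, %d droplet(s), seed %d\n",
    x$n_cols, x$n_rows, x$pixel_size_um, nrow(x$analytes), x$blur_sigma_px,
    x$baseline_sd, x$jitter_sigma_ln, length(x$droplets), x$seed))
  invisible(x)
}

# Region raster: 0 off-tissue, 1 muscle band, 2 villi. Regions partition the
# on-tissue footprint.
phantom_geometry <- function(spec) {
  nc <- spec$n_cols; nr <- spec$n_rows
  mc <- round(spec$margin_frac * nc); mr <- round(spec$margin_frac * nr)
  t_lo_c <- mc; t_hi_c <- nc - mc - 1L
  t_lo_r <- mr; t_hi_r <- nr - mr - 1L
  if (t_hi_c <= t_lo_c || t_hi_r <= t_lo_r)
    stopf("margin leaves no tissue on a %dx%d grid", nc, nr)
  tw <- t_hi_c - t_lo_c + 1L; th <- t_hi_r - t_lo_r + 1L
  band <- max(1L, as.integer(round(spec$band_frac * min(tw, th) / 2)))
  labels <- matrix(0L, nr, nc)
  labels[(t_lo_r:t_hi_r) + 1L, (t_lo_c:t_hi_c) + 1L] <- 1L
  v_lo_c <- t_lo_c + band; v_hi_c <- t_hi_c - band
  v_lo_r <- t_lo_r + band; v_hi_r <- t_hi_r - band
  if (v_hi_c >= v_lo_c && v_hi_r >= v_lo_r)
    labels[(v_lo_r:v_hi_r) + 1L, (v_lo_c:v_hi_c) + 1L] <- 2L
  labels
}

# Separable Gaussian blur with zero padding outside the grid; kernel
# truncated at 4 sigma. Exact linear operator, so blurred step edges follow
# the Gaussian error function.
gaussian_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_mat <- function(n) {
    r <- ceiling(4 * sigma)
    kern <- stats::dnorm(-r:r, sd = sigma)
    kern <- kern / sum(kern)
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1L & j <= n
      K[cbind(idx[ok], j[ok])] <- kern[off + r + 1L]
    }
    K
  }
  conv_mat(nrow(m)) %*% m %*% t(conv_mat(ncol(m)))
}

#' Ground truth of a phantom
#'
#' Builds region labels, the tissue mask (union of the regions) and the
#' per-analyte spatial intensity maps (region indicator times mean
#' intensity, Gaussian-blurred by `blur_sigma_px`, droplet artifacts
#' applied) — everything about the phantom except the noise realization.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth` with fields `region_labels`,
#'   `analyte_maps` (list named by m/z), `mask`, `spec`.
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_geometry(spec)
  region_code <- c(villi = 2L, muscle = 1L)
  maps <- lapply(seq_len(nrow(spec$analytes)), function(i) {
    a <- spec$analytes[i, ]
    ind <- if (a$region == "all") labels > 0L
           else labels == region_code[[a$region]]
    gaussian_blur2d(ind * a$intensity, spec$blur_sigma_px)
  })
  names(maps) <- sprintf("%.4f", spec$analytes$mz)
  truth <- structure(list(region_labels = labels, analyte_maps = maps,
                          mask = tissue_mask(labels > 0L), spec = spec),
                     class = "phantom_truth")
  for (d in spec$droplets)
    truth <- apply_droplet_artifact(truth, d$center, d$radius_px,
                                    d$smear_sigma)
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %dx%d grid, %d analyte maps, %d on-tissue pixels\n",
              x$spec$n_cols, x$spec$n_rows, length(x$analyte_maps),
              sum(x$mask$grid)))
  invisible(x)
}

#' Apply a condensation-droplet artifact to a phantom truth
#'
#' Inside a disc, every analyte map is replaced by its disc mean, then
#' re-blurred with `smear_sigma` (the disc pixels take the locally smoothed
#' values; pixels outside the disc are unchanged). This models a
#' condensation drop that mixes analytes locally without deleting signal:
#' a disc straddling a region boundary therefore carries both markers and
#' turns its pixels yellow under the mixed-pixel classification.
#'
#' @param truth A [phantom_truth()].
#' @param center Disc centre `c(col, row)`, 0-based grid coordinates.
#' @param radius_px Disc radius in pixels (> 0).
#' @param smear_sigma Gaussian sigma in pixels for the local re-blur
#'   (0 leaves the disc piecewise-constant at the disc mean).
#' @return The modified `phantom_truth`.
#' @export
apply_droplet_artifact <- function(truth, center, radius_px, smear_sigma = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (radius_px <= 0) stopf("radius_px must be > 0")
  nr <- truth$spec$n_rows; nc <- truth$spec$n_cols
  cols <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  rows <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
  disc <- (cols - center[1L])^2 + (rows - center[2L])^2 <= radius_px^2
  if (!any(disc))
    stopf("droplet at (%g,%g) radius %g lies fully off the %dx%d grid",
          center[1L], center[2L], radius_px, nc, nr)
  truth$analyte_maps <- lapply(truth$analyte_maps, function(m) {
    m[disc] <- mean(m[disc])
    if (smear_sigma > 0) {
      sm <- gaussian_blur2d(m, smear_sigma)
      m[disc] <- sm[disc]
    }
    m
  })
  truth
}

# Additive spectral template of one analyte on the shared axis: support
# indices and weights with apex normalized to 1.
analyte_template <- function(mz, axis, resolving_power, isotopes) {
  ab <- if (isotopes) averagine_envelope(mz, 5L) else 1
  centers <- mz + (seq_along(ab) - 1L) * ISOTOPE_SPACING
  sigmas <- centers / resolving_power / (2 * sqrt(2 * log(2)))
  lo <- min(centers) - 4 * max(sigmas)
  hi <- max(centers) + 4 * max(sigmas)
  idx <- which(axis >= lo & axis <= hi)
  if (!length(idx)) return(list(idx = integer(0), w = numeric(0)))
  w <- numeric(length(idx))
  for (k in seq_along(ab))
    w <- w + ab[k] * exp(-(axis[idx] - centers[k])^2 / (2 * sigmas[k]^2))
  list(idx = idx, w = w / max(w))
}

#' Render a dataset from a phantom truth
#'
#' Every grid pixel is measured (tissue and margin alike, mirroring the
#' practice of including off-tissue control regions). Per pixel the
#' spectrum is the sum of the analyte peak templates (Gaussian shape of
#' m/z-proportional width, optional averagine isotope envelope), scaled by
#' the analyte map value and the per-analyte log-normal image jitter, plus
#' folded-Gaussian baseline noise on the shared axis. Bitwise reproducible
#' given the seed.
#'
#' @param truth A [phantom_truth()].
#' @param seed RNG seed for the jitter and noise draws.
#' @return An [msi_dataset()] in continuous mode.
#' @export
phantom_dataset <- function(truth, seed) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  axis <- seq(spec$mz_range[1L], spec$mz_range[2L], by = spec$mz_step)
  nc <- spec$n_cols; nr <- spec$n_rows
  np <- nc * nr
  coords <- cbind(col = rep(0:(nc - 1L), times = nr),
                  row = rep(0:(nr - 1L), each = nc))
  n_analytes <- nrow(spec$analytes)
  M <- with_seed(seed, {
    jitter <- exp(stats::rnorm(n_analytes, 0, spec$jitter_sigma_ln))
    # drawn in pixel chunks (the stream is identical to one full draw) so
    # the |N(0, sd)| transform never copies the full matrix
    n_mz <- length(axis)
    M <- matrix(0, nrow = n_mz, ncol = np)
    chunk <- max(1L, 2e7 %/% n_mz)
    for (start in seq(1L, np, by = chunk)) {
      cols <- start:min(np, start + chunk - 1L)
      M[, cols] <- abs(stats::rnorm(n_mz * length(cols), 0,
                                    spec$baseline_sd))
    }
    for (a in seq_len(n_analytes)) {
      tpl <- analyte_template(spec$analytes$mz[a], axis,
                              spec$resolving_power, spec$isotopes)
      if (!length(tpl$idx)) next
      v <- as.vector(t(truth$analyte_maps[[a]]))   # row-major pixel order
      j <- which(v > 0)
      if (!length(j)) next
      M[tpl$idx, j] <- M[tpl$idx, j, drop = FALSE] +
        tpl$w %o% (v[j] * jitter[a])
    }
    M
  })
  new_msi_dataset(mode = "continuous", mz_axis = axis, intensities = M,
                  spectra = NULL, coords = coords, n_cols = nc, n_rows = nr,
                  pixel_size_um = spec$pixel_size_um, mz_range = range(axis))
}

#' Generate a phantom dataset with its ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `dataset` ([msi_dataset()]) and `truth`
#'   ([phantom_truth()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(n_cols = 20, n_rows = 20, seed = 7))
#' ph$dataset
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_truth(spec)
  list(dataset = phantom_dataset(truth, spec$seed), truth = truth)
}

#' Generate a cohort of replicate phantom runs
#'
#' Independent noise and jitter realizations of the same geometry, one per
#' run, each scaled by a per-run multiplicative site effect (emulating
#' between-site sensitivity differences). Run seeds are derived
#' deterministically from the master seed with [derive_seed()].
#'
#' @param spec A [phantom_spec()].
#' @param n_runs Number of runs (>= 1).
#' @param site_effects Numeric vector of per-run multiplicative intensity
#'   factors (default all 1).
#' @param seed Master seed (defaults to `spec$seed`).
#' @return List of runs, each `list(dataset, truth)`; the truth is shared.
#' @export
replicate_cohort <- function(spec, n_runs, site_effects = NULL,
                             seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is_count(n_runs)) stopf("n_runs must be a positive integer")
  if (is.null(site_effects)) site_effects <- rep(1, n_runs)
  if (length(site_effects) != n_runs)
    stopf("site_effects length %d != n_runs %d", length(site_effects), n_runs)
  if (any(site_effects <= 0)) stopf("site_effects must be positive")
  truth <- phantom_truth(spec)
  lapply(seq_len(n_runs), function(r) {
    ds <- phantom_dataset(truth, derive_seed(seed, r))
    if (site_effects[r] != 1)
      ds$intensities <- ds$intensities * site_effects[r]
    list(dataset = ds, truth = truth)
  })
}

#' Pixels carrying both of two analytes in the phantom truth
#'
#' The geometric overlap set: pixels whose truth maps for both analytes
#' exceed `threshold`. With zero blur and hard-edged regions this is the
#' (possibly empty) set of boundary pixels reached by both markers; under
#' delocalization it widens accordingly.
#'
#' @param truth A [phantom_truth()].
#' @param mz_a,mz_b Analyte m/z values present in the spec.
#' @param threshold Map threshold (default 0).
#' @return Logical `n_rows x n_cols` matrix.
#' @export
analyte_overlap <- function(truth, mz_a, mz_b, threshold = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  key <- function(mz) {
    k <- sprintf("%.4f", mz)
    if (!k %in% names(truth$analyte_maps))
      stopf("no analyte at m/z %.4f in the phantom spec", mz)
    k
  }
  (truth$analyte_maps[[key(mz_a)]] > threshold) &
    (truth$analyte_maps[[key(mz_b)]] > threshold)
}
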