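#' Construct an MSI dataset
#'
#' An MSI dataset is a pixel-indexed collection of mass spectra on a
#' rectangular grid with a physical pixel pitch. Pixels inside the grid
#' bounding box may be unmeasured (sparse acquisition); all per-pixel
#' statistics iterate over measured pixels only. The internal coordinate
#' convention is 0-based `(col, row)` with the origin at the top-left,
#' matching raster images; the 1-based imzML convention is converted at the
#' I/O boundary.
#'
#' In `continuous` mode all spectra share one m/z axis and the intensities
#' are held as a dense `n_points x n_pixels` matrix; in `processed` mode each
#' pixel carries its own axis and the spectra are held as a list.
#'
#' @param spectra List of [mass_spectrum()] objects.
#' @param coords Integer matrix or data.frame with columns `col`, `row`
#'   (0-based). Taken from the spectra's `pixel` fields when `NULL`.
#' @param n_cols,n_rows Grid extents; inferred from the maximum coordinates
#'   when `NULL`.
#' @param pixel_size_um Physical pixel pitch in micrometres (default 50, the
#'   raster size of the acquisition the package models).
#' @param mode `"continuous"` or `"processed"`; auto-detected when `NULL`.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(spectra, coords = NULL, n_cols = NULL, n_rows = NULL,
                        pixel_size_um = 50, mode = NULL) {
  if (!length(spectra)) stopf("dataset must contain at least one spectrum")
  if (!all(vapply(spectra, inherits, TRUE, "mass_spectrum")))
    stopf("spectra must be a list of mass_spectrum objects")
  if (is.null(coords)) {
    coords <- t(vapply(spectra, function(s) {
      if (is.null(s$pixel)) stopf("spectrum without pixel and no coords given")
      s$pixel
    }, integer(2L)))
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("col", "row")
  if (nrow(coords) != length(spectra))
    stopf("coords rows (%d) must match number of spectra (%d)",
          nrow(coords), length(spectra))
  if (anyDuplicated(coords))
    stopf("more than one spectrum at pixel (%d,%d)",
          coords[anyDuplicated(coords), 1L], coords[anyDuplicated(coords), 2L])
  if (any(coords < 0L)) stopf("negative pixel coordinates (0-based expected)")
  if (is.null(n_cols)) n_cols <- max(coords[, 1L]) + 1L
  if (is.null(n_rows)) n_rows <- max(coords[, 2L]) + 1L
  if (any(coords[, 1L] >= n_cols) || any(coords[, 2L] >= n_rows))
    stopf("pixel coordinates outside the %dx%d grid", n_cols, n_rows)

  axes <- lapply(spectra, `[[`, "mz")
  same_axis <- length(unique(lengths(axes))) == 1L &&
    all(vapply(axes[-1L], identical, TRUE, axes[[1L]]))
  if (is.null(mode)) mode <- if (same_axis) "continuous" else "processed"
  mode <- match.arg(mode, c("continuous", "processed"))
  if (mode == "continuous" && !same_axis)
    stopf("continuous mode requires an identical m/z axis in every spectrum")

  mz_range <- range(unlist(lapply(axes, range)))
  if (mode == "continuous") {
    new_msi_dataset(
      mode = "continuous", mz_axis = axes[[1L]],
      intensities = vapply(spectra, `[[`, numeric(length(axes[[1L]])),
                           "intensity"),
      spectra = NULL, coords = coords, n_cols = as.integer(n_cols),
      n_rows = as.integer(n_rows), pixel_size_um = pixel_size_um,
      mz_range = mz_range)
  } else {
    new_msi_dataset(
      mode = "processed", mz_axis = NULL, intensities = NULL,
      spectra = spectra, coords = coords, n_cols = as.integer(n_cols),
      n_rows = as.integer(n_rows), pixel_size_um = pixel_size_um,
      mz_range = mz_range)
  }
}

# Low-level constructor; assumes validated inputs. `intensities` is a
# n_points x n_pixels matrix for continuous mode.
new_msi_dataset <- function(mode, mz_axis, intensities, spectra, coords,
                            n_cols, n_rows, pixel_size_um, mz_range) {
  if (mode == "continuous" && !is.matrix(intensities))
    intensities <- matrix(intensities, ncol = nrow(coords))
  structure(list(mode = mode, mz_axis = mz_axis, intensities = intensities,
                 spectra = spectra, coords = coords, n_cols = n_cols,
                 n_rows = n_rows, pixel_size_um = pixel_size_um,
                 mz_range = mz_range),
            class = "msi_dataset")
}

#' Number of measured pixels in a dataset
#' @param x An `msi_dataset`.
#' @return Integer count.
#' @export
n_pixels <- function(x) {
  stopifnot(inherits(x, "msi_dataset"))
  nrow(x$coords)
}

#' Extract one spectrum from a dataset
#'
#' @param x An `msi_dataset`.
#' @param i Pixel index (1..[n_pixels()]) in storage order.
#' @return A [mass_spectrum()].
#' @export
spectrum_at <- function(x, i) {
  stopifnot(inherits(x, "msi_dataset"))
  if (!is_count(i) || i > n_pixels(x)) stopf("pixel index %s out of range", i)
  if (x$mode == "continuous")
    mass_spectrum(x$mz_axis, x$intensities[, i], x$coords[i, ])
  else x$spectra[[i]]
}

#' Per-pixel total ion current
#' @param x An `msi_dataset`.
#' @return Numeric vector over measured pixels (storage order).
#' @export
pixel_tic <- function(x) {
  stopifnot(inherits(x, "msi_dataset"))
  if (x$mode == "continuous") colSums(x$intensities)
  else vapply(x$spectra, function(s) sum(s$intensity), numeric(1L))
}

#' Mean spectrum of a dataset
#'
#' Arithmetic mean over measured pixels (optionally restricted to an
#' on-tissue mask) of the per-pixel TIC-normalized spectra. This is the
#' "TIC normalized average spectrum" consumed by the peak-intensity
#' coefficient-of-variation comparison. Continuous mode only.
#'
#' @param x An `msi_dataset` in continuous mode.
#' @param mask Optional [tissue_mask()]; only on-tissue pixels contribute.
#' @param tic_norm Normalize each pixel to its TIC before averaging
#'   (default `TRUE`).
#' @return A [mass_spectrum()].
#' @export
average_spectrum <- function(x, mask = NULL, tic_norm = TRUE) {
  stopifnot(inherits(x, "msi_dataset"))
  if (x$mode != "continuous")
    stopf("average_spectrum requires a shared m/z axis (continuous mode)")
  sel <- rep(TRUE, n_pixels(x))
  if (!is.null(mask)) {
    validate_mask_dims(mask, x)
    sel <- mask$grid[cbind(x$coords[, 2L] + 1L, x$coords[, 1L] + 1L)]
  }
  if (!any(sel)) stopf("no pixels selected for averaging")
  # averaging as one matrix-vector product avoids copying the intensity
  # matrix (datasets can run to gigabytes)
  w <- numeric(n_pixels(x))
  if (tic_norm) {
    tics <- pixel_tic(x)[sel]
    if (any(tics <= 0)) stopf("zero-TIC pixel in averaging selection")
    w[sel] <- 1 / (tics * sum(sel))
  } else {
    w[sel] <- 1 / sum(sel)
  }
  mass_spectrum(x$mz_axis, as.vector(x$intensities %*% w))
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(
    "<msi_dataset> %s mode, %d spectra on a %dx%d grid (%g um pixels)\n",
    x$mode, n_pixels(x), x$n_cols, x$n_rows, x$pixel_size_um))
  cat(sprintf("  m/z range %.4g-%.4g%s\n", x$mz_range[1L], x$mz_range[2L],
              if (x$mode == "continuous")
                sprintf(", shared axis of %d points", length(x$mz_axis))
              else ""))
  invisible(x)
}

#' @export
summary.msi_dataset <- function(object, ...) {
  tics <- pixel_tic(object)
  out <- list(mode = object$mode, n_pixels = n_pixels(object),
              grid = c(object$n_cols, object$n_rows),
              pixel_size_um = object$pixel_size_um,
              mz_range = object$mz_range, tic = summary(tics))
  class(out) <- "summary.msi_dataset"
  out
}

#' @export
print.summary.msi_dataset <- function(x, ...) {
  cat(sprintf("MSI dataset (%s), %d pixels on %dx%d grid, %g um pitch\n",
              x$mode, x$n_pixels, x$grid[1L], x$grid[2L], x$pixel_size_um))
  cat("Per-pixel TIC:\n"); print(x$tic)
  invisible(x)
}
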