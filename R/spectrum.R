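#' Construct a mass spectrum
#'
#' A mass spectrum is a pair of equal-length vectors: a strictly increasing
#' m/z axis (Thomson) and non-negative intensities (arbitrary detector
#' counts), optionally tagged with the 0-based `(col, row)` pixel it was
#' acquired at.
#'
#' @param mz Numeric vector of m/z values, strictly increasing.
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @param pixel Optional integer vector `c(col, row)`, 0-based grid position.
#' @return An object of class `mass_spectrum`.
#' @examples
#' s <- mass_spectrum(c(600, 601, 602), c(2, 2, 4))
#' tic_normalize(s)$intensity
#' @export
mass_spectrum <- function(mz, intensity, pixel = NULL) {
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (length(mz) != length(intensity))
    stopf("mz and intensity lengths differ (%d vs %d)",
          length(mz), length(intensity))
  if (length(mz) == 0L) stopf("empty spectrum")
  if (anyNA(mz) || anyNA(intensity)) stopf("NA values in spectrum")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stopf("mz axis is not strictly increasing (first violation near index %d)",
          which(diff(mz) <= 0)[1L] + 1L)
  if (any(intensity < 0)) stopf("negative intensities in spectrum")
  if (!is.null(pixel)) {
    if (length(pixel) != 2L || anyNA(pixel))
      stopf("pixel must be c(col, row)")
    pixel <- as.integer(pixel)
  }
  structure(list(mz = mz, intensity = intensity, pixel = pixel),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.4g-%.4g, TIC %.4g%s\n",
              length(x$mz), x$mz[1L], x$mz[length(x$mz)], sum(x$intensity),
              if (is.null(x$pixel)) ""
              else sprintf(", pixel (%d,%d)", x$pixel[1L], x$pixel[2L])))
  invisible(x)
}

#' Total ion current of a spectrum
#'
#' @param x A `mass_spectrum`.
#' @return Sum of the intensity vector.
#' @export
tic <- function(x) {
  stopifnot(inherits(x, "mass_spectrum"))
  sum(x$intensity)
}

#' Normalize intensities to the total ion current
#'
#' Divides every intensity by the spectrum's total ion current (TIC), so the
#' returned intensities sum to one. TIC normalization is idempotent and
#' invariant to a positive global scale factor; it is the per-pixel
#' normalization applied throughout the scoring workflow.
#'
#' @param x A `mass_spectrum` or an `msi_dataset`.
#' @param ... Unused.
#' @return An object of the same class with normalized intensities.
#' @export
tic_normalize <- function(x, ...) UseMethod("tic_normalize")

#' @export
tic_normalize.mass_spectrum <- function(x, ...) {
  s <- sum(x$intensity)
  if (s <= 0)
    stopf("cannot TIC-normalize a spectrum with zero total ion current")
  x$intensity <- x$intensity / s
  x
}

#' @rdname tic_normalize
#' @export
tic_normalize.msi_dataset <- function(x, ...) {
  tics <- pixel_tic(x)
  bad <- which(tics <= 0)
  if (length(bad))
    stopf("pixel (%d,%d) has zero total ion current; cannot TIC-normalize",
          x$coords[bad[1L], 1L], x$coords[bad[1L], 2L])
  if (x$mode == "continuous") {
    x$intensities <- sweep(x$intensities, 2L, tics, "/")
  } else {
    x$spectra <- lapply(x$spectra, tic_normalize)
  }
  x
}
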