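#' Extract an ion image for one m/z window
#'
#' Reduces, for every measured pixel, the intensities whose m/z lies in the
#' closed window `[mz_center - mz_tol, mz_center + mz_tol]` to a single
#' value. The default reducer `sum` is proportional to the ion count in the
#' window; `mean` and `max` are offered for sensitivity analysis. The window
#' half-width is expressed in Thomson (not ppm); the default 0.25 Th suits
#' TOF peptide channels.
#'
#' Pixels without a spectrum are flagged invalid (`NA` value, `valid ==
#' FALSE`), never silently zero. A window that is empty for every pixel
#' yields a warning and an all-zero image rather than an error.
#'
#' @param dataset An [msi_dataset()].
#' @param mz_center Window centre in Th.
#' @param mz_tol Half-width in Th (default 0.25).
#' @param reducer One of `"sum"`, `"max"`, `"mean"`.
#' @return An object of class `ion_image`: `values` and `valid` are
#'   `n_rows x n_cols` matrices.
#' @export
extract_ion_image <- function(dataset, mz_center, mz_tol = 0.25,
                              reducer = c("sum", "max", "mean")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  reducer <- match.arg(reducer)
  lo <- mz_center - mz_tol
  hi <- mz_center + mz_tol
  if (hi < dataset$mz_range[1L] || lo > dataset$mz_range[2L])
    stopf("window [%.4g, %.4g] does not intersect dataset m/z range [%.4g, %.4g]",
          lo, hi, dataset$mz_range[1L], dataset$mz_range[2L])

  np <- n_pixels(dataset)
  vals <- numeric(np)
  any_points <- FALSE
  if (dataset$mode == "continuous") {
    idx <- which(dataset$mz_axis >= lo & dataset$mz_axis <= hi)
    if (length(idx)) {
      any_points <- TRUE
      block <- dataset$intensities[idx, , drop = FALSE]
      vals <- switch(reducer,
                     sum = colSums(block),
                     mean = colMeans(block),
                     max = apply(block, 2L, max))
    }
  } else {
    for (i in seq_len(np)) {
      s <- dataset$spectra[[i]]
      j <- which(s$mz >= lo & s$mz <= hi)
      if (length(j)) {
        any_points <- TRUE
        vals[i] <- switch(reducer,
                          sum = sum(s$intensity[j]),
                          mean = mean(s$intensity[j]),
                          max = max(s$intensity[j]))
      }
    }
  }
  if (!any_points)
    warnf("m/z window [%.4g, %.4g] contains no data points in any pixel; returning zeros",
          lo, hi)

  values <- matrix(NA_real_, dataset$n_rows, dataset$n_cols)
  valid <- matrix(FALSE, dataset$n_rows, dataset$n_cols)
  at <- cbind(dataset$coords[, 2L] + 1L, dataset$coords[, 1L] + 1L)
  values[at] <- vals
  valid[at] <- TRUE
  structure(list(values = values, valid = valid, mz_center = mz_center,
                 mz_tol = mz_tol, reducer = reducer),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf(
    "<ion_image> m/z %.4f +/- %.3g (%s), %dx%d grid, %d valid pixels, range [%.4g, %.4g]\n",
    x$mz_center, x$mz_tol, x$reducer, ncol(x$values), nrow(x$values),
    sum(x$valid), if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
plot.ion_image <- function(x, main = NULL, ...) {
  v <- x$values
  v[!x$valid] <- NA
  # flip rows so the top-left origin renders top-left
  graphics::image(t(v[nrow(v):1L, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                  main = main %||%
                    sprintf("m/z %.4f +/- %.3g", x$mz_center, x$mz_tol), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
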