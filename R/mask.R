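#' Construct a tissue mask
#'
#' A binary raster aligned to the MSI pixel grid; `TRUE` marks on-tissue
#' pixels. Stored as an `n_rows x n_cols` logical matrix (row-major raster,
#' origin top-left), the same orientation as ion images.
#'
#' @param grid Logical matrix, `n_rows x n_cols`.
#' @return An object of class `tissue_mask`.
#' @export
tissue_mask <- function(grid) {
  if (!is.matrix(grid)) stopf("mask grid must be a matrix")
  if (anyNA(grid)) stopf("mask grid contains NA")
  storage.mode(grid) <- "logical"
  structure(list(grid = grid, n_cols = ncol(grid), n_rows = nrow(grid)),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d grid, %d on-tissue pixels (%.1f%%)\n",
              x$n_cols, x$n_rows, sum(x$grid),
              100 * mean(x$grid)))
  invisible(x)
}

validate_mask_dims <- function(mask, dataset) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (mask$n_cols != dataset$n_cols || mask$n_rows != dataset$n_rows)
    stopf("mask dimensions %dx%d do not match dataset grid %dx%d",
          mask$n_cols, mask$n_rows, dataset$n_cols, dataset$n_rows)
  invisible(TRUE)
}

# Logical vector over measured pixels (storage order): on-tissue & measured.
mask_select <- function(mask, dataset) {
  validate_mask_dims(mask, dataset)
  mask$grid[cbind(dataset$coords[, 2L] + 1L, dataset$coords[, 1L] + 1L)]
}

#' Derive an on-tissue mask from per-pixel TIC
#'
#' Fallback for when no mask derived from the optical image is available: a
#' measured pixel is called on-tissue when its total ion current is strictly
#' greater than the given quantile of all measured-pixel TICs. With
#' `quantile_threshold = 0` every measured pixel is on-tissue. Because the
#' comparison is strictly greater, a constant TIC field with a positive
#' threshold yields an all-off mask (with a warning) rather than an arbitrary
#' split.
#'
#' @param dataset An `msi_dataset`.
#' @param quantile_threshold Fraction in `[0, 1)`.
#' @return A [tissue_mask()].
#' @export
mask_from_tic <- function(dataset, quantile_threshold = 0.2) {
  stopifnot(inherits(dataset, "msi_dataset"))
  q <- quantile_threshold
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q >= 1)
    stopf("quantile_threshold must lie in [0, 1), got %s", format(q))
  tics <- pixel_tic(dataset)
  on <- if (q == 0) rep(TRUE, length(tics))
        else tics > stats::quantile(tics, q, type = 7, names = FALSE)
  grid <- matrix(FALSE, dataset$n_rows, dataset$n_cols)
  grid[cbind(dataset$coords[, 2L] + 1L, dataset$coords[, 1L] + 1L)] <- on
  if (!any(on))
    warnf("TIC-derived mask is empty (constant TIC field at threshold %g?)", q)
  tissue_mask(grid)
}

#' Read a tissue mask from PNG or run-length text
#'
#' PNG rasters are thresholded at 0.5 (first channel). The plain-text
#' run-length format is: a header line `ncols nrows`, then lines `value count`
#' describing the mask in row-major order (row 0 first).
#'
#' @param path File path; format chosen by extension (`.png` vs anything else).
#' @return A [tissue_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(tissue_mask(img > 0.5))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stopf("bad mask header in %s", path)
  runs <- do.call(rbind, lapply(strsplit(trimws(lines[-1L]), "\\s+"),
                                as.integer))
  if (ncol(runs) != 2L || anyNA(runs)) stopf("bad run-length lines in %s", path)
  v <- rep(runs[, 1L] > 0L, runs[, 2L])
  if (length(v) != hdr[1L] * hdr[2L])
    stopf("run lengths cover %d pixels, expected %d (%dx%d)",
          length(v), hdr[1L] * hdr[2L], hdr[1L], hdr[2L])
  tissue_mask(matrix(v, nrow = hdr[2L], ncol = hdr[1L], byrow = TRUE))
}

#' Write a tissue mask to PNG or run-length text
#'
#' @param mask A [tissue_mask()].
#' @param path Output path; `.png` writes a grayscale PNG, anything else the
#'   run-length text format of [read_mask()].
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(mask$grid * 1.0, path)
  } else {
    v <- as.integer(t(mask$grid))          # row-major
    r <- rle(v)
    writeLines(c(sprintf("%d %d", mask$n_cols, mask$n_rows),
                 sprintf("%d %d", r$values, r$lengths)), path)
  }
  invisible(path)
}
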