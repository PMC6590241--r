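# Mixed-pixel spatial-resolution score.
#
# Two ion images of markers specific to adjacent tissue regions are clipped
# to percentile bounds, every on-tissue pixel is classified RED / GREEN /
# YELLOW by a relative-intensity rule, and the score is the percentage of
# YELLOW (mixed) pixels among classified pixels. Yellow pixels mark analyte
# overlap: some arise unavoidably from finite pixel size at region
# boundaries, an excess indicates delocalization during wet preparation
# steps.

LBL_EXCLUDED <- 0L
LBL_RED <- 1L
LBL_GREEN <- 2L
LBL_YELLOW <- 3L
LABEL_NAMES <- c("EXCLUDED", "RED", "GREEN", "YELLOW")

#' Clip an ion image to percentile bounds
#'
#' Percentiles are computed over on-tissue valid pixels only (off-tissue
#' background must not set the floor); values below the low percentile are
#' raised to it and values above the high percentile lowered to it
#' (clamping). Off-tissue pixels are left untouched. With
#' `rescale = TRUE` the clipped channel is additionally rescaled affinely to
#' `[0, 1]` — an alternative reading of "set to the percentile" that is
#' exposed for sensitivity analysis (it changes scores, because the ratio
#' rule compares the two channels on their clipped scales).
#'
#' @param image An [ion_image()].
#' @param mask A [tissue_mask()] with matching dimensions.
#' @param low_pct,high_pct Percentile bounds (defaults 3 and 97).
#' @param rescale Affinely rescale to `[0, 1]` after clamping
#'   (default `FALSE`).
#' @return The clipped [ion_image()], with the clip bounds attached as
#'   attributes `clip_low`/`clip_high`.
#' @export
clip_channel <- function(image, mask, low_pct = 3, high_pct = 97,
                         rescale = FALSE) {
  stopifnot(inherits(image, "ion_image"), inherits(mask, "tissue_mask"))
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stopf("need 0 <= low_pct < high_pct <= 100, got %g and %g",
          low_pct, high_pct)
  if (nrow(image$values) != mask$n_rows || ncol(image$values) != mask$n_cols)
    stopf("image (%dx%d) and mask (%dx%d) dimensions differ",
          ncol(image$values), nrow(image$values), mask$n_cols, mask$n_rows)
  sel <- mask$grid & image$valid
  v <- image$values[sel]
  if (length(v) < 2L)
    stopf("fewer than 2 on-tissue valid pixels; cannot compute percentiles")
  p_lo <- pct_quantile(v, low_pct)
  p_hi <- pct_quantile(v, high_pct)
  if (p_lo == p_hi) {
    warnf("percentile bounds coincide (%.6g); channel returned as constant",
          p_lo)
    image$values[sel] <- p_lo
  } else {
    image$values[sel] <- pmin(pmax(v, p_lo), p_hi)
    if (rescale)
      image$values[sel] <- (image$values[sel] - p_lo) / (p_hi - p_lo)
  }
  attr(image, "clip_low") <- p_lo
  attr(image, "clip_high") <- p_hi
  image
}

#' Classify pixels as red, green, yellow or excluded
#'
#' Per on-tissue pixel with values `a` (red channel) and `b` (green
#' channel): when the less intense channel reaches at least `ratio` times
#' the more intense channel the pixel is YELLOW (mixed); otherwise it takes
#' the colour of the more intense channel. Exact ties (including both
#' channels at the common clip floor) are YELLOW, since `min == max >=
#' ratio * max`. Off-mask or unmeasured pixels are EXCLUDED. Channels are
#' expected to be clipped already (see [clip_channel()]).
#'
#' @param red,green Clipped [ion_image()] channels on the same grid.
#' @param mask A [tissue_mask()] with matching dimensions.
#' @param ratio Mixing threshold in `(0, 1]` (default 0.70).
#' @param min_signal_fraction Optional floor: pixels whose stronger channel
#'   is below this fraction of the strongest on-tissue pixel are EXCLUDED
#'   (default 0, i.e. every on-tissue pixel is classified).
#' @return A `mixed_pixel_result` with the label raster, per-colour counts
#'   and the score: `100 * |YELLOW| / (|RED| + |GREEN| + |YELLOW|)`.
#' @export
classify_pixels <- function(red, green, mask, ratio = 0.70,
                            min_signal_fraction = 0) {
  stopifnot(inherits(red, "ion_image"), inherits(green, "ion_image"),
            inherits(mask, "tissue_mask"))
  if (!identical(dim(red$values), dim(green$values)) ||
      nrow(red$values) != mask$n_rows || ncol(red$values) != mask$n_cols)
    stopf("red, green and mask must share grid dimensions")
  if (!(ratio > 0 && ratio <= 1)) stopf("ratio must lie in (0, 1]")

  on <- mask$grid & red$valid & green$valid
  a <- red$values
  b <- green$values
  labels <- matrix(LBL_EXCLUDED, mask$n_rows, mask$n_cols)
  if (min_signal_fraction > 0 && any(on)) {
    hi <- pmax(a, b)
    floor_val <- min_signal_fraction * max(hi[on])
    on <- on & hi >= floor_val
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  yellow <- on & lo >= ratio * hi
  labels[yellow] <- LBL_YELLOW
  labels[on & !yellow & a > b] <- LBL_RED
  labels[on & !yellow & b > a] <- LBL_GREEN

  counts <- c(RED = sum(labels == LBL_RED), GREEN = sum(labels == LBL_GREEN),
              YELLOW = sum(labels == LBL_YELLOW))
  denom <- sum(counts)
  score <- if (denom > 0) 100 * counts[["YELLOW"]] / denom else NA_real_
  structure(list(labels = labels, score_percent = score, counts = counts,
                 params = list(ratio = ratio,
                               min_signal_fraction = min_signal_fraction,
                               red_clip = c(attr(red, "clip_low"),
                                            attr(red, "clip_high")),
                               green_clip = c(attr(green, "clip_low"),
                                              attr(green, "clip_high")))),
            class = "mixed_pixel_result")
}

#' Mixed-pixel spatial-resolution score
#'
#' End-to-end scoring: extract the two marker ion images (after per-pixel
#' TIC normalization by default), clip each to its 3rd/97th percentile over
#' on-tissue pixels and rescale it to `[0, 1]` on that range, classify every
#' on-tissue pixel by the 70% ratio rule, and report the percentage of
#' yellow (mixed) pixels. Defaults follow the workflow the package models:
#' red marker m/z 944.6 (villi/lumen), green marker m/z 1105.6
#' (crypts/muscle), 0.25 Th windows.
#'
#' The per-channel rescaling is what makes the ratio rule well defined: the
#' two channels are intensities of unrelated ions with arbitrary relative
#' units, and only after mapping each to its clipped display range is the
#' score invariant to a positive scale factor on either channel (it is also
#' invariant to swapping them). Setting `rescale_after_clip = FALSE`
#' compares the channels on their raw clamped scales instead; that reading
#' loses scale invariance and is exposed for sensitivity analysis only.
#'
#' @param dataset An [msi_dataset()].
#' @param mask A [tissue_mask()]; when `NULL`, a TIC-derived fallback mask
#'   ([mask_from_tic()] at quantile `mask_quantile`) is used.
#' @param red_mz,green_mz Marker m/z values in Th.
#' @param mz_tol Window half-width in Th.
#' @param low_pct,high_pct Percentile clip bounds.
#' @param ratio Mixing threshold.
#' @param reducer Ion-image reducer (`"sum"`, `"max"`, `"mean"`).
#' @param tic_norm TIC-normalize pixels before extraction (default `TRUE`).
#' @param rescale_after_clip Rescale clipped channels to `[0,1]`
#'   (default `TRUE`; see Details).
#' @param min_signal_fraction See [classify_pixels()].
#' @param mask_quantile Quantile for the fallback TIC mask (default 0.2).
#' @return A `mixed_pixel_result`; all parameters used are carried in
#'   `$params`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_cols = 30, n_rows = 30, seed = 1))
#' res <- spatial_resolution_score(ph$dataset, ph$truth$mask)
#' res$score_percent
#' @export
spatial_resolution_score <- function(dataset, mask = NULL,
                                     red_mz = 944.6, green_mz = 1105.6,
                                     mz_tol = 0.25, low_pct = 3,
                                     high_pct = 97, ratio = 0.70,
                                     reducer = "sum", tic_norm = TRUE,
                                     rescale_after_clip = TRUE,
                                     min_signal_fraction = 0,
                                     mask_quantile = 0.2) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (is.null(mask)) mask <- mask_from_tic(dataset, mask_quantile)
  validate_mask_dims(mask, dataset)
  red <- extract_ion_image(dataset, red_mz, mz_tol, reducer)
  green <- extract_ion_image(dataset, green_mz, mz_tol, reducer)
  if (tic_norm) {
    # dividing the extracted value by the pixel TIC equals extracting from
    # TIC-normalized spectra for every reducer, without copying the dataset;
    # zero-TIC pixels cannot be normalized and are flagged invalid
    tics <- pixel_tic(dataset)
    at <- cbind(dataset$coords[, 2L] + 1L, dataset$coords[, 1L] + 1L)
    ok <- tics > 0
    for (img in c("red", "green")) {
      im <- get(img)
      im$values[at[ok, , drop = FALSE]] <-
        im$values[at[ok, , drop = FALSE]] / tics[ok]
      im$valid[at[!ok, , drop = FALSE]] <- FALSE
      assign(img, im)
    }
    if (any(!ok & mask$grid[at]))
      warnf("%d on-tissue pixel(s) with zero TIC were excluded", sum(!ok & mask$grid[at]))
  }
  red <- clip_channel(red, mask, low_pct, high_pct,
                      rescale = rescale_after_clip)
  green <- clip_channel(green, mask, low_pct, high_pct,
                        rescale = rescale_after_clip)
  res <- classify_pixels(red, green, mask, ratio,
                         min_signal_fraction = min_signal_fraction)
  res$params <- c(res$params,
                  list(red_mz = red_mz, green_mz = green_mz, mz_tol = mz_tol,
                       low_pct = low_pct, high_pct = high_pct,
                       reducer = reducer, tic_norm = tic_norm,
                       rescale_after_clip = rescale_after_clip))
  res
}

#' @export
print.mixed_pixel_result <- function(x, ...) {
  cat(sprintf("<mixed_pixel_result> score %.2f%% yellow\n", x$score_percent))
  cat(sprintf("  pixels: %d red, %d green, %d yellow, %d excluded\n",
              x$counts[["RED"]], x$counts[["GREEN"]], x$counts[["YELLOW"]],
              sum(x$labels == LBL_EXCLUDED)))
  invisible(x)
}

#' @export
summary.mixed_pixel_result <- function(object, ...) {
  total <- sum(object$counts)
  cat(sprintf("Mixed-pixel spatial-resolution score: %.2f%%\n",
              object$score_percent))
  cat(sprintf("Classified pixels: %d (red %.1f%%, green %.1f%%, yellow %.1f%%)\n",
              total, 100 * object$counts[["RED"]] / total,
              100 * object$counts[["GREEN"]] / total,
              100 * object$counts[["YELLOW"]] / total))
  cat(sprintf("Ratio threshold %.2f, clip percentiles as recorded in $params\n",
              object$params$ratio))
  invisible(object)
}

# RGB array (rows x cols x 3) for rendering: red/green/yellow on black.
mixed_pixel_rgb <- function(x) {
  stopifnot(inherits(x, "mixed_pixel_result"))
  r <- (x$labels == LBL_RED) | (x$labels == LBL_YELLOW)
  g <- (x$labels == LBL_GREEN) | (x$labels == LBL_YELLOW)
  array(c(r * 1.0, g * 1.0, x$labels * 0.0), dim = c(dim(x$labels), 3L))
}

#' @export
plot.mixed_pixel_result <- function(x, ...) {
  rgb <- mixed_pixel_rgb(x)
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::title(sprintf("mixed pixels: %.2f%% yellow", x$score_percent))
  invisible(x)
}

#' Write the label raster of a mixed-pixel result as PNG
#'
#' @param x A `mixed_pixel_result`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(x, path) {
  png::writePNG(mixed_pixel_rgb(x), path)
  invisible(path)
}
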