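# Spatial segmentation: peak-aligned feature matrices, bisecting k-means
# with correlation distance, and PCA with unit-variance scaling.
#
# Bisecting k-means recursively 2-splits the leaf with the largest
# within-cluster sum of correlation distances to its centroid; assignment
# uses correlation distance, the centroid update is the arithmetic mean of
# member rows. The recursion stops at max_depth or when no leaf holds two
# distinct rows. This is authored here rather than delegated: stats::kmeans
# is Euclidean-only and the correlation metric is the point.

#' Correlation distance between two vectors
#'
#' `1 - Pearson correlation`, ranging over `[0, 2]`. Invariant to per-vector
#' affine maps with positive scale.
#'
#' @param a,b Numeric vectors of equal length with positive variance.
#' @return A single number in `[0, 2]`.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("correlation distance undefined for a zero-variance vector")
  1 - stats::cor(a, b)
}

# Correlation distance of every row of X to centroid c; rows with zero
# variance get NA (callers apply the Euclidean fallback).
row_cor_dist <- function(X, centroid) {
  xc <- X - rowMeans(X)
  den_x <- sqrt(rowSums(xc^2))
  cc <- centroid - mean(centroid)
  den_c <- sqrt(sum(cc^2))
  if (den_c == 0) return(rep(NA_real_, nrow(X)))
  d <- 1 - as.vector(xc %*% cc) / (den_x * den_c)
  d[den_x == 0] <- NA_real_
  d
}

#' Build a peak-aligned feature matrix from one or more datasets
#'
#' Per dataset: spectra are TIC-normalized, peaks are picked on the
#' dataset's mean spectrum, and consensus m/z bins are formed across
#' datasets by single-linkage merging of the picked positions within
#' `align_tol`. Every on-tissue pixel then contributes one row: its
#' intensity integrated over `bin_tol` around each consensus m/z, after an
#' optional moving-average smoothing of the spectrum ("weak denoising",
#' window `denoise_window` points; 0 disables).
#'
#' @param datasets An [msi_dataset()] or list of them (continuous mode).
#' @param masks A [tissue_mask()] or list matching `datasets`.
#' @param min_snr Picking threshold on the mean spectra (default 3).
#' @param align_tol Consensus merge tolerance in Th (default 0.3, the scale
#'   of TOF peak jitter).
#' @param bin_tol Integration half-window per bin in Th (default 0.25).
#' @param denoise_window Moving-average window in points (default 3).
#' @param ... Passed to [pick_peaks()].
#' @return A `feature_matrix`: numeric matrix (pixels x bins) with
#'   attributes `mz` (consensus bin centres) and `pixels` (data frame with
#'   `dataset`, `col`, `row`).
#' @export
build_feature_matrix <- function(datasets, masks, min_snr = 3,
                                 align_tol = 0.3, bin_tol = 0.25,
                                 denoise_window = 3, ...) {
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  if (inherits(masks, "tissue_mask")) masks <- list(masks)
  if (length(datasets) < 1L) stopf("need at least one dataset")
  if (length(masks) != length(datasets))
    stopf("got %d masks for %d datasets", length(masks), length(datasets))
  if (any(vapply(datasets, function(d) d$mode, "") != "continuous"))
    stopf("feature matrices require continuous-mode datasets")

  peak_mzs <- unlist(lapply(seq_along(datasets), function(k) {
    avg <- average_spectrum(datasets[[k]], masks[[k]])
    pick_peaks(avg, min_snr = min_snr, ...)$mz
  }))
  if (!length(peak_mzs))
    stopf("no peaks found on any mean spectrum; lower min_snr")
  peak_mzs <- sort(peak_mzs)
  # single-linkage chains: successive gaps <= align_tol share a bin
  grp <- cumsum(c(TRUE, diff(peak_mzs) > align_tol))
  consensus <- as.vector(tapply(peak_mzs, grp, mean))

  rows <- list(); meta <- list()
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    sel <- which(mask_select(masks[[k]], ds))
    if (!length(sel)) next
    tics <- pixel_tic(ds)[sel]
    if (any(tics <= 0)) stopf("zero-TIC on-tissue pixel in dataset %d", k)
    block <- matrix(0, nrow = length(sel), ncol = length(consensus))
    n_mz <- length(ds$mz_axis)
    for (b in seq_along(consensus)) {
      rng <- range(which(ds$mz_axis >= consensus[b] - bin_tol &
                           ds$mz_axis <= consensus[b] + bin_tol))
      if (!is.finite(rng[1L])) next
      cf <- window_coeffs(rng[1L], rng[2L], denoise_window, n_mz)
      block[, b] <- as.vector(
        crossprod(ds$intensities[cf$rows, sel, drop = FALSE], cf$w))
    }
    # dividing the integrated bins by the pixel TIC equals integrating
    # TIC-normalized spectra, without copying the intensity matrix
    block <- block / tics
    rows[[k]] <- block
    meta[[k]] <- data.frame(dataset = k,
                            col = ds$coords[sel, 1L],
                            row = ds$coords[sel, 2L])
  }
  X <- do.call(rbind, rows)
  pixels <- do.call(rbind, meta)
  nonzero <- rowSums(X) > 0
  if (!all(nonzero)) {
    warnf("dropping %d all-zero pixel rows from the feature matrix",
          sum(!nonzero))
    X <- X[nonzero, , drop = FALSE]
    pixels <- pixels[nonzero, , drop = FALSE]
  }
  if (!nrow(X)) stopf("empty feature matrix; lower min_snr or check masks")
  rownames(pixels) <- NULL
  structure(X, mz = consensus, pixels = pixels,
            params = list(min_snr = min_snr, align_tol = align_tol,
                          bin_tol = bin_tol,
                          denoise_window = denoise_window),
            class = c("feature_matrix", "matrix", "array"))
}

# Coefficients expressing "sum of moving-average-smoothed rows a..e" as a
# weighted sum of raw axis rows: the smoother (odd window w) commutes with
# the window sum, giving unit weight inside and tapered weight at the edges.
window_coeffs <- function(a, e, w, n) {
  if (w <= 1L) return(list(rows = a:e, w = rep(1, e - a + 1L)))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  lo <- max(1L, a - h); hi <- min(n, e + h)
  wt <- numeric(hi - lo + 1L)
  for (i in a:e) {
    jlo <- max(lo, i - h); jhi <- min(hi, i + h)
    wt[(jlo:jhi) - lo + 1L] <- wt[(jlo:jhi) - lo + 1L] + 1 / w
  }
  list(rows = lo:hi, w = wt)
}

#' Bisecting k-means segmentation with correlation distance
#'
#' Builds a binary segmentation tree: starting from all rows, the leaf with
#' the largest within-cluster sum of correlation distances to its centroid
#' is repeatedly split by 2-means (`n_init` restarts seeded from the master
#' seed, assignment by correlation distance, centroids as arithmetic row
#' means, best restart by within-cluster distance sum), until `max_depth`
#' levels are reached or no leaf holds two distinct rows. Zero-variance rows
#' cannot be correlated; inside the splitter they are assigned to the nearer
#' centroid by Euclidean distance and contribute the metric's maximum
#' neutral distance 1 to the objective.
#'
#' @param features A `feature_matrix` (or plain numeric matrix, rows =
#'   observations).
#' @param max_depth Maximum tree depth (default 4; depth 1 = one split).
#' @param seed RNG seed controlling the restarts.
#' @param n_init Number of 2-means restarts per split (default 10).
#' @return A `segmentation_tree`; see [leaf_labels()] and [as_newick()].
#' @export
bisecting_kmeans <- function(features, max_depth = 4, seed = 1, n_init = 10) {
  X <- unclass(features)
  if (!is.matrix(X)) stopf("features must be a matrix")
  if (nrow(X) < 2L) stopf("need at least 2 rows to segment")
  if (!is_count(max_depth)) stopf("max_depth must be a positive integer")

  nodes <- list(list(id = 1L, parent = NA_integer_, level = 0L,
                     rows = seq_len(nrow(X)),
                     centroid = colMeans(X),
                     wss = cluster_wss(X, seq_len(nrow(X))),
                     children = NULL))
  with_seed(seed, {
    repeat {
      cand <- Filter(function(nd) {
        is.null(nd$children) && nd$level < max_depth &&
          length(nd$rows) >= 2L && has_distinct_rows(X, nd$rows)
      }, nodes)
      if (!length(cand)) break
      target <- cand[[which.max(vapply(cand, `[[`, numeric(1L), "wss"))]]
      split <- two_means(X[target$rows, , drop = FALSE], n_init)
      if (is.null(split)) {                      # could not split; freeze leaf
        nodes[[target$id]]$children <- integer(0)
        next
      }
      for (side in 1:2) {
        rows <- target$rows[split$labels == side]
        nid <- length(nodes) + 1L
        nodes[[nid]] <- list(id = nid, parent = target$id,
                             level = target$level + 1L, rows = rows,
                             centroid = colMeans(X[rows, , drop = FALSE]),
                             wss = cluster_wss(X, rows), children = NULL)
        nodes[[target$id]]$children <- c(nodes[[target$id]]$children, nid)
      }
    }
  })
  structure(list(nodes = nodes, n_rows = nrow(X),
                 mz = attr(features, "mz"),
                 pixels = attr(features, "pixels"),
                 params = list(max_depth = max_depth, seed = seed,
                               n_init = n_init)),
            class = "segmentation_tree")
}

has_distinct_rows <- function(X, rows) {
  first <- X[rows[1L], ]
  for (r in rows[-1L]) if (any(X[r, ] != first)) return(TRUE)
  FALSE
}

# Within-cluster sum of correlation distances to the centroid.
cluster_wss <- function(X, rows) {
  sub <- X[rows, , drop = FALSE]
  d <- row_cor_dist(sub, colMeans(sub))
  d[is.na(d)] <- 1
  sum(d)
}

# One 2-means split with n_init restarts; returns labels (1/2) and the
# objective, or NULL when every restart collapses.
two_means <- function(X, n_init) {
  n <- nrow(X)
  best <- NULL
  for (init in seq_len(n_init)) {
    start <- sample.int(n, 2L)
    if (all(X[start[1L], ] == X[start[2L], ])) next
    c1 <- X[start[1L], ]; c2 <- X[start[2L], ]
    labels <- integer(n)
    for (iter in 1:100) {
      d1 <- row_cor_dist(X, c1); d2 <- row_cor_dist(X, c2)
      bad <- is.na(d1) | is.na(d2)
      new_labels <- ifelse(d1 <= d2, 1L, 2L)
      if (any(bad)) {                      # Euclidean fallback
        e1 <- rowSums(sweep(X[bad, , drop = FALSE], 2L, c1)^2)
        e2 <- rowSums(sweep(X[bad, , drop = FALSE], 2L, c2)^2)
        new_labels[bad] <- ifelse(e1 <= e2, 1L, 2L)
      }
      if (!any(new_labels == 1L) || !any(new_labels == 2L)) break
      if (identical(new_labels, labels)) break
      labels <- new_labels
      c1 <- colMeans(X[labels == 1L, , drop = FALSE])
      c2 <- colMeans(X[labels == 2L, , drop = FALSE])
    }
    if (!any(labels == 1L) || !any(labels == 2L)) next
    obj <- {
      d1 <- row_cor_dist(X[labels == 1L, , drop = FALSE], c1)
      d2 <- row_cor_dist(X[labels == 2L, , drop = FALSE], c2)
      sum(ifelse(is.na(d1), 1, d1)) + sum(ifelse(is.na(d2), 1, d2))
    }
    if (is.null(best) || obj < best$obj) best <- list(labels = labels,
                                                      obj = obj)
  }
  best
}

#' Cluster labels at a tree level
#'
#' @param tree A `segmentation_tree`.
#' @param level Cut level; `NULL` (default) returns the final leaves.
#' @return Integer vector of cluster ids, one per feature-matrix row.
#' @export
leaf_labels <- function(tree, level = NULL) {
  stopifnot(inherits(tree, "segmentation_tree"))
  labels <- integer(tree$n_rows)
  walk <- function(id) {
    nd <- tree$nodes[[id]]
    stop_here <- is.null(nd$children) || !length(nd$children) ||
      (!is.null(level) && nd$level >= level)
    if (stop_here) labels[nd$rows] <<- id
    else for (ch in nd$children) walk(ch)
  }
  walk(1L)
  match(labels, sort(unique(labels)))
}

#' Newick text rendering of a segmentation tree
#'
#' Leaves are labelled `n<id>_<size>`, branch lengths are the split levels.
#'
#' @param tree A `segmentation_tree`.
#' @return A single Newick string.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "segmentation_tree"))
  render <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$children) || !length(nd$children))
      sprintf("n%d_%d:%d", nd$id, length(nd$rows), nd$level)
    else sprintf("(%s):%d",
                 paste(vapply(nd$children, render, ""), collapse = ","),
                 nd$level)
  }
  paste0(render(1L), ";")
}

#' @export
print.segmentation_tree <- function(x, ...) {
  leaves <- Filter(function(nd) is.null(nd$children) || !length(nd$children),
                   x$nodes)
  cat(sprintf("<segmentation_tree> %d rows, %d nodes, %d leaves (max level %d)\n",
              x$n_rows, length(x$nodes), length(leaves),
              max(vapply(x$nodes, `[[`, integer(1L), "level"))))
  for (nd in leaves)
    cat(sprintf("  leaf n%d: %d rows, level %d, wss %.3f\n", nd$id,
                length(nd$rows), nd$level, nd$wss))
  invisible(x)
}

#' PCA scores with unit-variance scaling
#'
#' Columns are centred and scaled to unit variance (zero-variance columns
#' are dropped with a warning); scores are the projections onto the leading
#' eigenvectors of the correlation matrix. Explained-variance fractions are
#' non-increasing and sum to at most one.
#'
#' @param features A `feature_matrix` or numeric matrix (rows =
#'   observations).
#' @param n_components Number of components (reduced with a warning when it
#'   exceeds the matrix rank).
#' @return A list of class `msi_pca`: `scores` (rows x components),
#'   `explained_variance` (fractions), `loadings`, `dropped_columns`.
#' @export
pca_scores <- function(features, n_components = 5) {
  X <- unclass(features)
  if (!is.matrix(X)) stopf("features must be a matrix")
  if (!is_count(n_components)) stopf("n_components must be a positive integer")
  if (nrow(X) < n_components)
    stopf("n_components (%d) exceeds the number of rows (%d)",
          n_components, nrow(X))
  sds <- apply(X, 2L, stats::sd)
  dropped <- which(sds == 0)
  if (length(dropped)) {
    warnf("dropping %d zero-variance column(s) before scaling",
          length(dropped))
    X <- X[, -dropped, drop = FALSE]
  }
  if (!ncol(X)) stopf("no columns with positive variance")
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-10)
  k <- n_components
  if (k > rank) {
    warnf("n_components reduced from %d to the matrix rank %d", k, rank)
    k <- rank
  }
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 explained_variance =
                   (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 dropped_columns = dropped),
            class = "msi_pca")
}

#' @export
print.msi_pca <- function(x, ...) {
  cat(sprintf("<msi_pca> %d observations, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}
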