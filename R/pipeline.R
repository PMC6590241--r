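# Configuration, pipeline commands and report rendering.
#
# One flat config carries every tunable default of the package; a run's
# effective config is embedded verbatim in every report so results are
# self-describing. A single master seed drives all stages: stage seeds are
# derived with derive_seed(master, stage_counter), documented counters
# 1 = simulation, 2 = spectrum sampling, 3 = bootstrap, 4 = segmentation.

msiqc_defaults <- function() list(
  # ion images & resolution score
  red_mz = 944.6, green_mz = 1105.6, mz_tol = 0.25, reducer = "sum",
  low_pct = 3, high_pct = 97, ratio = 0.70, rescale_after_clip = TRUE,
  min_signal_fraction = 0, tic_norm = TRUE, mask_quantile = 0.2,
  # peak picking
  min_snr_pick = 1, max_peaks = 10000, noise_window = 50, merge_tol = 0.1,
  snap = TRUE, envelope_tol = 0.1,
  # spectral quality
  n_sample = 100, n_boot = 1000, level = 0.95, snr_threshold = 3,
  mz_cutoffs = c(1500, 2000),
  # intensity CV
  cv_min_snr = 3, cv_tol = 0.25,
  # segmentation
  min_snr_features = 3, align_tol = 0.3, bin_tol = 0.25, denoise_window = 3,
  depth = 4, n_init = 10,
  # I/O and reproducibility
  seed = 1, out_dir = NULL, imzml = NULL, mask = NULL, avg_spectra = NULL,
  targets = NULL, phantom = list(), intensity_dtype = "float32")

#' Build a validated run configuration
#'
#' Starts from the package defaults (every default named across the module
#' documentation) and overrides the given keys. Unknown keys are a usage
#' error listing the offending names.
#'
#' @param ... Named overrides, or a single named list.
#' @return A named list of class `msiqc_config`.
#' @export
msiqc_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  cfg <- msiqc_defaults()
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stopf("config overrides must be named")
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "msiqc_config")
}

#' Load a configuration file
#'
#' YAML or JSON, chosen by extension; keys mirror [msiqc_config()].
#'
#' @param path Config file path.
#' @return A validated `msiqc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else tryCatch(yaml::read_yaml(path),
                error = function(e) stopf("cannot parse %s: %s", path,
                                          conditionMessage(e)))
  if (!is.list(raw)) stopf("config file %s does not contain a mapping", path)
  msiqc_config(raw)
}

resolve_dataset <- function(cfg) {
  if (inherits(cfg$imzml, "msi_dataset")) return(cfg$imzml)
  if (is.character(cfg$imzml)) return(read_imzml(cfg$imzml))
  stopf("config key 'imzml' must be a path or an msi_dataset")
}

resolve_mask <- function(cfg, dataset) {
  m <- cfg$mask
  if (is.null(m)) return(mask_from_tic(dataset, cfg$mask_quantile))
  if (inherits(m, "tissue_mask")) {
    validate_mask_dims(m, dataset); return(m)
  }
  if (is.character(m)) {
    mk <- read_mask(m); validate_mask_dims(mk, dataset); return(mk)
  }
  stopf("config key 'mask' must be a path or a tissue_mask")
}

input_checksums <- function(cfg) {
  paths <- Filter(function(p) is.character(p) && file.exists(p),
                  c(cfg["imzml"], cfg["mask"],
                    as.list(unlist(cfg$avg_spectra))))
  if (!length(paths)) return(NULL)
  paths <- unlist(paths, use.names = FALSE)
  stats::setNames(as.vector(tools::md5sum(paths)), basename(paths))
}

serializable_config <- function(cfg) {
  ser <- function(v) {
    if (is.null(v)) return(v)
    if (is.atomic(v) && is.null(oldClass(v))) return(v)
    if (is.data.frame(v)) return(v)
    if (is.list(v) && is.null(oldClass(v))) return(lapply(v, ser))
    sprintf("<in-memory %s>", class(v)[1L])
  }
  lapply(unclass(cfg), ser)
}

#' Run a pipeline command
#'
#' Ties the modules together behind one entry point used by both the
#' `msiqc` command-line script and programmatic callers. Outputs are
#' deterministic given the config seed; when `out_dir` is set, a JSON
#' report (inputs' checksums, effective config, package version, metrics),
#' a Markdown summary and command-specific artifacts are written there.
#'
#' @param command One of `"simulate"`, `"score-resolution"`, `"quality"`,
#'   `"cv"`, `"segment"`.
#' @param config A [msiqc_config()] (or named list of overrides).
#' @return The report list, invisibly for commands with file output.
#' @export
run_pipeline <- function(command = c("simulate", "score-resolution",
                                     "quality", "cv", "segment"),
                         config = msiqc_config()) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "msiqc_config")) config else msiqc_config(config)
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)

  report <- list(command = command,
                 package = "msiqc",
                 version = as.character(utils::packageVersion("msiqc")),
                 config = serializable_config(cfg),
                 inputs = input_checksums(cfg))

  if (command == "simulate") {
    spec <- do.call(phantom_spec, c(cfg$phantom,
                                    if (is.null(cfg$phantom$seed))
                                      list(seed = derive_seed(cfg$seed, 1L))))
    ph <- generate_phantom(spec)
    files <- NULL
    if (!is.null(out)) {
      files <- c(imzml = file.path(out, "phantom.imzML"),
                 mask = file.path(out, "mask.png"),
                 mask_rle = file.path(out, "mask.rle"))
      write_imzml(ph$dataset, files[["imzml"]],
                  intensity_dtype = cfg$intensity_dtype)
      write_mask(ph$truth$mask, files[["mask"]])
      write_mask(ph$truth$mask, files[["mask_rle"]])
    }
    report$metrics <- list(n_pixels = n_pixels(ph$dataset),
                           n_on_tissue = sum(ph$truth$mask$grid),
                           seed = spec$seed)
    finish_report(report, out)
    return(invisible(c(ph, list(report = report, files = files))))
  }

  if (command == "score-resolution") {
    ds <- resolve_dataset(cfg)
    mask <- resolve_mask(cfg, ds)
    res <- spatial_resolution_score(
      ds, mask, red_mz = cfg$red_mz, green_mz = cfg$green_mz,
      mz_tol = cfg$mz_tol, low_pct = cfg$low_pct, high_pct = cfg$high_pct,
      ratio = cfg$ratio, reducer = cfg$reducer, tic_norm = cfg$tic_norm,
      rescale_after_clip = cfg$rescale_after_clip,
      min_signal_fraction = cfg$min_signal_fraction,
      mask_quantile = cfg$mask_quantile)
    report$metrics <- list(score_percent = res$score_percent,
                           n_red = res$counts[["RED"]],
                           n_green = res$counts[["GREEN"]],
                           n_yellow = res$counts[["YELLOW"]])
    if (!is.null(out))
      write_label_png(res, file.path(out, "mixed_pixels.png"))
    finish_report(report, out)
    return(invisible(list(result = res, report = report)))
  }

  if (command == "quality") {
    ds <- resolve_dataset(cfg)
    mask <- resolve_mask(cfg, ds)
    spectra <- sample_spectra(ds, mask, n = cfg$n_sample,
                              seed = derive_seed(cfg$seed, 2L))
    peaklists <- lapply(spectra, pick_peaks, min_snr = cfg$min_snr_pick,
                        max_peaks = cfg$max_peaks,
                        noise_window = cfg$noise_window,
                        merge_tol = cfg$merge_tol, snap = cfg$snap,
                        envelope_tol = cfg$envelope_tol)
    rep_q <- quality_metrics(peaklists, snr_threshold = cfg$snr_threshold,
                             mz_cutoffs = cfg$mz_cutoffs,
                             n_boot = cfg$n_boot, level = cfg$level,
                             seed = derive_seed(cfg$seed, 3L))
    report$metrics <- list(n_sampled = rep_q$n_sampled,
                           metrics = rep_q$metrics)
    if (!is.null(out)) {
      write_peaklist_csv(peaklists, file.path(out, "peaklist.csv"))
      utils::write.csv(rep_q$metrics, file.path(out, "quality_metrics.csv"),
                       row.names = FALSE)
    }
    finish_report(report, out)
    return(invisible(list(result = rep_q, report = report)))
  }

  if (command == "cv") {
    spectra <- cfg$avg_spectra
    if (is.null(spectra)) stopf("config key 'avg_spectra' is required for cv")
    if (is.character(spectra)) spectra <- lapply(spectra, read_spectrum_csv)
    targets <- cfg$targets
    if (is.character(targets))
      targets <- utils::read.csv(targets)$target_mz
    if (!is.numeric(targets)) stopf("config key 'targets' must give m/z values")
    tab <- intensity_cv(spectra, targets, tol = cfg$cv_tol,
                        min_snr = cfg$cv_min_snr)
    report$metrics <- list(cv_table = as.data.frame(tab),
                           median_cv_percent =
                             stats::median(tab$cv_percent, na.rm = TRUE))
    if (!is.null(out))
      utils::write.csv(as.data.frame(tab), file.path(out, "intensity_cv.csv"),
                       row.names = FALSE)
    finish_report(report, out)
    return(invisible(list(result = tab, report = report)))
  }

  # segment
  ds_in <- cfg$imzml
  if (inherits(ds_in, "msi_dataset")) ds_in <- list(ds_in)
  if (is.character(ds_in)) ds_in <- lapply(ds_in, read_imzml)
  if (!is.list(ds_in)) stopf("config key 'imzml' must name >= 1 dataset")
  masks <- cfg$mask
  if (inherits(masks, "tissue_mask")) masks <- list(masks)
  if (is.character(masks)) masks <- lapply(masks, read_mask)
  if (is.null(masks))
    masks <- lapply(ds_in, mask_from_tic, quantile_threshold =
                      cfg$mask_quantile)
  fm <- build_feature_matrix(ds_in, masks, min_snr = cfg$min_snr_features,
                             align_tol = cfg$align_tol, bin_tol = cfg$bin_tol,
                             denoise_window = cfg$denoise_window)
  tree <- bisecting_kmeans(fm, max_depth = cfg$depth,
                           seed = derive_seed(cfg$seed, 4L),
                           n_init = cfg$n_init)
  labels <- leaf_labels(tree)
  report$metrics <- list(n_rows = tree$n_rows,
                         n_features = length(tree$mz),
                         consensus_mz = tree$mz,
                         n_leaves = length(unique(labels)),
                         newick = as_newick(tree))
  if (!is.null(out)) {
    writeLines(as_newick(tree), file.path(out, "tree.nwk"))
    for (lev in seq_len(cfg$depth)) {
      lab <- leaf_labels(tree, lev)
      png_path <- file.path(out, sprintf("labels_level%d.png", lev))
      write_label_raster(tree, lab, png_path)
      if (max(lab) == max(leaf_labels(tree))) break
    }
  }
  finish_report(report, out)
  invisible(list(feature_matrix = fm, tree = tree, labels = labels,
                 report = report))
}

# Cluster-label raster PNG over the first dataset's grid.
write_label_raster <- function(tree, labels, path) {
  px <- tree$pixels
  first <- px$dataset == px$dataset[1L]
  nr <- max(px$row[first]) + 1L
  nc <- max(px$col[first]) + 1L
  img <- array(0, dim = c(nr, nc, 3L))
  pal <- grDevices::col2rgb(grDevices::hcl.colors(max(labels), "Dark 3")) / 255
  at <- cbind(px$row[first] + 1L, px$col[first] + 1L)
  for (ch in 1:3)
    img[cbind(at, ch)] <- pal[ch, labels[first]]
  png::writePNG(img, path)
  invisible(path)
}

read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stopf("spectrum file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(df)))
    stopf("%s must have columns mz, intensity", path)
  mass_spectrum(df$mz, df$intensity)
}

finish_report <- function(report, out) {
  if (is.null(out)) return(invisible(report))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  md <- c(sprintf("# msiqc %s report", report$command), "",
          sprintf("Package version %s.", report$version), "",
          "## Metrics", "",
          utils::capture.output(utils::str(report$metrics, give.attr = FALSE)))
  writeLines(md, file.path(out, "summary.md"))
  invisible(report)
}
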