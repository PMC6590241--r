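# imzML 1.1 input/output.
#
# An imzML dataset is an XML index (.imzML) plus a binary companion (.ibd)
# holding the arrays: 16 bytes of UUID, then little-endian IEEE arrays at the
# byte offsets recorded per spectrum in the XML. Continuous mode stores the
# shared m/z axis once (every spectrum's mz array points at the same offset);
# processed mode stores one mz + intensity pair per spectrum. imzML pixel
# coordinates are 1-based and are converted to the package's 0-based
# convention here, at the I/O boundary.

IMZML_NS <- "http://psi.hupo.org/ms/mzml"

ibd_path <- function(path) {
  base <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  for (ext in c(".ibd", ".IBD")) {
    cand <- paste0(base, ext)
    if (file.exists(cand)) return(cand)
  }
  paste0(base, ".ibd")
}

dtype_size <- function(dtype) c(float32 = 4L, float64 = 8L)[[dtype]]

#' Write a dataset as an imzML + ibd file pair
#'
#' Produces a standard-conformant imzML 1.1 file readable by independent
#' parsers. m/z values are stored as 64-bit floats; intensities default to
#' 32-bit floats (the common MSI convention) but can be widened to 64-bit
#' when an exact binary round trip is required.
#'
#' @param dataset An [msi_dataset()].
#' @param path Output `.imzML` path; the `.ibd` companion is written next to
#'   it.
#' @param intensity_dtype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path,
                        intensity_dtype = c("float32", "float64")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  intensity_dtype <- match.arg(intensity_dtype)
  if (n_pixels(dataset) < 1L) stopf("refusing to write a dataset with zero pixels")
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)

  np <- n_pixels(dataset)
  isz <- dtype_size(intensity_dtype)
  uuid <- dataset_uuid(dataset)

  # layout of the ibd file
  if (dataset$mode == "continuous") {
    nmz <- length(dataset$mz_axis)
    mz_off <- rep(16, np)
    mz_len <- rep(nmz, np)
    int_len <- rep(nmz, np)
    int_off <- 16 + nmz * 8 + (seq_len(np) - 1) * nmz * isz
  } else {
    lens <- vapply(dataset$spectra, function(s) length(s$mz), integer(1L))
    mz_len <- lens
    int_len <- lens
    rec <- lens * (8 + isz)
    starts <- 16 + c(0, cumsum(rec))[seq_len(np)]
    mz_off <- starts
    int_off <- starts + lens * 8
  }

  ibd <- ibd_path(path)
  con <- tryCatch(file(ibd, "wb"),
                  error = function(e) stopf("cannot write %s: %s", ibd,
                                            conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  if (dataset$mode == "continuous") {
    writeBin(dataset$mz_axis, con, size = 8L, endian = "little")
    for (i in seq_len(np))
      writeBin(dataset$intensities[, i], con, size = isz, endian = "little")
  } else {
    for (i in seq_len(np)) {
      writeBin(dataset$spectra[[i]]$mz, con, size = 8L, endian = "little")
      writeBin(dataset$spectra[[i]]$intensity, con, size = isz,
               endian = "little")
    }
  }

  xml <- imzml_xml(dataset, uuid, intensity_dtype,
                   mz_off, mz_len, int_off, int_len, isz)
  out <- tryCatch(file(path, "wb"),
                  error = function(e) stopf("cannot write %s: %s", path,
                                            conditionMessage(e)))
  on.exit(close(out), add = TRUE)
  writeLines(xml, out, sep = "\n")
  invisible(path)
}

# Deterministic 16-byte identifier derived from dataset shape and content
# summaries, so identical datasets produce identical files.
dataset_uuid <- function(dataset) {
  tics <- pixel_tic(dataset)
  key <- c(n_pixels(dataset), dataset$n_cols, dataset$n_rows,
           dataset$mz_range, sum(tics), if (length(tics)) tics[1L] else 0)
  raw16 <- serialize(signif(key, 12), connection = NULL)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw16, tf)
  md5 <- tools::md5sum(tf)[[1L]]
  as.raw(strtoi(substring(md5, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

uuid_string <- function(uuid) {
  h <- paste(format(uuid), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(h, 1, 8), substr(h, 9, 12),
          substr(h, 13, 16), substr(h, 17, 20), substr(h, 21, 32))
}

cvp <- function(ref, acc, name, value = "") {
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
          ref, acc, name, value)
}

imzml_xml <- function(dataset, uuid, intensity_dtype,
                      mz_off, mz_len, int_off, int_len, isz) {
  np <- n_pixels(dataset)
  mode_cv <- if (dataset$mode == "continuous")
    cvp("IMS", "IMS:1000030", "continuous")
  else cvp("IMS", "IMS:1000031", "processed")
  int_dtype_cv <- if (intensity_dtype == "float32")
    cvp("MS", "MS:1000521", "32-bit float")
  else cvp("MS", "MS:1000523", "64-bit float")

  head <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    sprintf('<mzML xmlns="%s" version="1.1">', IMZML_NS),
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="1.3.1" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" version="1.15" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" version="0.9.1" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription>',
    '<fileContent>',
    cvp("MS", "MS:1000579", "MS1 spectrum"),
    mode_cv,
    cvp("IMS", "IMS:1000080", "universally unique identifier",
        uuid_string(uuid)),
    '</fileContent>',
    '</fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    cvp("MS", "MS:1000523", "64-bit float"),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cvp("MS", "MS:1000515", "intensity array"),
    int_dtype_cv,
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1">',
    '<software id="msiqc" version="0.1.0"/>',
    '</softwareList>',
    '<scanSettingsList count="1">',
    '<scanSettings id="scansettings1">',
    cvp("IMS", "IMS:1000042", "max count of pixels x", dataset$n_cols),
    cvp("IMS", "IMS:1000043", "max count of pixels y", dataset$n_rows),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>',
            dataset$pixel_size_um),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>',
            dataset$pixel_size_um),
    '</scanSettings>',
    '</scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1">',
    '<dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="msiqc">',
    cvp("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod>',
    '</dataProcessing>',
    '</dataProcessingList>',
    '<run defaultInstrumentConfigurationRef="IC1" id="run1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">', np))

  # spectrum blocks, vectorized over pixels
  i <- seq_len(np)
  spectra <- sprintf(paste0(
    '<spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">',
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan>',
    '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
    '</scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="mzArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '<binary/></binaryDataArray>',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="intensityArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '<binary/></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    i, mz_len, i - 1L,
    dataset$coords[, 1L] + 1L, dataset$coords[, 2L] + 1L,
    mz_len, mz_len * 8, mz_off,
    int_len, int_len * isz, int_off)

  c(head, spectra, '</spectrumList>', '</run>', '</mzML>')
}

#' Read an imzML + ibd file pair
#'
#' Supports continuous and processed binary modes with 32- or 64-bit float
#' arrays, no compression. Grid extents are inferred from the maximum pixel
#' coordinates (1-based in the file, converted to 0-based internally).
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stopf("imzML file not found: %s", path)
  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stopf("ibd companion not found: %s", ibd)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("cannot parse %s: %s", path,
                                            conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  accs <- function(node, xpath) xml2::xml_attr(xml2::xml_find_all(node, xpath),
                                               "accession")
  fc_acc <- accs(doc, ".//fileDescription/fileContent/cvParam")
  mode <- if ("IMS:1000030" %in% fc_acc) "continuous"
          else if ("IMS:1000031" %in% fc_acc) "processed"
          else stopf("%s declares neither continuous nor processed mode", path)

  # dtype of each referenceable array group
  group_dtype <- function(id) {
    g <- xml2::xml_find_first(doc, sprintf(
      ".//referenceableParamGroup[@id='%s']", id))
    if (is.na(g)) stopf("%s lacks referenceableParamGroup '%s'", path, id)
    a <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
    if ("MS:1000523" %in% a) "float64"
    else if ("MS:1000521" %in% a) "float32"
    else stopf("unsupported binary data type in group '%s'", id)
  }
  mz_dtype <- group_dtype("mzArray")
  int_dtype <- group_dtype("intensityArray")

  px_size <- xml2::xml_attr(xml2::xml_find_first(
    doc, ".//scanSettings/cvParam[@accession='IMS:1000046']"), "value")
  px_size <- if (is.na(px_size)) 50 else as.double(px_size)

  sp_nodes <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (!length(sp_nodes)) stopf("no spectra in %s", path)

  # per-spectrum positions and array index entries
  get_vals <- function(xpath) {
    v <- xml2::xml_attr(xml2::xml_find_all(doc, xpath), "value")
    as.double(v)
  }
  pos_x <- get_vals(".//run/spectrumList/spectrum/scanList/scan/cvParam[@accession='IMS:1000050']")
  pos_y <- get_vals(".//run/spectrumList/spectrum/scanList/scan/cvParam[@accession='IMS:1000051']")
  np <- length(sp_nodes)
  if (length(pos_x) != np || length(pos_y) != np)
    stopf("missing pixel positions in %s", path)

  arr_info <- function(group) {
    base <- sprintf(
      ".//run/spectrumList/spectrum/binaryDataArrayList/binaryDataArray[referenceableParamGroupRef/@ref='%s']",
      group)
    list(
      len = get_vals(paste0(base, "/cvParam[@accession='IMS:1000103']")),
      off = get_vals(paste0(base, "/cvParam[@accession='IMS:1000102']")))
  }
  mzi <- arr_info("mzArray")
  ini <- arr_info("intensityArray")
  if (length(mzi$len) != np || length(ini$len) != np)
    stopf("missing binary array index entries in %s", path)

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_arr <- function(off, n, dtype) {
    seek(con, where = off, origin = "start")
    readBin(con, "double", n = n, size = dtype_size(dtype), endian = "little")
  }

  coords <- cbind(col = as.integer(pos_x) - 1L, row = as.integer(pos_y) - 1L)
  check_axis <- function(mz, i) {
    if (length(mz) > 1L && any(diff(mz) <= 0))
      stopf("non-monotone m/z axis in spectrum at pixel (%d,%d)",
            coords[i, 1L], coords[i, 2L])
  }

  if (mode == "continuous") {
    mz <- read_arr(mzi$off[1L], mzi$len[1L], mz_dtype)
    check_axis(mz, 1L)
    ints <- matrix(0, nrow = length(mz), ncol = np)
    for (i in seq_len(np))
      ints[, i] <- read_arr(ini$off[i], ini$len[i], int_dtype)
    if (any(ints < 0)) stopf("negative intensities in %s", ibd)
    new_msi_dataset(mode = "continuous", mz_axis = mz, intensities = ints,
                    spectra = NULL, coords = coords,
                    n_cols = max(coords[, 1L]) + 1L,
                    n_rows = max(coords[, 2L]) + 1L,
                    pixel_size_um = px_size, mz_range = range(mz))
  } else {
    spectra <- vector("list", np)
    for (i in seq_len(np)) {
      mz <- read_arr(mzi$off[i], mzi$len[i], mz_dtype)
      check_axis(mz, i)
      spectra[[i]] <- mass_spectrum(mz, read_arr(ini$off[i], ini$len[i],
                                                 int_dtype), coords[i, ])
    }
    mz_range <- range(vapply(spectra, function(s) range(s$mz), numeric(2L)))
    new_msi_dataset(mode = "processed", mz_axis = NULL, intensities = NULL,
                    spectra = spectra, coords = coords,
                    n_cols = max(coords[, 1L]) + 1L,
                    n_rows = max(coords[, 2L]) + 1L,
                    pixel_size_um = px_size, mz_range = mz_range)
  }
}
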