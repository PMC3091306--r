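#' Scans and acquisitions
#'
#' A `scan` is one short individual spectrum: a peak list (m/z ascending,
#' intensities >= 0) plus MS level, polarity and -- for MS2 scans -- the
#' recorded precursor m/z. An `acquisition` is the ordered set of scans from
#' one direct infusion of a sample.
#'
#' @param mz,intensity numeric peak vectors (same length).
#' @param ms_level 1 or 2.
#' @param polarity `"+"` or `"-"`.
#' @param precursor_mz recorded precursor m/z (required for MS2 scans).
#' @param index scan index within the acquisition.
#' @return an object of class `scan`.
#' @export
scan <- function(mz, intensity, ms_level = 1L, polarity = "+",
                 precursor_mz = NULL, index = NA_integer_) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) == 0L) stop("empty scan")
  if (any(intensity < 0)) stop("negative intensity")
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (!polarity %in% c("+", "-")) stop("polarity must be '+' or '-'")
  if (ms_level == 2L && is.null(precursor_mz))
    stop("MS2 scan requires a precursor_mz")
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 ms_level = as.integer(ms_level), polarity = polarity,
                 precursor_mz = if (is.null(precursor_mz)) NA_real_ else as.numeric(precursor_mz),
                 index = as.integer(index)),
            class = "scan")
}

#' @rdname scan
#' @param id acquisition identifier.
#' @param scans list of `scan` objects.
#' @param source path of the file the acquisition was read from, if any.
#' @param metadata free-form named list (instrument etc.).
#' @export
acquisition <- function(id, scans, source = NA_character_, metadata = list()) {
  if (length(scans) == 0L) stop("acquisition must contain at least one scan")
  stopifnot(all(vapply(scans, inherits, logical(1), "scan")))
  structure(list(id = as.character(id), scans = scans, source = source,
                 metadata = metadata),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  lv <- vapply(x$scans, function(s) s$ms_level, integer(1))
  cat(sprintf("<acquisition> %s: %d scans (%d MS1, %d MS2), polarity %s\n",
              x$id, length(x$scans), sum(lv == 1L), sum(lv == 2L),
              paste(unique(vapply(x$scans, function(s) s$polarity, character(1))),
                    collapse = "/")))
  invisible(x)
}

#' Split an acquisition by scan polarity
#'
#' Files that interleave positive and negative scans are split into one
#' logical acquisition per polarity (suffix `+`/`-`) rather than rejected;
#' downstream alignment requires a single polarity.
#' @param acq an `acquisition`.
#' @return list of single-polarity acquisitions.
#' @export
split_polarity <- function(acq) {
  pol <- vapply(acq$scans, function(s) s$polarity, character(1))
  if (length(unique(pol)) == 1L) return(list(acq))
  lapply(unique(pol), function(p)
    acquisition(paste0(acq$id, p), acq$scans[pol == p], acq$source, acq$metadata))
}

.decode_peaks <- function(b64, precision, compression = "none",
                          byte_order = "network") {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (compression %in% c("zlib", "gzip")) raw <- memDecompress(raw, type = "gzip")
  else if (compression != "none") stop("unsupported peaks compression: ", compression)
  size <- if (as.integer(precision) == 64L) 8L else 4L
  endian <- if (byte_order %in% c("network", "big")) "big" else "little"
  vals <- readBin(raw, "double", n = length(raw) %/% size, size = size, endian = endian)
  if (length(vals) %% 2L != 0L) stop("odd number of decoded peak values")
  list(mz = vals[seq(1L, length(vals), by = 2L)],
       intensity = vals[seq(2L, length(vals), by = 2L)])
}

#' Read an mzXML acquisition
#'
#' Supports the subset written by the common raw-file converters: centroided
#' scans, 32/64-bit network-byte-order peak arrays, uncompressed or zlib.
#' MS2 scans must carry a `precursorMz` element.
#'
#' @param path mzXML file.
#' @param id acquisition identifier (defaults to the file name).
#' @return an `acquisition` (or list of them if polarities are mixed and
#'   `split = TRUE`).
#' @param split split mixed-polarity files into one acquisition per polarity.
#' @export
read_mzxml <- function(path, id = NULL, split = FALSE) {
  doc <- xml2::read_xml(path)
  ns <- tryCatch(xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "mz"),
                 error = function(e) character(0))
  scans_xml <- if (length(ns)) xml2::xml_find_all(doc, ".//mz:scan", ns)
               else xml2::xml_find_all(doc, "//scan")
  if (length(scans_xml) == 0L) scans_xml <- xml2::xml_find_all(doc, "//scan")
  if (length(scans_xml) == 0L) stop("no scans found in ", path)
  scans <- lapply(seq_along(scans_xml), function(i) {
    sx <- scans_xml[[i]]
    lvl <- xml2::xml_attr(sx, "msLevel")
    if (is.na(lvl)) stop("scan without msLevel in ", path)
    pol <- xml2::xml_attr(sx, "polarity")
    if (is.na(pol)) pol <- "+"
    peaks_xml <- if (length(ns)) xml2::xml_find_first(sx, "./mz:peaks", ns)
                 else xml2::xml_find_first(sx, "./peaks")
    if (inherits(peaks_xml, "xml_missing")) peaks_xml <- xml2::xml_find_first(sx, "./peaks")
    comp <- xml2::xml_attr(peaks_xml, "compressionType")
    pk <- .decode_peaks(xml2::xml_text(peaks_xml),
                        precision = xml2::xml_attr(peaks_xml, "precision"),
                        compression = if (is.na(comp)) "none" else comp,
                        byte_order = xml2::xml_attr(peaks_xml, "byteOrder"))
    prec <- NULL
    if (as.integer(lvl) == 2L) {
      px <- if (length(ns)) xml2::xml_find_first(sx, "./mz:precursorMz", ns)
            else xml2::xml_find_first(sx, "./precursorMz")
      if (inherits(px, "xml_missing")) px <- xml2::xml_find_first(sx, "./precursorMz")
      if (inherits(px, "xml_missing")) stop("MS2 scan without precursorMz in ", path)
      prec <- as.numeric(xml2::xml_text(px))
    }
    scan(pk$mz, pk$intensity, ms_level = as.integer(lvl), polarity = pol,
         precursor_mz = prec, index = i)
  })
  acq <- acquisition(if (is.null(id)) basename(path) else id, scans, source = path)
  if (split) split_polarity(acq) else acq
}

#' Read a two-column peak-list file
#'
#' Plain-text peak lists (`*.dta` / `*.csv` style): two numeric columns, m/z
#' and intensity, separated by whitespace, comma or tab; lines starting with
#' `#` are ignored. Peaks are sorted by m/z on input.
#'
#' @param path file path.
#' @inheritParams scan
#' @return a `scan`.
#' @export
read_peaklist <- function(path, ms_level = 1L, polarity = "+",
                          precursor_mz = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no peaks in ", path)
  parts <- strsplit(lines, "[,\t ]+")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) stop("peak-list row with fewer than 2 columns: '",
                     lines[which(bad)[1]], "'")
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(mz) || anyNA(it))
    stop("non-numeric value in peak list row: '", lines[which(is.na(mz) | is.na(it))[1]], "'")
  scan(mz, it, ms_level = ms_level, polarity = polarity, precursor_mz = precursor_mz)
}

#' Dataset manifests
#'
#' A manifest lists the acquisition files of an experiment and optional
#' named groups (samples, blanks, replicates). Flat INI-style text:
#' \preformatted{
#' [files]
#' a = path/to/a.mzXML
#' [groups]
#' sample = a
#' }
#' Identifiers must be unique; without a `[groups]` section all acquisitions
#' form the implicit group `"all"`.
#'
#' @param path manifest file.
#' @param base_dir directory file paths are resolved against (defaults to the
#'   manifest's own directory).
#' @return list with `files` (named character vector id -> path) and
#'   `groups` (named list of id vectors), class `dataset_manifest`.
#' @export
load_manifest <- function(path, base_dir = dirname(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ";")]
  section <- ""
  files <- character(); groups <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- tolower(gsub("\\[|\\]", "", ln)); next }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("malformed manifest line: '", ln, "'")
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (section == "files") {
      if (key %in% names(files)) stop("duplicate acquisition identifier: ", key)
      p <- if (file.exists(val)) val else file.path(base_dir, val)
      if (!file.exists(p)) stop("missing acquisition file: ", val)
      files[key] <- p
    } else if (section == "groups") {
      ids <- trimws(strsplit(val, ",")[[1]])
      groups[[key]] <- ids
    }
  }
  if (length(files) == 0L) stop("manifest lists no files")
  for (g in names(groups)) {
    miss <- setdiff(groups[[g]], names(files))
    if (length(miss) > 0L)
      stop("group '", g, "' refers to unknown acquisition(s): ",
           paste(miss, collapse = ", "))
  }
  if (length(groups) == 0L) groups <- list(all = names(files))
  structure(list(files = files, groups = groups), class = "dataset_manifest")
}

#' Read all acquisitions listed in a manifest
#' @param manifest a `dataset_manifest` (see [load_manifest()]).
#' @return list of `acquisition` objects in manifest order.
#' @export
read_manifest_acquisitions <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  mapply(function(id, p) read_mzxml(p, id = id),
         names(manifest$files), manifest$files, SIMPLIFY = FALSE)
}
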