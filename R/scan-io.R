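#' Write a scan image as a 16-bit RGB TIFF
#'
#' Channels are written uncompressed at 16 bits per sample, exactly as
#' stored (no colour transformation). Pixel spacing and timestamp are
#' carried by the series manifest (see [write_series()]); readers of a
#' bare TIFF fall back to the 72-DPI default spacing.
#'
#' @param image A [scan_image()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_scan <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  arr <- array(0, dim = c(dim(image$red), 3L))
  arr[, , 1] <- image$red
  arr[, , 2] <- image$green
  arr[, , 3] <- image$blue
  tiff::writeTIFF(arr / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a film scan from TIFF
#'
#' Accepts RGB TIFFs at 8 or 16 bits per sample; 8-bit values are
#' up-scaled to the 16-bit range (255 maps to 65535, i.e. x257). Pixel
#' spacing is taken from the TIFF resolution tags when present, else the
#' 72-DPI default (25.4/72 mm) is assumed. No colour correction is
#' applied.
#'
#' @param path TIFF file path.
#' @param t_post Minutes postirradiation to stamp on the scan (the TIFF
#'   itself carries no timestamp).
#' @param pixel_spacing Override spacing in mm/px; `NULL` (default) means
#'   use resolution tags or the 72-DPI default.
#' @return A [scan_image()].
#' @export
read_scan <- function(path, t_post = NA_real_, pixel_spacing = NULL) {
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) {
                    stop(sprintf("cannot read TIFF '%s': %s",
                                 path, conditionMessage(e)))
                  })
  d <- dim(img)
  if (length(d) != 3L || d[3] < 3L) {
    stop(sprintf("'%s' is not an RGB image (need 3 samples per pixel)", path))
  }
  if (is.null(pixel_spacing)) {
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      pixel_spacing <- switch(if (is.null(unit)) "inch" else unit,
                              cm = 10 / xres,
                              25.4 / xres)
    } else {
      pixel_spacing <- 25.4 / 72
    }
  }
  # readTIFF normalises to [0,1]; x65535 restores 16-bit counts and maps
  # 8-bit v to v*257 exactly.
  chan <- function(k) matrix(round(img[, , k] * 65535), d[1], d[2])
  scan_image(red = chan(1), green = chan(2), blue = chan(3),
             pixel_spacing = pixel_spacing, t_post = t_post,
             source_path = path)
}

scan_filename <- function(t) sprintf("scan_t%05d.tif", as.integer(round(t)))

#' Write a scan series to a directory
#'
#' Writes one TIFF per scan (`scan_t00005.tif`, ...) plus a `series.json`
#' manifest recording the timestamps, interval, pixel spacing and any
#' extra metadata (seed, model parameters). Timestamps live redundantly in
#' the filenames; the manifest is authoritative.
#'
#' @param series A [scan_series()].
#' @param dir Output directory (created if missing).
#' @param metadata Named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_series <- function(series, dir, metadata = list()) {
  stopifnot(inherits(series, "scan_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  times <- series_times(series)
  files <- scan_filename(times)
  for (i in seq_along(series$scans)) {
    write_scan(series$scans[[i]], file.path(dir, files[i]))
  }
  manifest <- c(list(
    t_first = series$t_first,
    interval = series$interval,
    count = length(series$scans),
    times = times,
    files = files,
    pixel_spacing = series$scans[[1]]$pixel_spacing), metadata)
  mpath <- file.path(dir, "series.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Load a scan series from a directory or manifest
#'
#' If a `series.json` manifest is present it is authoritative for
#' timestamps and pixel spacing; otherwise timestamps are parsed from the
#' `scan_t<minutes>.tif` filenames. Scans are sorted by time regardless of
#' directory listing order, and the interval is verified constant.
#'
#' @param path Directory containing the scans, or the manifest path.
#' @return A [scan_series()].
#' @export
load_series <- function(path) {
  if (dir.exists(path)) {
    mpath <- file.path(path, "series.json")
    dir <- path
  } else {
    mpath <- path
    dir <- dirname(path)
  }
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    times <- as.numeric(man$times)
    files <- file.path(dir, man$files)
    spacing <- if (!is.null(man$pixel_spacing)) man$pixel_spacing else NULL
  } else {
    files <- list.files(dir, pattern = "^scan_t[0-9]+\\.tif$",
                        full.names = TRUE)
    if (!length(files)) {
      stop(sprintf("no series manifest and no scan_t*.tif files in '%s'", dir))
    }
    times <- as.numeric(sub("^scan_t([0-9]+)\\.tif$", "\\1", basename(files)))
    spacing <- NULL
  }
  if (length(times) != length(files) || any(is.na(times))) {
    stop("series manifest is inconsistent: missing or unparsable timestamps")
  }
  scans <- mapply(function(f, t) read_scan(f, t_post = t,
                                           pixel_spacing = spacing),
                  files, times, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  scan_series(scans)
}

#' Write a dose plane as a plain-text grid
#'
#' Format: comment header lines `# spacing_mm=<s>` and
#' `# origin_mm=<x>,<y>`, then one comma-separated row of Gy values per
#' image row. Values are written with nine significant digits, so a
#' round-trip is faithful well beyond the 1e-6 Gy level.
#'
#' @param plane A [dose_plane()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(plane, path) {
  stopifnot(inherits(plane, "dose_plane"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# spacing_mm=%.9g", plane$pixel_spacing),
    sprintf("# origin_mm=%.9g,%.9g", plane$origin[1], plane$origin[2])),
    con)
  writeLines(apply(plane$dose, 1, function(r)
    paste(sprintf("%.9g", r), collapse = ",")), con)
  invisible(path)
}

#' Read a plain-text dose grid
#'
#' @param path File written by [write_dose_grid()] (or hand-authored in
#'   the same format).
#' @return A [dose_plane()].
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  get_field <- function(key) {
    m <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(sprintf("^#\\s*%s=", key), "", m[1])
  }
  spacing <- get_field("spacing_mm")
  if (is.null(spacing)) stop(sprintf("'%s': missing '# spacing_mm=' header", path))
  spacing <- as.numeric(spacing)
  origin <- get_field("origin_mm")
  origin <- if (is.null(origin)) c(0, 0) else as.numeric(strsplit(origin, ",")[[1]])
  if (!length(body)) stop(sprintf("'%s': no dose rows", path))
  rows <- lapply(strsplit(body, ","), function(r) as.numeric(trimws(r)))
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("'%s': ragged rows (row lengths %s)", path,
                 paste(unique(ncols), collapse = ", ")))
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop(sprintf("'%s': non-numeric dose entries", path))
  if (any(m < 0)) stop(sprintf("'%s': negative dose entries rejected", path))
  dose_plane(m, pixel_spacing = spacing, origin = origin)
}
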