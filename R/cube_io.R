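#' @title Hyperspectral cube containers
#' @description
#' Cubes are stored in canonical in-memory order `rows x cols x bands`
#' (0 offsets never exposed; R indexing is 1-based).  `raw_cube` holds
#' detector counts, `reflectance_cube` holds unitless calibrated
#' reflectance plus the provenance of its raw/white/dark sources and a QC
#' mask of pixels whose flat-field denominator was degenerate.
#' @name cube-classes
NULL

new_raw_cube <- function(data, axis) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(axis, "spectral_axis"))
  if (dim(data)[3L] != axis$L) stop("band dimension does not match axis")
  if (any(data < 0)) stop("detector counts must be non-negative")
  structure(list(data = data, axis = axis), class = "raw_cube")
}

#' Construct a raw (counts) cube
#'
#' @param data 3-D numeric array, rows x cols x bands, non-negative counts.
#' @param axis A [spectral_axis()] whose length matches `dim(data)[3]`.
#' @return A `raw_cube` object.
#' @export
raw_cube <- function(data, axis) new_raw_cube(data, axis)

#' Construct a reflectance cube
#'
#' @param data 3-D numeric array of unitless reflectance.
#' @param axis A [spectral_axis()].
#' @param provenance Optional named list recording source identifiers.
#' @param qc_mask Optional logical rows x cols matrix flagging imputed
#'   pixels.
#' @return A `reflectance_cube` object.
#' @export
reflectance_cube <- function(data, axis, provenance = list(), qc_mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(axis, "spectral_axis"))
  if (dim(data)[3L] != axis$L) stop("band dimension does not match axis")
  if (!all(is.finite(data))) stop("reflectance must be finite everywhere")
  structure(list(data = data, axis = axis, provenance = provenance,
                 qc_mask = qc_mask),
            class = "reflectance_cube")
}

#' @export
print.raw_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_cube> %d x %d pixels, %d bands\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# ENVI-style header + flat binary I/O.
#
# Header: text "key = value" lines after a leading "ENVI" magic; wavelength
# list in braces.  Interleaves supported: bsq (band-sequential) and bil
# (band-interleaved-by-line).  Data types: 12 (uint16 little-endian) and 4
# (float32 little-endian), the two the acquisition systems emit.
# ---------------------------------------------------------------------------

parse_envi_header <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  get_field <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(
      paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\n{]+)$"), txt, perl = TRUE))[[1L]]
    if (length(m) < 2L) {
      if (required) stop("ENVI header missing field: ", key)
      return(NA_character_)
    }
    trimws(m[2L])
  }
  samples <- as.integer(get_field("samples"))
  lines_ <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  if (anyNA(c(samples, lines_, bands, dtype))) {
    stop("ENVI header has non-numeric samples/lines/bands/data type")
  }
  if (!interleave %in% c("bsq", "bil")) {
    stop("unsupported interleave: ", interleave)
  }
  wl_m <- regmatches(txt, regexec("(?si)wavelength\\s*=\\s*\\{([^}]*)\\}",
                                  txt, perl = TRUE))[[1L]]
  if (length(wl_m) < 2L) stop("ENVI header missing wavelength list")
  wl <- as.numeric(strsplit(wl_m[2L], "[,\\s]+")[[1L]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != bands) {
    stop(sprintf("wavelength count (%d) != bands (%d)", length(wl), bands))
  }
  list(samples = samples, lines = lines_, bands = bands,
       data_type = dtype, interleave = interleave, wavelengths = wl)
}

#' Read an ENVI-style hyperspectral cube
#'
#' Reads a flat little-endian binary cube described by a text header and
#' returns it in canonical `rows x cols x bands` order regardless of the
#' on-disk interleave (`bsq` or `bil`).  `lines` maps to rows (scan
#' frames), `samples` to cols (across-track).
#'
#' @param path Path to the binary cube file.
#' @param header_path Path to the text header; defaults to `<path>.hdr`.
#' @return A [raw_cube()] (counts are returned as stored; float cubes are
#'   allowed and used for calibrated products).
#' @export
read_cube <- function(path, header_path = paste0(path, ".hdr")) {
  h <- parse_envi_header(header_path)
  n <- h$samples * h$lines * h$bands
  what <- switch(as.character(h$data_type),
                 "12" = "integer", "4" = "double",
                 stop("unsupported ENVI data type: ", h$data_type))
  size <- switch(as.character(h$data_type), "12" = 2L, "4" = 4L)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- if (what == "integer") {
    readBin(con, "integer", n = n + 1L, size = size, signed = FALSE,
            endian = "little")
  } else {
    readBin(con, "double", n = n + 1L, size = size, endian = "little")
  }
  if (length(vals) != n) {
    stop(sprintf("cube file holds %d values, header promises %d",
                 length(vals), n))
  }
  vals <- as.numeric(vals)
  data <- if (h$interleave == "bsq") {
    # on disk: band-major, then line (row), then sample (col)
    aperm(array(vals, dim = c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L))
  } else { # bil: line-major, band, sample
    aperm(array(vals, dim = c(h$samples, h$bands, h$lines)), c(3L, 1L, 2L))
  }
  new_raw_cube(data, spectral_axis(h$wavelengths))
}

#' Write an ENVI-style hyperspectral cube
#'
#' @param cube A `raw_cube` or `reflectance_cube`.
#' @param path Output binary path; the header is written to `<path>.hdr`.
#' @param interleave `"bsq"` (default) or `"bil"`.
#' @param data_type `4` for float32 (default) or `12` for uint16.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil"),
                       data_type = 4L) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, c("raw_cube", "reflectance_cube")))
  d <- dim(cube$data)
  vals <- if (interleave == "bsq") {
    as.vector(aperm(cube$data, c(2L, 1L, 3L)))
  } else {
    as.vector(aperm(cube$data, c(2L, 3L, 1L)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (data_type == 12L) {
    v <- as.integer(round(vals))
    if (any(v < 0L) || any(v > 65535L)) stop("values do not fit uint16")
    writeBin(v, con, size = 2L, endian = "little")
  } else if (data_type == 4L) {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  } else stop("unsupported data type: ", data_type)
  hdr <- c(
    "ENVI",
    "description = { hsisas cube }",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {",
           paste(format(cube$axis$wavelengths_nm, trim = TRUE, digits = 10),
                 collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Flat-field reflectance calibration
#'
#' Converts detector counts to unitless reflectance with the standard
#' flat-field convention `(raw - dark) / (white - dark)`, element-wise over
#' the cube.  Pixels whose denominator `white - dark` falls at or below
#' `eps` (default `1e-9 * max(white)`) are imputed to reflectance 0 and
#' flagged in the returned QC mask so they cannot inject NaN into
#' downstream correlation matrices.  Output is clipped to
#' `[0, clip_max]`; specular highlights legitimately exceed 1, hence the
#' default ceiling of 2.
#'
#' @param raw,white,dark [raw_cube()]s of identical shape and axis: the
#'   scene, the white-reference board, and the closed-cap dark frame.
#' @param clip_max Upper clip bound for reflectance (default 2).
#' @param eps Denominator guard; default `1e-9 * max(white counts)`.
#' @param white_mode `"per_pixel"` (default) applies the white reference
#'   element-wise; `"column_mean"` averages the white frame over rows first,
#'   the appropriate choice when the white board is imaged at a single
#'   location of the push-broom scan.
#' @return A [reflectance_cube()]; `$qc_mask` marks imputed pixels.
#' @export
calibrate <- function(raw, white, dark, clip_max = 2, eps = NULL,
                      white_mode = c("per_pixel", "column_mean")) {
  white_mode <- match.arg(white_mode)
  stopifnot(inherits(raw, "raw_cube"), inherits(white, "raw_cube"),
            inherits(dark, "raw_cube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data))) {
    stop("raw/white/dark cubes must share one shape")
  }
  if (!axes_identical(raw$axis, white$axis) ||
      !axes_identical(raw$axis, dark$axis)) {
    stop("raw/white/dark cubes must share one spectral axis")
  }
  wdat <- white$data
  if (white_mode == "column_mean") {
    # collapse scan direction: one spectrum per across-track column
    cm <- apply(wdat, c(2L, 3L), mean)
    wdat <- aperm(array(cm, dim = dim(wdat)[c(2L, 3L, 1L)]), c(3L, 1L, 2L))
  }
  if (is.null(eps)) eps <- 1e-9 * max(wdat)
  denom <- wdat - dark$data
  if (all(denom <= eps)) stop("white reference does not exceed dark frame")
  bad <- denom <= eps
  denom[bad] <- 1 # placeholder; result overwritten below
  refl <- (raw$data - dark$data) / denom
  refl[bad] <- 0
  refl[refl < 0] <- 0
  refl[refl > clip_max] <- clip_max
  qc <- apply(bad, c(1L, 2L), any)
  reflectance_cube(refl, raw$axis,
                   provenance = list(white_mode = white_mode,
                                     clip_max = clip_max, eps = eps),
                   qc_mask = qc)
}
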