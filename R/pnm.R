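#' Read / write plain-text PNM images
#'
#' The pre-installed stack has no PNG codec, so raster interchange
#' (ultrasound frames, ROI masks, rendered maps) uses the ASCII PNM
#' formats: P2 (grayscale) and P3 (RGB), 8-bit.  `write_pnm` picks P2 for
#' a matrix and P3 for a rows x cols x 3 array.
#'
#' @param path File path.
#' @return `read_pnm` returns a numeric matrix (P2) or rows x cols x 3
#'   array (P3) of values in `[0, maxval]`.
#' @export
read_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1L]
  if (!magic %in% c("P2", "P3")) stop("unsupported PNM magic: ", magic)
  nums <- as.numeric(toks[-1L])
  w <- nums[1L]; h <- nums[2L]
  vals <- nums[-(1:3)]
  if (magic == "P2") {
    if (length(vals) != w * h) stop("PNM size mismatch")
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(vals) != 3 * w * h) stop("PNM size mismatch")
    px <- matrix(vals, ncol = 3L, byrow = TRUE)
    out <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) out[, , ch] <- matrix(px[, ch], h, w, byrow = TRUE)
    out
  }
}

#' @rdname read_pnm
#' @param image Matrix (written as P2) or rows x cols x 3 array (P3);
#'   values are rounded and clipped to `[0, maxval]`.
#' @param maxval Maximum sample value (default 255).
#' @export
write_pnm <- function(image, path, maxval = 255L) {
  clip <- function(v) pmin(pmax(round(v), 0L), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(image)) {
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
               con)
    write(t(clip(image)), file = con, ncolumns = min(ncol(image), 20L))
  } else if (is.array(image) && length(dim(image)) == 3L &&
             dim(image)[3L] == 3L) {
    writeLines(c("P3", paste(dim(image)[2L], dim(image)[1L]),
                 as.character(maxval)), con)
    h <- dim(image)[1L]; w <- dim(image)[2L]
    px <- cbind(as.vector(t(image[, , 1L])), as.vector(t(image[, , 2L])),
                as.vector(t(image[, , 3L])))
    write(t(clip(px)), file = con, ncolumns = 15L)
  } else stop("image must be a matrix or rows x cols x 3 array")
  invisible(path)
}
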