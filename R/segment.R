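#' Band-ratio contrast image
#'
#' Element-wise ratio of two bands of a reflectance cube, the standard
#' contrast enhancement for tissue vs. background in the SWIR: tissue
#' water absorbs strongly near 1450 nm while the board does not, so the
#' default 1303/1453 nm ratio is high on skin and near 1 on the board.
#'
#' @param cube A [reflectance_cube()].
#' @param numerator_nm,denominator_nm Wavelengths (nm) of the two bands;
#'   defaults 1303 and 1453.
#' @param eps Guard for the denominator band (default 1e-9).
#' @return A `ratio_image`: list with `data` (rows x cols matrix),
#'   `numerator_nm`, `denominator_nm`.
#' @export
band_ratio <- function(cube, numerator_nm = 1303, denominator_nm = 1453,
                       eps = 1e-9) {
  stopifnot(inherits(cube, "reflectance_cube"))
  bn <- nearest_band(cube$axis, numerator_nm)
  bd <- nearest_band(cube$axis, denominator_nm)
  num <- cube$data[, , bn]
  den <- pmax(cube$data[, , bd], eps)
  structure(list(data = num / den,
                 numerator_nm = cube$axis$wavelengths_nm[bn],
                 denominator_nm = cube$axis$wavelengths_nm[bd]),
            class = "ratio_image")
}

#' Otsu threshold
#'
#' Histogram threshold maximizing between-class variance over an
#' `n_bins` histogram of the image values.  Returns the bin *edge*
#' separating the two classes; values strictly greater than the threshold
#' are foreground.  Ties in the between-class variance break toward the
#' lower threshold.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @param n_bins Histogram resolution (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || rng[1L] == rng[2L]) {
    stop("otsu_threshold: image is constant, no threshold exists")
  }
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(v, bin)
  sums[as.integer(rownames(agg))] <- agg
  n <- length(v)
  w0 <- cumsum(counts)                      # pixels at or below edge k+1
  mu0 <- cumsum(sums)                       # their value sum (exact)
  mu_t <- mu0[n_bins]
  # candidate thresholds: interior edges edges[2..n_bins]
  k <- seq_len(n_bins - 1L)
  p0 <- w0[k] / n
  p1 <- 1 - p0
  valid <- p0 > 0 & p1 > 0
  m0 <- mu0[k] / w0[k]
  m1 <- (mu_t - mu0[k]) / (n - w0[k])
  sigma_b <- p0 * p1 * (m0 - m1)^2
  sigma_b[!valid] <- -Inf
  best <- which.max(sigma_b)               # first maximizer -> lower edge
  edges[best + 1L]
}

# 4-connected component labelling by iterative flood fill (queue-based).
# Adequate for the segmentation masks this package sees; returns an
# integer matrix of labels, 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      nb <- c(cur[r > 1L] - 1L, cur[r < nr] + 1L,
              cur[cl > 1L] - nr, cur[cl < nc] + nr)
      nb <- unique(nb[mask[nb] & labels[nb] == 0L])
      labels[nb] <- lab
      queue <- nb
    }
  }
  labels
}

# binary morphological closing with a k x k square structuring element
morph_close <- function(mask, k = 3L) {
  dilate <- function(m) {
    out <- m
    r <- (k - 1L) %/% 2L
    nr <- nrow(m); nc <- ncol(m)
    for (dr in -r:r) for (dc in -r:r) {
      if (dr == 0L && dc == 0L) next
      src_r <- max(1L, 1L - dr):min(nr, nr - dr)
      src_c <- max(1L, 1L - dc):min(nc, nc - dc)
      out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] |
        m[src_r, src_c]
    }
    out
  }
  erode <- function(m) !dilate(!m)
  erode(dilate(mask))
}

#' Segment the hand from a band-ratio image
#'
#' Otsu-binarizes the ratio image, takes the side with the higher mean
#' ratio as foreground, optionally closes small gaps (3x3 closing) and
#' keeps the largest 4-connected component.
#'
#' @param ratio A `ratio_image` from [band_ratio()].
#' @param cleanup Apply closing + largest-component cleanup (default TRUE;
#'   set FALSE for a strict raw Otsu mask).
#' @param n_bins Histogram resolution passed to [otsu_threshold()].
#' @return Logical rows x cols mask.
#' @export
segment_hand <- function(ratio, cleanup = TRUE, n_bins = 256L) {
  stopifnot(inherits(ratio, "ratio_image"))
  img <- ratio$data
  thr <- otsu_threshold(img, n_bins)
  fg <- img > thr
  # foreground is the class with the higher mean ratio (hand spectra have
  # the deeper 1450-nm water dip, hence the larger 1303/1453 ratio)
  if (mean(img[fg]) < mean(img[!fg])) fg <- !fg
  if (cleanup) {
    fg <- morph_close(fg, 3L)
    labs <- label_components(fg)
    if (max(labs) == 0L) stop("segmentation produced an empty foreground")
    sizes <- tabulate(labs[labs > 0L])
    fg <- labs == which.max(sizes)
  }
  if (!any(fg)) stop("segmentation produced an empty foreground")
  fg
}

#' Extract the wrist region of interest
#'
#' Intersects the hand mask with a fixed-height horizontal band anchored
#' at an operator-supplied wrist row: rows `[wrist_row, wrist_row +
#' extension_rows)` (half-open, clamped at the image edge), matching the
#' convention that scan rows increase from fingers toward the forearm.
#' `direction = "up"` extends toward decreasing rows instead; `centered =
#' TRUE` centers the band on `wrist_row`.
#'
#' @param cube A [reflectance_cube()].
#' @param hand_mask Logical rows x cols mask from [segment_hand()].
#' @param wrist_row 1-based wrist row selected by the operator.
#' @param extension_rows Height of the band in rows (default 100).
#' @param direction `"down"` (default) or `"up"`.
#' @param centered Center the band on `wrist_row` (default FALSE).
#' @return A `wrist_roi`: list with `mask`, `wrist_row`, `extension_rows`,
#'   `spectra` (n x L matrix gathered in raster row-major order), `n`.
#' @export
extract_wrist_roi <- function(cube, hand_mask, wrist_row,
                              extension_rows = 100L,
                              direction = c("down", "up"),
                              centered = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(cube, "reflectance_cube"), is.logical(hand_mask))
  d <- dim(cube$data)
  if (!all(dim(hand_mask) == d[1:2])) stop("mask/cube shape mismatch")
  if (wrist_row < 1L || wrist_row > d[1L]) stop("wrist_row out of range")
  if (centered) {
    lo <- wrist_row - floor(extension_rows / 2)
    hi <- lo + extension_rows - 1L
  } else if (direction == "down") {
    lo <- wrist_row; hi <- wrist_row + extension_rows - 1L
  } else {
    hi <- wrist_row; lo <- wrist_row - extension_rows + 1L
  }
  rows <- max(1L, lo):min(d[1L], hi)
  band <- matrix(FALSE, d[1L], d[2L])
  band[rows, ] <- TRUE
  mask <- hand_mask & band
  n <- sum(mask)
  if (n == 0L) stop("wrist ROI is empty")
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  # raster (row-major) order: sort linear indices by (row, col)
  idx <- which(mask)
  r <- (idx - 1L) %% d[1L] + 1L
  cl <- (idx - 1L) %/% d[1L] + 1L
  ord <- order(r, cl)
  idx <- idx[ord]
  structure(list(mask = mask, wrist_row = wrist_row,
                 extension_rows = extension_rows,
                 spectra = flat[idx, , drop = FALSE],
                 pixel_index = idx, n = n, axis = cube$axis),
            class = "wrist_roi")
}

#' @export
print.wrist_roi <- function(x, ...) {
  cat(sprintf("<wrist_roi> %d pixels, %d bands, wrist row %d (+%d)\n",
              x$n, ncol(x$spectra), x$wrist_row, x$extension_rows))
  invisible(x)
}

#' Dice similarity of two masks
#'
#' @param a,b Logical matrices of one shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
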