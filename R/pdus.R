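#' @title Power-Doppler ultrasound quantification
#' @description
#' Quantifies the synovial area and the power-Doppler (PD) signal area
#' from an RGB ultrasound frame given an expert-drawn synovial polygon:
#' polygon rasterization -> red-gray conversion -> threshold -> pixel
#' count, the standard computer-aided PD quantification pipeline.
#' @name pdus
NULL

# do segments p1-p2 and p3-p4 properly intersect (shared endpoints ignored)?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(poly) {
  nv <- nrow(poly)
  nxt <- c(seq_len(nv)[-1L], 1L)
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      # skip edges sharing a vertex
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(poly[i, ], poly[nxt[i], ],
                         poly[j, ], poly[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# even-odd rule: is the point (r, c) inside the polygon?  Pixels whose
# centers sit exactly on an edge are claimed (boundary included) by a
# half-open crossing rule plus an explicit on-edge test.
point_in_polygon <- function(r, c, poly) {
  nv <- nrow(poly)
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    ri <- poly[i, 1L]; ci <- poly[i, 2L]
    rj <- poly[j, 1L]; cj <- poly[j, 2L]
    # on-edge check
    if ((ci - c) * (cj - c) <= 0 && (ri - r) * (rj - r) <= 0) {
      cr <- (cj - ci) * (r - ri) - (rj - ri) * (c - ci)
      if (abs(cr) < 1e-9) return(TRUE)
    }
    if ((ri > r) != (rj > r)) {
      x_int <- ci + (r - ri) * (cj - ci) / (rj - ri)
      if (c < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Rasterize a synovial ROI polygon
#'
#' Even-odd-rule fill of a simple polygon over the frame's pixel grid;
#' pixels whose centers fall inside (boundary included) are set.
#'
#' @param frame An `ultrasound_frame` (see [ultrasound_frame()]) or any
#'   object with the target image dimensions via `dim()`; alternatively
#'   pass `shape = c(rows, cols)`.
#' @param polygon Matrix of ordered vertices, columns (row, col), >= 3
#'   rows, 1-based pixel coordinates.
#' @param shape Optional c(rows, cols) overriding `frame`.
#' @return A `synovial_roi`: list with `polygon`, `mask`, `area_px`.
#' @export
rasterize_roi <- function(frame = NULL, polygon, shape = NULL) {
  poly <- as.matrix(polygon)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  if (!polygon_is_simple(poly)) stop("polygon is self-intersecting")
  if (is.null(shape)) {
    shape <- if (inherits(frame, "ultrasound_frame")) dim(frame$rgb)[1:2]
             else dim(frame)[1:2]
  }
  if (any(poly[, 1L] < 1) || any(poly[, 1L] > shape[1L]) ||
      any(poly[, 2L] < 1) || any(poly[, 2L] > shape[2L])) {
    stop("polygon vertex outside image bounds")
  }
  mask <- matrix(FALSE, shape[1L], shape[2L])
  rr <- floor(min(poly[, 1L])):ceiling(max(poly[, 1L]))
  cc <- floor(min(poly[, 2L])):ceiling(max(poly[, 2L]))
  for (r in rr) for (c in cc) {
    if (point_in_polygon(r, c, poly)) mask[r, c] <- TRUE
  }
  structure(list(polygon = poly, mask = mask, area_px = sum(mask)),
            class = "synovial_roi")
}

#' RGB ultrasound frame container
#'
#' @param rgb rows x cols x 3 array, 8-bit channel values in \[0, 255\].
#' @param mm_per_pixel Optional pixel spacing for mm^2 area reporting.
#' @return An `ultrasound_frame`.
#' @export
ultrasound_frame <- function(rgb, mm_per_pixel = NULL) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  if (min(rgb) < 0 || max(rgb) > 255) stop("channel values must be 8-bit")
  structure(list(rgb = rgb, mm_per_pixel = mm_per_pixel),
            class = "ultrasound_frame")
}

#' Red-gray image from an RGB frame
#'
#' `mode = "red"` (default) returns the red channel, the literal reading
#' of RGB decomposition followed by a red-gray image.  `mode = "reddom"`
#' returns `max(R - max(G, B), 0)`, which is zero on achromatic (gray
#' echo) pixels and isolates the Doppler color overlay; use it when the
#' acquisition color gain cannot be assumed to suppress background red.
#'
#' @param frame An `ultrasound_frame` or rows x cols x 3 array.
#' @param mode `"red"` or `"reddom"`.
#' @return Numeric rows x cols matrix.
#' @export
red_gray <- function(frame, mode = c("red", "reddom")) {
  mode <- match.arg(mode)
  rgb <- if (inherits(frame, "ultrasound_frame")) frame$rgb else frame
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3L] == 3L)) {
    stop("frame must have exactly 3 channels")
  }
  out <- if (mode == "red") rgb[, , 1L, drop = FALSE]
  else pmax(rgb[, , 1L, drop = FALSE] -
              pmax(rgb[, , 2L, drop = FALSE], rgb[, , 3L, drop = FALSE]), 0)
  matrix(out, dim(rgb)[1L], dim(rgb)[2L])
}

#' Power-Doppler area within the synovial ROI
#'
#' Counts ROI pixels whose red-gray value strictly exceeds the threshold.
#' `threshold = "auto"` applies the Otsu rule to the ROI pixels only
#' (degenerate constant ROIs fall back to "no signal", area 0).
#'
#' @param gray Red-gray matrix from [red_gray()].
#' @param roi A `synovial_roi` from [rasterize_roi()].
#' @param threshold Numeric cut, or `"auto"` for Otsu within the ROI.
#' @return Integer pixel count, with the threshold used attached as
#'   attribute `"threshold"`.
#' @export
pd_area <- function(gray, roi, threshold = "auto") {
  stopifnot(inherits(roi, "synovial_roi"))
  if (!all(dim(gray) == dim(roi$mask))) stop("gray/ROI shape mismatch")
  vals <- gray[roi$mask]
  if (length(vals) == 0L) stop("empty synovial ROI")
  thr <- if (identical(threshold, "auto")) {
    if (min(vals) == max(vals)) Inf else otsu_threshold(vals)
  } else threshold
  structure(sum(vals > thr), threshold = thr)
}
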