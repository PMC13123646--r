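#' Build the target signature d
#'
#' The target is the mean post-treatment wrist spectrum: pooled,
#' pixel-weighted mean over the contributing ROIs (a 30-pixel ROI weighs
#' three times a 10-pixel ROI, i.e. the column mean of the stacked pixel
#' matrix).  `scope = "subject"` pools one subject's two hands,
#' `scope = "cohort"` pools every subject's post-treatment ROIs.
#'
#' @param post_rois List of `wrist_roi` objects (or plain n x L matrices).
#' @param scope `"subject"` or `"cohort"`; metadata only, recorded in the
#'   result.
#' @return A `target_signature`: list with `d` (length-L vector), `scope`,
#'   `n_pixels`.
#' @export
build_target <- function(post_rois, scope = c("subject", "cohort")) {
  scope <- match.arg(scope)
  if (inherits(post_rois, "wrist_roi") || is.matrix(post_rois)) {
    post_rois <- list(post_rois)
  }
  if (length(post_rois) == 0L) stop("empty ROI pool for target")
  mats <- lapply(post_rois, function(r) {
    if (inherits(r, "wrist_roi")) r$spectra else as.matrix(r)
  })
  pooled <- do.call(rbind, mats)
  if (nrow(pooled) == 0L) stop("empty ROI pool for target")
  d <- colMeans(pooled)
  if (!all(is.finite(d)) || all(d == 0)) stop("degenerate target signature")
  structure(list(d = d, scope = scope, n_pixels = nrow(pooled)),
            class = "target_signature")
}

#' CEM abundance score of a single spectrum
#'
#' The constrained-energy-minimization score
#' `delta(r) = (r R^-1 d) / (d' R^-1 d)`: unit response at the target
#' (`delta(d) = 1`), linear in `r`, output energy minimized under the
#' correlation structure `R`.  With `denominator = "plain"` the
#' normalization `d' R d` (no inverse) is used instead; that variant does
#' not satisfy `delta(d) = 1` and is provided for comparison only.
#'
#' @param spectrum Length-L numeric vector r.
#' @param R_inv L x L regularized inverse of the correlation matrix (a
#'   matrix, or a `correlation_matrix` whose `$R_inv` is used).
#' @param d A `target_signature` or length-L vector.
#' @param denominator `"inverse"` (default) or `"plain"`; for `"plain"`
#'   the raw correlation matrix `R` must be supplied as `R_plain`.
#' @param R_plain Raw L x L matrix, only for `denominator = "plain"`.
#' @return Scalar score.
#' @export
cem_score <- function(spectrum, R_inv, d,
                      denominator = c("inverse", "plain"), R_plain = NULL) {
  denominator <- match.arg(denominator)
  if (inherits(R_inv, "correlation_matrix")) {
    if (is.null(R_plain)) R_plain <- R_inv$R
    R_inv <- R_inv$R_inv
  }
  dv <- if (inherits(d, "target_signature")) d$d else as.numeric(d)
  r <- as.numeric(spectrum)
  stopifnot(length(r) == length(dv), all(dim(R_inv) == length(dv)))
  w <- drop(R_inv %*% dv)
  den <- if (denominator == "inverse") {
    sum(dv * w)
  } else {
    if (is.null(R_plain)) stop("plain denominator needs the raw matrix R")
    drop(crossprod(dv, R_plain %*% dv))
  }
  if (abs(den) < 1e-30) stop("singular target: d' R^-1 d is zero")
  sum(r * w) / den
}

#' Score every ROI pixel (abundance map)
#'
#' Applies [cem_score()] to every pixel of the ROI via one linear solve
#' `w = R_reg^-1 d` followed by per-pixel dot products; identical to the
#' per-pixel form to numerical precision.
#'
#' @param cube A [reflectance_cube()] (only used for shape/axis checks;
#'   may be NULL when the ROI carries its spectra).
#' @param roi A `wrist_roi`.
#' @param R A `correlation_matrix`.
#' @param d A `target_signature` or length-L vector.
#' @inheritParams cem_score
#' @return An `abundance_map`: list with `scores` (rows x cols matrix,
#'   NA off the ROI), `values` (per-ROI-pixel scores in raster order),
#'   `kind`, `lambda`.
#' @export
score_map <- function(cube = NULL, roi, R, d,
                      denominator = c("inverse", "plain")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(roi, "wrist_roi"), inherits(R, "correlation_matrix"))
  dv <- if (inherits(d, "target_signature")) d$d else as.numeric(d)
  L <- ncol(roi$spectra)
  if (length(dv) != L || nrow(R$R) != L) {
    stop(sprintf("dimension mismatch: roi L=%d, d L=%d, R L=%d",
                 L, length(dv), nrow(R$R)))
  }
  if (!is.null(cube) && cube$axis$L != L) stop("cube/ROI band mismatch")
  w <- drop(R$R_inv %*% dv)
  den <- if (denominator == "inverse") sum(dv * w) else
    drop(crossprod(dv, R$R %*% dv))
  if (abs(den) < 1e-30) stop("singular target: d' R^-1 d is zero")
  vals <- drop(roi$spectra %*% w) / den
  scores <- matrix(NA_real_, nrow(roi$mask), ncol(roi$mask))
  scores[roi$pixel_index] <- vals
  structure(list(scores = scores, values = vals, kind = R$kind,
                 corr_mode = R$corr_mode, lambda = R$ridge_lambda),
            class = "abundance_map")
}

#' Reduce an abundance map to one per-wrist scalar
#'
#' @param map An `abundance_map` (or numeric vector of pixel scores).
#' @param reducer `"mean"` (default), `"median"`, or `"trimmed"`
#'   (10% trimmed mean).
#' @return Scalar wrist-level score.
#' @export
wrist_score <- function(map, reducer = c("mean", "median", "trimmed")) {
  reducer <- match.arg(reducer)
  v <- if (inherits(map, "abundance_map")) map$values else as.numeric(map)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty abundance map")
  switch(reducer,
         mean = mean(v),
         median = stats::median(v),
         trimmed = mean(v, trim = 0.1))
}

#' Score a full cohort
#'
#' For every subject with both visits: pairs the pre/post ROI spectra per
#' hand, builds the subject's intra-subject correlation matrix and
#' subject-scope target (pooled post-treatment hands), and the cohort
#' inter-subject matrix and cohort-scope target, then scores all four
#' wrist images of each subject against both.  Emits one record per
#' (subject, hand, visit): `2 * 2 * m` rows for a complete cohort.
#' Subjects missing a visit are excluded from scoring with a warning.
#'
#' @param rois Nested list: `rois[[subject]][[visit]][[hand]]` with visits
#'   `"pre"`/`"post"`, hands `"L"`/`"R"`, each a `wrist_roi`.
#' @param corr_mode Correlation estimator passed to the matrix builders
#'   (see [cross_band_correlation()]); default `"cem"`, the reading under
#'   which the detector suppresses off-target (pre-treatment) spectra.
#' @param reducer Pixel-to-wrist reduction (see [wrist_score()]).
#' @param ridge_lambda Passed to [regularized_inverse()].
#' @param pairing,seed Passed to [pair_pixels()].
#' @return A data.frame of score records: subject_id, hand, visit,
#'   intra_score, inter_score, n_pixels, reducer, corr_mode, lambda_intra,
#'   lambda_inter.
#' @export
score_cohort <- function(rois, corr_mode = c("cem", "pearson"),
                         reducer = "mean", ridge_lambda = "auto",
                         pairing = "truncate", seed = NULL) {
  corr_mode <- match.arg(corr_mode)
  subjects <- names(rois)
  complete <- vapply(subjects, function(s) {
    all(c("pre", "post") %in% names(rois[[s]])) &&
      length(rois[[s]]$pre) > 0L && length(rois[[s]]$post) > 0L
  }, logical(1))
  if (any(!complete)) {
    warning("excluding subject(s) missing a visit: ",
            paste(subjects[!complete], collapse = ", "))
    subjects <- subjects[complete]
  }
  if (length(subjects) == 0L) stop("no subject has both visits")

  # per-subject pairing (hands pooled in Left, Right order)
  paired <- lapply(subjects, function(s) {
    pre <- do.call(rbind, lapply(rois[[s]]$pre, `[[`, "spectra"))
    post <- do.call(rbind, lapply(rois[[s]]$post, `[[`, "spectra"))
    pair_pixels(pre, post, strategy = pairing, seed = seed, subject_id = s)
  })
  names(paired) <- subjects

  inter_R <- inter_correlation(paired, corr_mode = corr_mode,
                               ridge_lambda = ridge_lambda)
  d_cohort <- build_target(unlist(lapply(subjects, function(s)
    rois[[s]]$post), recursive = FALSE), scope = "cohort")

  records <- list()
  for (s in subjects) {
    intra_R <- cross_band_correlation(paired[[s]], corr_mode = corr_mode,
                                      ridge_lambda = ridge_lambda)
    d_subj <- build_target(rois[[s]]$post, scope = "subject")
    for (visit in c("pre", "post")) {
      for (hand in names(rois[[s]][[visit]])) {
        roi <- rois[[s]][[visit]][[hand]]
        m_intra <- score_map(NULL, roi, intra_R, d_subj)
        m_inter <- score_map(NULL, roi, inter_R, d_cohort)
        records[[length(records) + 1L]] <- data.frame(
          subject_id = s, hand = hand, visit = visit,
          intra_score = wrist_score(m_intra, reducer),
          inter_score = wrist_score(m_inter, reducer),
          n_pixels = roi$n, reducer = reducer, corr_mode = corr_mode,
          lambda_intra = intra_R$ridge_lambda,
          lambda_inter = inter_R$ridge_lambda,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, records)
}
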