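#' Pair pre- and post-treatment wrist spectra
#'
#' The correlation estimators run over a common pixel index i, so unequal
#' ROI pixel counts must be reconciled.  `truncate` (default) keeps the
#' first `n = min(n_pre, n_post)` rows of each ROI in raster order —
#' deterministic; `subsample` draws `n` rows from each without
#' replacement using `seed`.
#'
#' @param pre_roi,post_roi `wrist_roi` objects (see [extract_wrist_roi()]).
#' @param strategy `"truncate"` or `"subsample"`.
#' @param seed Integer seed; required for `"subsample"`.
#' @return A `paired_spectra`: list with `X`, `Y` (n x L), `x_bar`,
#'   `y_bar`, `n`, `subject_id`.
#' @param subject_id Optional identifier carried into downstream records.
#' @export
pair_pixels <- function(pre_roi, post_roi,
                        strategy = c("truncate", "subsample"),
                        seed = NULL, subject_id = NA_character_) {
  strategy <- match.arg(strategy)
  X <- if (inherits(pre_roi, "wrist_roi")) pre_roi$spectra else as.matrix(pre_roi)
  Y <- if (inherits(post_roi, "wrist_roi")) post_roi$spectra else as.matrix(post_roi)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("empty ROI in pairing")
  if (ncol(X) != ncol(Y)) stop("pre/post band counts differ")
  n <- min(nrow(X), nrow(Y))
  if (strategy == "truncate") {
    X <- X[seq_len(n), , drop = FALSE]
    Y <- Y[seq_len(n), , drop = FALSE]
  } else {
    if (is.null(seed)) stop("subsample pairing requires a seed")
    X <- X[with_seed(seed, sample.int(nrow(X), n)), , drop = FALSE]
    Y <- Y[with_seed(seed + 1L, sample.int(nrow(Y), n)), , drop = FALSE]
  }
  structure(list(X = X, Y = Y,
                 x_bar = colMeans(X), y_bar = colMeans(Y),
                 n = n, subject_id = subject_id),
            class = "paired_spectra")
}

# correlation core shared by the intra and inter estimators:
# R[a, b] = Pearson corr over pixels of pre band a vs post band b
band_pair_pearson <- function(X, Y) {
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sx <- colSums(Xc^2)
  sy <- colSums(Yc^2)
  degen <- c(which(sx <= 0), which(sy <= 0))
  if (length(degen)) {
    stop("zero-variance band(s): ", paste(sort(unique(degen)), collapse = ", "))
  }
  crossprod(Xc, Yc) / sqrt(outer(sx, sy))
}

# classic CEM sample (auto)correlation of the pooled, uncentered spectra
pooled_autocorrelation <- function(Z) crossprod(Z) / nrow(Z)

new_correlation_matrix <- function(R, kind, corr_mode, n_effective, m = 1L,
                                   ridge_lambda = "auto") {
  inv <- regularized_inverse(R, ridge_lambda)
  structure(list(R = R, kind = kind, corr_mode = corr_mode,
                 ridge_lambda = attr(inv, "lambda"), R_inv = inv,
                 n_effective = n_effective, m = m),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> kind=%s mode=%s L=%d n=%d m=%d lambda=%.3g\n",
              x$kind, x$corr_mode, nrow(x$R), x$n_effective, x$m,
              x$ridge_lambda))
  invisible(x)
}

#' Intra-subject spectral correlation matrix
#'
#' Builds the L x L correlation matrix relating a subject's pre- and
#' post-treatment wrist spectra.  Two readings are provided:
#' `"pearson"` (default) computes the band-pair cross-correlation
#' `R[a,b] = corr(pre band a, post band b)` across the n paired pixels,
#' the matrix form of the printed estimator; `"cem"` computes the classic
#' CEM sample autocorrelation `(1/N) sum r r'` of the pooled (pre + post)
#' uncentered pixel spectra, the form the cited detector literature uses.
#' The mode travels with the matrix and is recorded in every downstream
#' output.
#'
#' @param P A `paired_spectra` from [pair_pixels()].
#' @param corr_mode `"pearson"` or `"cem"`.
#' @param ridge_lambda Ridge strength for the regularized inverse, or
#'   `"auto"` (see [regularized_inverse()]).
#' @return A `correlation_matrix` with fields `R`, `R_inv`, `kind =
#'   "intra"`, `corr_mode`, `ridge_lambda`, `n_effective`.
#' @export
cross_band_correlation <- function(P, corr_mode = c("pearson", "cem"),
                                   ridge_lambda = "auto") {
  corr_mode <- match.arg(corr_mode)
  stopifnot(inherits(P, "paired_spectra"))
  R <- if (corr_mode == "pearson") {
    band_pair_pearson(P$X, P$Y)
  } else {
    pooled_autocorrelation(rbind(P$X, P$Y))
  }
  new_correlation_matrix(R, "intra", corr_mode, P$n, 1L, ridge_lambda)
}

#' Inter-subject (cohort) spectral correlation matrix
#'
#' Identical estimator to [cross_band_correlation()] but with the sums
#' running over the pooled paired pixels of all m subjects, means taken
#' over the pooled set.
#'
#' @param cohort List of `paired_spectra`, one per subject (m >= 1).
#' @inheritParams cross_band_correlation
#' @return A `correlation_matrix` with `kind = "inter"` and `m` set.
#' @export
inter_correlation <- function(cohort, corr_mode = c("pearson", "cem"),
                              ridge_lambda = "auto") {
  corr_mode <- match.arg(corr_mode)
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  Ls <- vapply(cohort, function(p) ncol(p$X), integer(1))
  if (length(unique(Ls)) != 1L) stop("subjects disagree on band count L")
  X <- do.call(rbind, lapply(cohort, `[[`, "X"))
  Y <- do.call(rbind, lapply(cohort, `[[`, "Y"))
  R <- if (corr_mode == "pearson") {
    band_pair_pearson(X, Y)
  } else {
    pooled_autocorrelation(rbind(X, Y))
  }
  new_correlation_matrix(R, "inter", corr_mode, nrow(X), length(cohort),
                         ridge_lambda)
}

#' Regularized inverse of a (possibly non-symmetric) correlation matrix
#'
#' The band-pair cross-correlation matrix is generally non-symmetric and,
#' with n paired pixels potentially below L bands, rank-deficient by
#' construction, while the CEM quadratic form presumes a symmetric
#' positive-definite system.  The matrix is therefore symmetrized,
#' `R_s = (R + R')/2`, and a ridge added before inversion.  `lambda =
#' "auto"` starts at `1e-6 * trace(R_s)/L` (floored at 1e-12 for
#' zero-trace input) and escalates tenfold until the smallest eigenvalue
#' of `R_s + lambda I` exceeds 1e-10.
#'
#' @param R Square numeric matrix, finite entries.
#' @param lambda Non-negative ridge, or `"auto"`.
#' @param symmetrize Symmetrize before inversion (default TRUE).
#' @return The inverse of `R_s + lambda I`, with the lambda used attached
#'   as attribute `"lambda"`.
#' @export
regularized_inverse <- function(R, lambda = "auto", symmetrize = TRUE) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square")
  if (!all(is.finite(R))) stop("R has non-finite entries")
  Rs <- if (symmetrize) (R + t(R)) / 2 else R
  L <- nrow(Rs)
  if (identical(lambda, "auto")) {
    lam <- max(1e-6 * sum(diag(Rs)) / L, 1e-12)
    ev_min <- min(Re(eigen(Rs, symmetric = symmetrize,
                           only.values = TRUE)$values))
    while (ev_min + lam <= 1e-10) lam <- lam * 10
  } else {
    lam <- lambda
  }
  inv <- solve(Rs + diag(lam, L))
  attr(inv, "lambda") <- lam
  inv
}

# evaluate a deterministic expression under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
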