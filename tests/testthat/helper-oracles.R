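# Independent oracles used by the derived-value tests.  These deliberately
# take the dumbest correct route (scalar loops, exhaustive search, full
# enumeration) and share no code with the implementation paths they check.

# entry-by-entry Pearson cross-correlation via scalar loops
oracle_band_pair_pearson <- function(X, Y) {
  L <- ncol(X)
  R <- matrix(NA_real_, L, L)
  for (a in seq_len(L)) {
    for (b in seq_len(L)) {
      xa <- X[, a] - mean(X[, a])
      yb <- Y[, b] - mean(Y[, b])
      R[a, b] <- sum(xa * yb) / sqrt(sum(xa^2) * sum(yb^2))
    }
  }
  R
}

# exhaustive between-class-variance maximizer over histogram bin edges
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  best_edge <- NA_real_
  best_sigma <- -Inf
  for (k in 2:n_bins) {
    t <- edges[k]
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    p0 <- length(lo) / length(v)
    sigma <- p0 * (1 - p0) * (mean(lo) - mean(hi))^2
    if (sigma > best_sigma + 1e-15) {
      best_sigma <- sigma
      best_edge <- t
    }
  }
  best_edge
}

# exact signed-rank p by enumerating all 2^n sign assignments
oracle_signrank_p <- function(pre, post, alternative = "two.sided") {
  d <- (post - pre)
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  w_all <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code))[seq_len(n)]
    w_all[code + 1L] <- sum(ranks[signs == 1L])
  }
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# winding-number point-in-polygon (boundary counted inside), independent
# of the even-odd crossing implementation
oracle_point_in_polygon <- function(r, c, poly) {
  nv <- nrow(poly)
  ang <- 0
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    v1 <- c(poly[i, 1L] - r, poly[i, 2L] - c)
    v2 <- c(poly[j, 1L] - r, poly[j, 2L] - c)
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12) return(TRUE)      # on a vertex
    cr <- v1[1L] * v2[2L] - v1[2L] * v2[1L]
    dt <- sum(v1 * v2)
    if (abs(cr) < 1e-9 && dt < 0) return(TRUE)       # on an edge
    ang <- ang + atan2(cr, dt)
  }
  abs(ang) > pi
}

random_spd <- function(L) {
  A <- matrix(rnorm(L * L), L)
  crossprod(A) + diag(0.5, L)
}

# convex simple polygon from random points (row, col)
random_convex_polygon <- function(n_pts, rows, cols, margin = 3) {
  pts <- cbind(runif(n_pts, 1 + margin, rows - margin),
               runif(n_pts, 1 + margin, cols - margin))
  hull <- chull(pts[, 2L], pts[, 1L])
  pts[hull, , drop = FALSE]
}

# tiny cohort defaults used across tests: reduced geometry, deterministic
tiny_scene <- function(L = 16L) phantom_scene(rows = 64L, cols = 48L, L = L)
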