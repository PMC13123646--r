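#' Median and interquartile range
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @param method Quantile definition: `"linear"` (default; interpolation
#'   at positions `p*(n-1)`, R type 7), `"spss"` (weighted average, SPSS
#'   default, R type 6), or `"tukey"` (R type 2).  The method used is
#'   recorded so reports never imply false precision.
#' @return Named vector `c(median, q1, q3)` with attribute `"method"`.
#' @export
median_iqr <- function(values, method = c("linear", "spss", "tukey")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("median_iqr: empty input")
  type <- switch(method, linear = 7L, spss = 6L, tukey = 2L)
  q <- stats::quantile(v, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  structure(c(median = q[1L], q1 = q[2L], q3 = q[3L]), method = method)
}

# exact null distribution of W+ for signed ranks `r` (possibly tied ->
# half-integer average ranks).  Dynamic program over doubled ranks; exact
# for ties and equivalent to full 2^n sign enumeration.
signrank_exact_p <- function(w_plus, ranks, alternative) {
  r2 <- round(ranks * 2)           # average ranks are multiples of 1/2
  tot <- sum(r2)
  # f[s+1] = number of sign assignments with doubled W+ == s
  f <- numeric(tot + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(tot + 1L)] <- g[(r + 1L):(tot + 1L)] + f[1L:(tot + 1L - r)]
    f <- g
  }
  total <- 2^length(r2)
  w2 <- round(w_plus * 2)
  p_ge <- sum(f[(w2 + 1L):(tot + 1L)]) / total
  p_le <- sum(f[1L:(w2 + 1L)]) / total
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the classic signed-rank convention;
#' `zero_method = "pratt"` ranks them first and then discards their
#' ranks); ties receive average ranks.  The p-value is exact — computed
#' from the full null distribution of W+ over all sign assignments, which
#' the tie-aware count-vector dynamic program enumerates — for effective
#' n up to `exact_limit` (default 25), and a normal approximation with
#' tie correction and continuity correction beyond.
#'
#' @param pre,post Equal-length paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (post > pre in
#'   terms of positive `post - pre`... the statistic is W+ of
#'   `post - pre`), or `"less"`.
#' @param zero_method `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit Largest effective n for the exact path.
#' @return List: `statistic` (W+), `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 zero_method = c("wilcoxon", "pratt"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  stopifnot(length(pre) == length(post))
  keep <- !(is.na(pre) | is.na(post))
  d <- (post - pre)[keep]
  if (length(d) == 0L || all(d == 0)) {
    stop("wilcoxon_signed_rank: all paired differences are zero")
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
  } else {
    ranks_all <- rank(abs(d))
    ranks <- ranks_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_plus <- sum(ranks[d > 0])
  if (n <= exact_limit) {
    p <- signrank_exact_p(w_plus, ranks, alternative)
    method <- "exact"
  } else {
    mu <- sum(ranks) / 2
    # tie-corrected variance of W+; with average ranks sum(ranks^2)
    # carries the tie correction automatically
    sigma2 <- sum(ranks^2) / 4
    z_num <- w_plus - mu
    cc <- 0.5
    z <- switch(alternative,
                two.sided = (abs(z_num) - cc) / sqrt(sigma2),
                greater = (z_num - cc) / sqrt(sigma2),
                less = (z_num + cc) / sqrt(sigma2))
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, max(0, p))
    method <- "normal"
  }
  list(statistic = w_plus, p_value = p, n_effective = n, method = method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties, Pearson correlation of the ranks, two-sided p
#' from `t = rho * sqrt((n-2) / (1-rho^2))` on n-2 degrees of freedom
#' (p = 0 at |rho| = 1).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman_rho: need at least 3 complete pairs")
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("spearman_rho: correlation undefined for a constant argument")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

# sign conventions: positive delta always means improvement
.delta_conventions <- c(
  roi_syn_area_px = "pre_minus_post", pd_area_px = "pre_minus_post",
  das28 = "pre_minus_post", esr_mm_per_h = "pre_minus_post",
  crp_mg_per_dl = "pre_minus_post",
  intra_hsisas = "post_minus_pre", inter_hsisas = "post_minus_pre")

#' Improvement-oriented treatment deltas
#'
#' Converts a wrist-level cohort table (long over visits) into one row per
#' wrist of improvement-oriented changes: `pre - post` for variables
#' expected to decrease under effective treatment (synovial area, PD
#' area, DAS28, ESR, CRP) and `post - pre` for the abundance scores, so
#' a positive delta always means improvement.  DAS28 is patient-level:
#' its delta is computed once per subject and assigned to both wrists;
#' wrists whose subject lacks either DAS28 visit get NA in the DAS28
#' column only.
#'
#' @param table Data.frame with columns `subject_id`, `hand`, `visit`
#'   (`"pre"`/`"post"`) and any of the measurement columns named in the
#'   conventions above.  Wrists missing a visit are dropped with a
#'   warning.
#' @return Data.frame with one row per wrist: subject_id, hand, and
#'   `d_<variable>` columns.
#' @export
improvement_deltas <- function(table) {
  stopifnot(all(c("subject_id", "hand", "visit") %in% names(table)))
  vars <- intersect(names(.delta_conventions), names(table))
  if (length(vars) == 0L) stop("no known measurement columns in table")
  key <- unique(table[table$visit %in% c("pre", "post"),
                      c("subject_id", "hand")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    s <- key$subject_id[i]; h <- key$hand[i]
    pre <- table[table$subject_id == s & table$hand == h &
                   table$visit == "pre", , drop = FALSE]
    post <- table[table$subject_id == s & table$hand == h &
                    table$visit == "post", , drop = FALSE]
    if (nrow(pre) != 1L || nrow(post) != 1L) {
      warning(sprintf("wrist %s/%s lacks a visit; excluded", s, h))
      return(NULL)
    }
    out <- data.frame(subject_id = s, hand = h, stringsAsFactors = FALSE)
    for (v in vars) {
      conv <- .delta_conventions[[v]]
      out[[paste0("d_", v)]] <- if (conv == "pre_minus_post") {
        pre[[v]] - post[[v]]
      } else post[[v]] - pre[[v]]
    }
    out
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) stop("no complete wrists")
  res
}

#' Cohort summary and correlation report
#'
#' Emits (i) a pre/post summary table — per variable the median (q1, q3)
#' at each visit and the two-sided Wilcoxon signed-rank p over paired
#' wrists (patient-level variables such as DAS28 are paired at patient
#' level; their n is reported separately) — and (ii) a Spearman
#' correlation matrix over the improvement-oriented deltas with
#' significance stars at p < 0.05 (*) and p < 0.01 (**).  Two wrists of
#' one subject are treated as independent observations; that modelling
#' simplification is stated in the report notes.  No multiple-testing
#' correction is applied (per-test alpha); a Holm-adjusted column can be
#' added.
#'
#' @param table Wrist-level cohort data.frame as in
#'   [improvement_deltas()].
#' @param quantile_method Passed to [median_iqr()].
#' @param holm Also emit Holm-adjusted p-values (default FALSE).
#' @return List of class `cohort_report`: `summary` (data.frame),
#'   `spearman` (rho matrix), `spearman_p`, `spearman_stars`, `deltas`,
#'   `notes`.
#' @export
paper_tables <- function(table, quantile_method = "linear", holm = FALSE) {
  vars <- intersect(names(.delta_conventions), names(table))
  patient_level <- "das28"
  summary_rows <- list()
  for (v in vars) {
    sub <- table[!is.na(table[[v]]), c("subject_id", "hand", "visit", v)]
    if (v %in% patient_level) {
      sub <- sub[!duplicated(sub[, c("subject_id", "visit")]), ]
      sub$hand <- "P"
    }
    pre <- sub[sub$visit == "pre", ]
    post <- sub[sub$visit == "post", ]
    merged <- merge(pre, post, by = c("subject_id", "hand"),
                    suffixes = c("_pre", "_post"))
    if (nrow(merged) < 3L) {
      warning("variable ", v, " has fewer than 3 complete pairs; skipped")
      next
    }
    mi_pre <- median_iqr(merged[[paste0(v, "_pre")]], quantile_method)
    mi_post <- median_iqr(merged[[paste0(v, "_post")]], quantile_method)
    p <- tryCatch(
      wilcoxon_signed_rank(merged[[paste0(v, "_pre")]],
                           merged[[paste0(v, "_post")]])$p_value,
      error = function(e) NA_real_)
    summary_rows[[v]] <- data.frame(
      variable = v, n_pairs = nrow(merged),
      pre_median = mi_pre[["median"]], pre_q1 = mi_pre[["q1"]],
      pre_q3 = mi_pre[["q3"]],
      post_median = mi_post[["median"]], post_q1 = mi_post[["q1"]],
      post_q3 = mi_post[["q3"]],
      p_value = p, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  if (holm && !is.null(summary)) {
    summary$p_holm <- stats::p.adjust(summary$p_value, "holm")
  }

  deltas <- improvement_deltas(table)
  dvars <- grep("^d_", names(deltas), value = TRUE)
  k <- length(dvars)
  rho <- pmat <- matrix(NA_real_, k, k, dimnames = list(dvars, dvars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    res <- tryCatch(spearman_rho(deltas[[dvars[i]]], deltas[[dvars[j]]]),
                    error = function(e) NULL)
    if (!is.null(res)) {
      rho[i, j] <- res$rho
      pmat[i, j] <- res$p_value
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(rho))
  stars[!is.na(pmat) & pmat < 0.05] <- "*"
  stars[!is.na(pmat) & pmat < 0.01] <- "**"
  structure(list(
    summary = summary, spearman = rho, spearman_p = pmat,
    spearman_stars = stars, deltas = deltas,
    notes = c(paste("wrist-level observations; within-subject dependence",
                    "of the two wrists is not modelled"),
              paste("quantile method:", quantile_method),
              "no multiple-testing correction (per-test alpha = 0.05)")),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Pre/post summary (median (q1, q3), Wilcoxon signed-rank p):\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  cat("\nSpearman rho over improvement-oriented deltas:\n")
  disp <- matrix(paste0(format(round(x$spearman, 3)), x$spearman_stars),
                 nrow(x$spearman), dimnames = dimnames(x$spearman))
  diag(disp) <- "-"
  print(disp, quote = FALSE)
  cat("\nNotes:\n")
  for (n in x$notes) cat(" -", n, "\n")
  invisible(x)
}
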