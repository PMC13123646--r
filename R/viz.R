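#' Mean +/- 1 SD spectra of two pixel pools
#'
#' Computes per-band mean and standard deviation over each pool and, when
#' `file` is given, draws the two curves with shaded +/-1 SD bands over
#' the wavelength axis.  The computed statistics are returned so callers
#' (and tests) never need to parse the figure.
#'
#' @param pre_pool,post_pool n x L matrices of pixel spectra.
#' @param axis A [spectral_axis()].
#' @param file Optional figure path (pdf).
#' @return Invisibly, a list with `wavelengths_nm`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`.
#' @export
plot_mean_spectra <- function(pre_pool, post_pool, axis, file = NULL) {
  pre_pool <- as.matrix(pre_pool); post_pool <- as.matrix(post_pool)
  if (nrow(pre_pool) == 0L || nrow(post_pool) == 0L) stop("empty pool")
  stats_of <- function(S) list(mean = colMeans(S),
                               sd = apply(S, 2L, stats::sd))
  a <- stats_of(pre_pool); b <- stats_of(post_pool)
  wl <- axis$wavelengths_nm
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    ylim <- range(a$mean - a$sd, a$mean + a$sd, b$mean - b$sd,
                  b$mean + b$sd)
    graphics::plot(wl, a$mean, type = "n", ylim = ylim,
                   xlab = "wavelength (nm)", ylab = "reflectance",
                   main = "Mean wrist spectra (+/- 1 SD)")
    graphics::polygon(c(wl, rev(wl)), c(a$mean - a$sd, rev(a$mean + a$sd)),
                      col = grDevices::adjustcolor("red", 0.25), border = NA)
    graphics::polygon(c(wl, rev(wl)), c(b$mean - b$sd, rev(b$mean + b$sd)),
                      col = grDevices::adjustcolor("forestgreen", 0.25),
                      border = NA)
    graphics::lines(wl, a$mean, col = "red", lwd = 2)
    graphics::lines(wl, b$mean, col = "forestgreen", lwd = 2)
    graphics::legend("bottomleft", c("pre", "post"),
                     col = c("red", "forestgreen"), lwd = 2, bty = "n")
  }
  invisible(list(wavelengths_nm = wl, pre_mean = a$mean, pre_sd = a$sd,
                 post_mean = b$mean, post_sd = b$sd))
}

#' Red-to-green rendering of an abundance map
#'
#' Scores are clipped to \[0, 1\] for display only and mapped linearly
#' from red (0, severe) to green (1, mild); off-ROI pixels show the
#' 1303-nm band of the backdrop cube as grayscale when supplied, black
#' otherwise.  Written as an ASCII PPM when `file` is given.
#'
#' @param map An `abundance_map`.
#' @param cube Optional [reflectance_cube()] backdrop.
#' @param file Optional output path (`.ppm`).
#' @return Invisibly, the rows x cols x 3 RGB array (0--255).
#' @export
render_abundance_map <- function(map, cube = NULL, file = NULL) {
  stopifnot(inherits(map, "abundance_map"))
  s <- map$scores
  nr <- nrow(s); nc <- ncol(s)
  back <- if (!is.null(cube)) {
    b <- cube$data[, , nearest_band(cube$axis, 1303)]
    255 * (b - min(b)) / max(max(b) - min(b), 1e-12)
  } else matrix(0, nr, nc)
  rgb <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) rgb[, , ch] <- back
  roi <- !is.na(s)
  sc <- pmin(pmax(s[roi], 0), 1)
  rgb[, , 1L][roi] <- 255 * (1 - sc)
  rgb[, , 2L][roi] <- 255 * sc
  rgb[, , 3L][roi] <- 0
  rgb <- round(rgb)
  if (!is.null(file)) write_pnm(rgb, file)
  invisible(rgb)
}

#' 2-D projection of intra vs inter scores
#'
#' Scatter of (intra_score, inter_score) per wrist, pre vs post in
#' distinct markers, plus the two group centroids and a separation
#' statistic (centroid distance over pooled within-group SD; an artifact
#' addition, reported alongside the figure rather than read off it).
#'
#' @param records Score-record data.frame from [score_cohort()].
#' @param file Optional figure path (pdf).
#' @return Invisibly, list with `centroids` (matrix), `separation`
#'   (NA when only one visit group is present).
#' @export
plot_projection <- function(records, file = NULL) {
  stopifnot(all(c("intra_score", "inter_score", "visit") %in%
                  names(records)))
  groups <- split(records[, c("intra_score", "inter_score")],
                  records$visit)
  centroids <- t(vapply(groups, colMeans, numeric(2)))
  separation <- NA_real_
  if (length(groups) == 2L) {
    pooled_var <- mean(unlist(lapply(groups, function(g)
      c(stats::var(g$intra_score), stats::var(g$inter_score)))),
      na.rm = TRUE)
    dist <- sqrt(sum((centroids[1L, ] - centroids[2L, ])^2))
    separation <- dist / max(sqrt(pooled_var), 1e-12)
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 6)
    on.exit(grDevices::dev.off())
    cols <- c(pre = "red", post = "forestgreen")
    pchs <- c(pre = 1, post = 17)
    graphics::plot(records$intra_score, records$inter_score,
                   col = cols[records$visit], pch = pchs[records$visit],
                   xlab = "Intra score", ylab = "Inter score",
                   main = "Intra/Inter abundance-score projection")
    graphics::points(centroids[, 1L], centroids[, 2L], pch = 3, cex = 2,
                     col = cols[rownames(centroids)])
    graphics::legend("topleft", rownames(centroids),
                     col = cols[rownames(centroids)],
                     pch = pchs[rownames(centroids)], bty = "n")
  }
  invisible(list(centroids = centroids, separation = separation))
}

# small stable FNV-1a hash of a serialized R object, for config
# provenance in reports
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply in 16-bit halves (doubles lose bits past 2^53)
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline on a synthetic (or loaded) cohort
#'
#' calibrate -> band-ratio/Otsu segmentation -> wrist ROI extraction ->
#' intra/inter correlation matrices -> CEM scoring -> cohort statistics
#' -> optional figures.  Deterministic: identical cohort and options give
#' byte-identical CSV outputs.  Every report embeds the resolved option
#' hash, correlation mode, ridge lambdas, target scope and reducer.
#'
#' @param cohort Output of [generate_cohort()] (cube-based or
#'   `spectra_only`).
#' @param out_dir Output directory; created if missing.
#' @param corr_mode,reducer,ridge_lambda Passed to [score_cohort()].
#' @param extension_rows Wrist-band height (default 100).
#' @param figures Also write figures/renders (default FALSE).
#' @return Invisibly, list with `records`, `report`, `table`, `files`.
#' @export
run_pipeline <- function(cohort, out_dir, corr_mode = "cem",
                         reducer = "mean", ridge_lambda = "auto",
                         extension_rows = 100L, figures = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- list(corr_mode = corr_mode, reducer = reducer,
               ridge_lambda = ridge_lambda,
               extension_rows = extension_rows,
               target_scope = c(intra = "subject", inter = "cohort"),
               seed = cohort$seed)
  log_line <- function(...) message(sprintf("[hsisas] %s", sprintf(...)))

  rois <- list()
  for (sid in names(cohort$subjects)) {
    subj <- cohort$subjects[[sid]]
    if (isTRUE(cohort$spectra_only)) {
      rois[[sid]] <- subj$rois
      next
    }
    rois[[sid]] <- list(pre = list(), post = list())
    for (visit in c("pre", "post")) {
      for (hand in names(subj$cubes[[visit]])) {
        refl <- calibrate(subj$cubes[[visit]][[hand]], subj$white,
                          subj$dark)
        mask <- segment_hand(band_ratio(refl))
        rois[[sid]][[visit]][[hand]] <- extract_wrist_roi(
          refl, mask, subj$wrist_row, extension_rows)
      }
      log_line("segmented %s/%s (%d+%d px)", sid, visit,
               rois[[sid]][[visit]][[1L]]$n,
               if (length(rois[[sid]][[visit]]) > 1L)
                 rois[[sid]][[visit]][[2L]]$n else 0L)
    }
  }

  records <- score_cohort(rois, corr_mode = corr_mode, reducer = reducer,
                          ridge_lambda = ridge_lambda)
  table <- merge(records, cohort$clinical,
                 by = c("subject_id", "hand", "visit"), all.x = TRUE)
  names(table)[names(table) == "intra_score"] <- "intra_hsisas"
  names(table)[names(table) == "inter_score"] <- "inter_hsisas"
  table <- table[order(table$subject_id, table$hand, table$visit), ]
  report <- paper_tables(table)

  meta <- c(sprintf("config_hash=%s", config_hash(opts)),
            sprintf("corr_mode=%s", corr_mode),
            sprintf("reducer=%s", reducer),
            sprintf("target_scope_intra=subject"),
            sprintf("target_scope_inter=cohort"),
            sprintf("lambda_intra=%.6g", records$lambda_intra[1L]),
            sprintf("lambda_inter=%.6g", records$lambda_inter[1L]))
  files <- list(
    scores = file.path(out_dir, "scores.csv"),
    table = file.path(out_dir, "cohort_table.csv"),
    summary = file.path(out_dir, "summary.csv"),
    spearman = file.path(out_dir, "spearman.csv"),
    deltas = file.path(out_dir, "deltas.csv"),
    meta = file.path(out_dir, "meta.txt"))
  write_csv_canonical <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 12,
                                                   format = "g"))
    utils::write.csv(df, path, row.names = FALSE)
  }
  write_csv_canonical(records, files$scores)
  write_csv_canonical(table, files$table)
  write_csv_canonical(report$summary, files$summary)
  utils::write.csv(data.frame(variable = rownames(report$spearman),
                              round(report$spearman, 10),
                              check.names = FALSE),
                   files$spearman, row.names = FALSE)
  write_csv_canonical(report$deltas, files$deltas)
  writeLines(c(meta, report$notes), files$meta)

  if (figures) {
    pre_pool <- do.call(rbind, unlist(lapply(rois, function(s)
      lapply(s$pre, `[[`, "spectra")), recursive = FALSE))
    post_pool <- do.call(rbind, unlist(lapply(rois, function(s)
      lapply(s$post, `[[`, "spectra")), recursive = FALSE))
    axis <- rois[[1L]]$pre[[1L]]$axis
    plot_mean_spectra(pre_pool, post_pool, axis,
                      file.path(out_dir, "mean_spectra.pdf"))
    plot_projection(records, file.path(out_dir, "projection.pdf"))
  }
  log_line("pipeline complete: %d records -> %s", nrow(records), out_dir)
  invisible(list(records = records, report = report, table = table,
                 rois = rois, files = files, options = opts))
}
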