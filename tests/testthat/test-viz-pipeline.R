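test_that("plot_mean_spectra returns per-band means and SDs", {
  ax <- spectral_axis(seq(900, 1700, length.out = 5))
  set.seed(111)
  pool <- matrix(runif(40 * 5), 40)
  same <- plot_mean_spectra(pool, pool, ax)
  expect_equal(same$pre_mean, same$post_mean)
  expect_equal(same$pre_sd, same$post_sd)
  const <- matrix(rep(0.5, 10 * 5), 10)
  expect_equal(plot_mean_spectra(const, pool, ax)$pre_sd, rep(0, 5))
  expect_error(plot_mean_spectra(pool[0, ], pool, ax), "empty")
  f <- tempfile(fileext = ".pdf")
  plot_mean_spectra(pool, pool + 0.1, ax, file = f)
  expect_true(file.size(f) > 0)
})

test_that("cohort mean-spectra difference peaks at the inflammation
           band", {
  co <- generate_cohort(m = 4, scene = tiny_scene(64L), seed = 112,
                        spectra_only = TRUE)
  pre <- do.call(rbind, lapply(co$subjects, function(s)
    rbind(s$rois$pre$L$spectra, s$rois$pre$R$spectra)))
  post <- do.call(rbind, lapply(co$subjects, function(s)
    rbind(s$rois$post$L$spectra, s$rois$post$R$spectra)))
  st <- plot_mean_spectra(pre, post, co$scene$axis)
  wl_max <- st$wavelengths_nm[which.max(abs(st$post_mean - st$pre_mean))]
  expect_lt(abs(wl_max - 1250), 40)
})

test_that("abundance maps render red to green with a grayscale backdrop", {
  ax <- spectral_axis(seq(900, 1700, length.out = 4))
  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  mk_map <- function(val) {
    s <- matrix(NA_real_, 3, 3); s[2, 2] <- val
    structure(list(scores = s, values = val, kind = "intra",
                   corr_mode = "cem", lambda = 0),
              class = "abundance_map")
  }
  expect_equal(render_abundance_map(mk_map(1))[2, 2, ], c(0, 255, 0))
  expect_equal(render_abundance_map(mk_map(0))[2, 2, ], c(255, 0, 0))
  expect_equal(render_abundance_map(mk_map(0.5))[2, 2, ],
               c(round(127.5), round(127.5), 0))
  # display clipping only: scores beyond [0, 1] saturate
  expect_equal(render_abundance_map(mk_map(3))[2, 2, ], c(0, 255, 0))
  f <- tempfile(fileext = ".ppm")
  rgb <- render_abundance_map(mk_map(0.25), file = f)
  expect_equal(read_pnm(f), rgb)
})

test_that("pnm round-trips grayscale and rgb images", {
  set.seed(113)
  g <- matrix(sample(0:255, 35, TRUE), 5, 7)
  f <- tempfile(fileext = ".pgm")
  write_pnm(g, f)
  expect_equal(read_pnm(f), g)
  rgbim <- array(sample(0:255, 60, TRUE), c(4, 5, 3))
  f2 <- tempfile(fileext = ".ppm")
  write_pnm(rgbim, f2)
  expect_equal(read_pnm(f2), rgbim)
})

test_that("projection statistics summarize group separation", {
  rec <- data.frame(
    visit = rep(c("pre", "post"), each = 4),
    intra_score = c(rnorm(4, 0.2, 0.02), rnorm(4, 0.9, 0.02)),
    inter_score = c(rnorm(4, 0.5, 0.02), rnorm(4, 0.95, 0.02)))
  pr <- plot_projection(rec)
  expect_true(all(pr$centroids["post", ] > pr$centroids["pre", ]))
  expect_gt(pr$separation, 1)
  one <- plot_projection(rec[rec$visit == "pre", ])
  expect_true(is.na(one$separation))
  # duplicated records leave centroids and separation unchanged
  dup <- plot_projection(rbind(rec, rec))
  expect_equal(dup$centroids, pr$centroids)
})

test_that("run_pipeline is deterministic and fully populated", {
  co <- generate_cohort(m = 3, scene = phantom_scene(rows = 64L,
                                                     cols = 48L, L = 24L),
                        seed = 114)
  d1 <- file.path(tempdir(), "pipe1")
  d2 <- file.path(tempdir(), "pipe2")
  r1 <- suppressMessages(run_pipeline(co, d1))
  r2 <- suppressMessages(run_pipeline(co, d2))
  for (f in c("scores.csv", "cohort_table.csv", "summary.csv",
              "spearman.csv", "deltas.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_identical(nrow(r1$records), 12L)
  s <- r1$report$summary
  expect_true(all(c("intra_hsisas", "inter_hsisas", "das28",
                    "esr_mm_per_h", "crp_mg_per_dl") %in% s$variable))
  expect_true(all(is.finite(s$p_value)))
  meta <- readLines(file.path(d1, "meta.txt"))
  expect_true(any(grepl("config_hash=", meta)))
  expect_true(any(grepl("corr_mode=cem", meta)))
})

test_that("the cli dispatches pdus quantification end to end", {
  fix <- generate_pdus_fixture(rbind(c(5, 5), c(5, 60), c(50, 60),
                                     c(50, 5)),
                               blob_areas = 80L, shape = c(60L, 70L),
                               seed = 115)
  img <- tempfile(fileext = ".ppm")
  write_pnm(fix$frame$rgb, img)
  roi_csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(row = fix$roi$polygon[, 1],
                              col = fix$roi$polygon[, 2]),
                   roi_csv, row.names = FALSE)
  out <- capture.output(
    hsisas_cli(c("pdus", "--image", img, "--roi", roi_csv,
                 "--mode", "reddom", "--threshold", "0")))
  expect_match(out, "pd_area_px=80")
  expect_identical(hsisas_cli(character(0)), 1L)
  expect_error(hsisas_cli(c("nope")), "unknown subcommand")
})
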