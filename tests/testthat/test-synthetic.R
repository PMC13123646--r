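test_that("generation is a pure function of the seed", {
  scene <- tiny_scene()
  a <- generate_subject(spectral_model(), scene, seed = 91)
  b <- generate_subject(spectral_model(), scene, seed = 91)
  expect_identical(a$cubes$pre$L$data, b$cubes$pre$L$data)
  expect_identical(a$cubes$post$R$data, b$cubes$post$R$data)
  c <- generate_subject(spectral_model(), scene, seed = 92)
  expect_false(identical(a$cubes$pre$L$data, c$cubes$pre$L$data))
})

test_that("calibration recovers the noiseless reflectance field", {
  scene <- tiny_scene()
  model <- spectral_model()
  subj <- generate_subject(model, scene, seed = 93)
  refl <- calibrate(subj$cubes$pre$L, subj$white, subj$dark)
  err <- abs(refl$data - subj$truth$reflectance$pre$L)
  # clipping at 0 censors a few negative noise excursions on dark pixels
  expect_gte(mean(err <= 4 * model$noise_sd_pixel), 0.9999)
})

test_that("null model leaves pre/post mean spectra within noise", {
  scene <- tiny_scene()
  model <- spectral_model(treatment_delta = 0)
  subj <- generate_subject(model, scene, seed = 94)
  mask <- subj$truth$hand_masks$L
  pre <- calibrate(subj$cubes$pre$L, subj$white, subj$dark)
  post <- calibrate(subj$cubes$post$L, subj$white, subj$dark)
  flat_pre <- matrix(pre$data, ncol = scene$axis$L)[mask, ]
  flat_post <- matrix(post$data, ncol = scene$axis$L)[mask, ]
  dbar <- abs(colMeans(flat_post) - colMeans(flat_pre))
  expect_true(all(dbar < 3 * model$noise_sd_pixel / sqrt(sum(mask))
                  + 1e-12))
})

test_that("the treatment effect is maximal at the inflammation band", {
  scene <- tiny_scene(64L)
  subj <- generate_subject(spectral_model(treatment_delta = 0.1), scene,
                           seed = 95)
  mask <- subj$truth$hand_masks$L
  pre <- calibrate(subj$cubes$pre$L, subj$white, subj$dark)
  post <- calibrate(subj$cubes$post$L, subj$white, subj$dark)
  flat_pre <- matrix(pre$data, ncol = scene$axis$L)[mask, ]
  flat_post <- matrix(post$data, ncol = scene$axis$L)[mask, ]
  dbar <- abs(colMeans(flat_post) - colMeans(flat_pre))
  wl_max <- scene$axis$wavelengths_nm[which.max(dbar)]
  expect_lt(abs(wl_max - 1250), 40)
})

test_that("hand and board separate in the 1303/1453 band ratio", {
  scene <- tiny_scene()
  subj <- generate_subject(spectral_model(noise_sd_pixel = 0), scene,
                           seed = 96)
  refl <- calibrate(subj$cubes$pre$L, subj$white, subj$dark)
  ratio <- band_ratio(refl)$data
  mask <- subj$truth$hand_masks$L
  expect_gt(mean(ratio[mask]) / mean(ratio[!mask]), 1.5)
})

test_that("cohort manifest has the stated shape and DAS28 exclusions", {
  co <- generate_cohort(m = 11, scene = tiny_scene(8L), seed = 97,
                        spectra_only = TRUE)
  expect_length(co$subjects, 11L)
  expect_identical(nrow(co$clinical), 44L)
  expect_identical(sum(co$clinical$visit == "pre"), 22L)
  # das28 identical across hands within subject and visit
  by_sv <- split(co$clinical$das28,
                 paste(co$clinical$subject_id, co$clinical$visit))
  expect_true(all(vapply(by_sv, function(v)
    length(unique(v)) == 1L, logical(1))))
  co2 <- generate_cohort(m = 10, scene = tiny_scene(8L), seed = 98,
                         spectra_only = TRUE, missing_das28_fraction = 0.3)
  expect_identical(sum(is.na(co2$clinical$das28)), 3L * 4L)
  # missing-DAS28 subjects still appear in score analyses
  tab <- merge(score_cohort(lapply(co2$subjects, `[[`, "rois")),
               co2$clinical, by = c("subject_id", "hand", "visit"))
  names(tab)[names(tab) == "intra_score"] <- "intra_hsisas"
  rep <- paper_tables(tab)
  expect_identical(rep$summary$n_pairs[rep$summary$variable == "das28"],
                   7L)
  expect_identical(
    rep$summary$n_pairs[rep$summary$variable == "intra_hsisas"], 20L)
})

test_that("mean intra-score improvement is monotone in the treatment
           effect", {
  deltas <- c(0, 0.05, 0.15)
  mean_improvement <- vapply(deltas, function(dl) {
    co <- generate_cohort(m = 4, model = spectral_model(treatment_delta = dl),
                          scene = tiny_scene(32L), seed = 99,
                          spectra_only = TRUE)
    rec <- score_cohort(lapply(co$subjects, `[[`, "rois"))
    mean(rec$intra_score[rec$visit == "post"]) -
      mean(rec$intra_score[rec$visit == "pre"])
  }, numeric(1))
  expect_true(all(diff(mean_improvement) >= 0))
})

test_that("painted fixtures carry their exact ground truth", {
  poly <- rbind(c(10, 10), c(10, 120), c(100, 120), c(100, 10))
  fix <- generate_pdus_fixture(poly, blob_areas = c(120L, 45L), seed = 100)
  expect_identical(fix$pd_truth_px, 165L)
  expect_identical(
    as.integer(pd_area(red_gray(fix$frame, "reddom"), fix$roi, 0)), 165L)
  empty <- generate_pdus_fixture(poly, blob_areas = integer(0), seed = 101)
  expect_identical(
    as.integer(pd_area(red_gray(empty$frame, "reddom"), empty$roi, 0)), 0L)
  expect_error(generate_pdus_fixture(poly, blob_areas = 100000L),
               "fit")
})
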