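#' Spectral model for the synthetic SWIR cohort
#'
#' Reflectance is a low-order polynomial baseline minus Gaussian
#' absorption bands.  Defaults encode the tissue features the method
#' exploits: water absorption near 970, 1190 and 1450 nm, plus an
#' inflammation-modulated band near 1250 nm whose amplitude *increases*
#' after treatment (post-treatment reflectance near 1250 nm is lower, the
#' direction observed clinically).  `treatment_delta` is the mean
#' amplitude added to the 1250-nm band between visits; each subject
#' scales it by a lognormal random effect so treatment response is
#' heterogeneous and recoverable in correlation analyses.
#'
#' @param treatment_delta Mean post-pre amplitude change of the 1250-nm
#'   band (reflectance units; default 0.10, a clearly visible dip).
#' @param noise_sd_pixel Additive Gaussian pixel noise SD in reflectance
#'   units (default 0.02, a realistic SWIR detector level).
#' @param noise_sd_subject SD of the subject-level lognormal brightness
#'   factor (default 0.05).
#' @param effect_sdlog SD (log scale) of the subject treatment-response
#'   multiplier (default 0.35).
#' @param baseline_coef Polynomial coefficients over
#'   `t = (lambda - 1300)/400`.
#' @param bands Data.frame of fixed absorption bands
#'   (center_nm, width_nm, amplitude).
#' @param inflammation Center/width/base amplitude of the treatment-
#'   modulated band.
#' @return A `spectral_model` list.
#' @export
spectral_model <- function(treatment_delta = 0.10,
                           noise_sd_pixel = 0.02,
                           noise_sd_subject = 0.05,
                           effect_sdlog = 0.35,
                           baseline_coef = c(0.55, -0.08, -0.05),
                           bands = data.frame(
                             center_nm = c(970, 1190, 1450),
                             width_nm = c(30, 40, 45),
                             amplitude = c(0.08, 0.10, 0.35)),
                           inflammation = list(center_nm = 1250,
                                               width_nm = 35,
                                               amplitude = 0.05)) {
  structure(list(treatment_delta = treatment_delta,
                 noise_sd_pixel = noise_sd_pixel,
                 noise_sd_subject = noise_sd_subject,
                 effect_sdlog = effect_sdlog,
                 baseline_coef = baseline_coef, bands = bands,
                 inflammation = inflammation),
            class = "spectral_model")
}

gaussian_band <- function(wl, center, width, amp) {
  amp * exp(-(wl - center)^2 / (2 * width^2))
}

# noiseless tissue spectrum for a given extra inflammation-band amplitude
model_spectrum <- function(model, wl, inflammation_extra = 0) {
  t <- (wl - 1300) / 400
  s <- outer(t, seq_along(model$baseline_coef) - 1L, `^`) %*%
    model$baseline_coef
  s <- drop(s)
  for (i in seq_len(nrow(model$bands))) {
    s <- s - gaussian_band(wl, model$bands$center_nm[i],
                           model$bands$width_nm[i],
                           model$bands$amplitude[i])
  }
  s <- s - gaussian_band(wl, model$inflammation$center_nm,
                         model$inflammation$width_nm,
                         model$inflammation$amplitude + inflammation_extra)
  pmin(pmax(s, 0), 1.5)
}

# flat green-board background: high 1303/1453 contrast against tissue
board_spectrum <- function(wl) {
  s <- rep(0.45, length(wl)) -
    gaussian_band(wl, 1450, 45, 0.06) -
    gaussian_band(wl, 970, 30, 0.02) -
    gaussian_band(wl, 1190, 40, 0.02)
  pmin(pmax(s, 0), 1.5)
}

#' Phantom scene geometry
#'
#' A stylized hand silhouette (palm, three fingers, forearm) rasterized
#' on a flat board, plus the operator wrist row.  The default reduced
#' geometry (96 x 64 pixels, 64 bands over 900--1700 nm) keeps tests at
#' desk scale; `full_size = TRUE` switches to the acquisition geometry
#' (635 x 640 pixels, 512 bands).
#'
#' @param rows,cols,L Scene geometry.
#' @param full_size Use the full acquisition geometry.
#' @return A `phantom_scene` list with `rows`, `cols`, `axis`,
#'   `hand_polygon` (template, unit palm coordinates scaled to the
#'   scene), `wrist_row`.
#' @export
phantom_scene <- function(rows = 96L, cols = 64L, L = 64L,
                          full_size = FALSE) {
  if (full_size) { rows <- 635L; cols <- 640L; L <- 512L }
  # hand template in unit coordinates (row 0 = finger tips, 1 = bottom)
  # palm spans rows .28-.62, fingers above, forearm below to the edge
  u <- rbind(
    c(0.62, 0.28), c(0.30, 0.28),               # palm left edge up
    c(0.06, 0.30), c(0.06, 0.42), c(0.28, 0.42), # finger 1
    c(0.06, 0.46), c(0.06, 0.58), c(0.28, 0.58), # finger 2
    c(0.06, 0.62), c(0.06, 0.74), c(0.30, 0.74), # finger 3
    c(0.34, 0.84), c(0.46, 0.90),                # thumb bump
    c(0.62, 0.74),                               # palm right edge
    c(0.62, 0.70), c(0.995, 0.68),               # forearm right
    c(0.995, 0.34), c(0.62, 0.32))               # forearm left
  poly <- cbind(1 + u[, 1L] * (rows - 1L), 1 + u[, 2L] * (cols - 1L))
  structure(list(rows = rows, cols = cols,
                 axis = spectral_axis(seq(900, 1700, length.out = L)),
                 hand_polygon = poly,
                 wrist_row = as.integer(round(0.64 * rows))),
            class = "phantom_scene")
}

# affine-jittered hand mask for one subject (deterministic in the RNG
# state at call time)
subject_hand_mask <- function(scene, jitter = TRUE) {
  poly <- scene$hand_polygon
  if (jitter) {
    ctr <- colMeans(poly)
    sc <- stats::runif(1, 0.95, 1.05)
    shift <- stats::runif(2, -2, 2)
    poly <- sweep(sweep(poly, 2L, ctr), 2L, c(sc, sc), `*`)
    poly <- sweep(poly, 2L, ctr + shift, `+`)
    poly[, 1L] <- pmin(pmax(poly[, 1L], 1), scene$rows)
    poly[, 2L] <- pmin(pmax(poly[, 2L], 1), scene$cols)
  }
  rasterize_roi(polygon = poly, shape = c(scene$rows, scene$cols))$mask
}

# build a raw counts cube from a per-pixel reflectance array so that
# calibrate(raw, white, dark) recovers reflectance + N(0, noise_sd)
counts_from_reflectance <- function(refl, white, dark, noise_sd) {
  gain <- white$data - dark$data
  noise <- array(stats::rnorm(length(refl), 0, noise_sd), dim = dim(refl))
  counts <- dark$data + (refl + noise) * gain
  counts[counts < 0] <- 0
  raw_cube(counts, white$axis)
}

#' Generate one synthetic subject
#'
#' Produces raw pre/post cubes for both hands plus shared white and dark
#' reference cubes, wrist coordinates and ground truth.  The pre and post
#' scenes differ only in the inflammation-band amplitude (the subject's
#' treatment effect) and fresh pixel noise; the subject brightness
#' factor, the smooth spatial gain field and the hand geometry are fixed
#' across visits, emulating a re-imaged wrist under the standardized rig.
#' Deterministic in `seed`.
#'
#' @param model A [spectral_model()].
#' @param scene A [phantom_scene()].
#' @param subject_id Identifier carried into the output.
#' @param seed Integer seed (fully determines the subject).
#' @return List with `cubes[[visit]][[hand]]` (raw cubes), `white`,
#'   `dark`, `wrist_row`, `truth` (hand masks per hand, noiseless
#'   reflectance spectra, subject effect `e_s`, brightness).
#' @export
generate_subject <- function(model, scene, subject_id = "S1", seed = 1L) {
  with_seed(seed, {
    wl <- scene$axis$wavelengths_nm
    L <- scene$axis$L
    e_s <- exp(stats::rnorm(1, 0, model$effect_sdlog))
    brightness <- exp(stats::rnorm(1, 0, model$noise_sd_subject))
    delta_s <- model$treatment_delta * e_s
    if (model$treatment_delta == 0) delta_s <- 0

    spec_pre <- model_spectrum(model, wl, 0)
    spec_post <- model_spectrum(model, wl, delta_s)
    if (any(spec_post <= 0 & spec_pre > 0)) {
      warning("treatment delta drove reflectance to zero; clipped")
    }
    spec_board <- board_spectrum(wl)

    dims <- c(scene$rows, scene$cols, L)
    dark <- raw_cube(array(100, dims), scene$axis)
    # mild smooth illumination falloff across track in the white frame
    illum <- 1 - 0.1 * ((seq_len(scene$cols) - scene$cols / 2) /
                          scene$cols)^2
    white <- raw_cube(
      aperm(array(rep(3000 * illum, scene$rows * L),
                  dim = c(scene$cols, scene$rows, L)), c(2L, 1L, 3L)) + 100,
      scene$axis)

    masks <- list(L = subject_hand_mask(scene),
                  R = subject_hand_mask(scene)[, scene$cols:1])
    # smooth per-subject tissue gain field, fixed across visits
    r0 <- stats::runif(1, 0.3, 0.7) * scene$rows
    c0 <- stats::runif(1, 0.3, 0.7) * scene$cols
    gf <- outer(seq_len(scene$rows), seq_len(scene$cols), function(r, c) {
      1 + 0.05 * exp(-((r - r0)^2 + (c - c0)^2) / (2 * (scene$rows / 3)^2))
    })

    build_field <- function(mask, spec) {
      fg <- as.numeric(mask) * brightness * as.numeric(gf)
      bg <- as.numeric(!mask)
      field <- outer(fg, spec) + outer(bg, spec_board)
      array(pmin(pmax(field, 0), 1.5), dim = dims)
    }
    cubes <- list(pre = list(), post = list())
    refl_truth <- list(pre = list(), post = list())
    for (hand in c("L", "R")) {
      fp <- build_field(masks[[hand]], spec_pre)
      fq <- build_field(masks[[hand]], spec_post)
      refl_truth$pre[[hand]] <- fp
      refl_truth$post[[hand]] <- fq
      cubes$pre[[hand]] <- counts_from_reflectance(fp, white, dark,
                                                   model$noise_sd_pixel)
      cubes$post[[hand]] <- counts_from_reflectance(fq, white, dark,
                                                    model$noise_sd_pixel)
    }
    list(subject_id = subject_id, cubes = cubes, white = white,
         dark = dark, wrist_row = scene$wrist_row,
         truth = list(hand_masks = masks, reflectance = refl_truth,
                      spectra = list(pre = spec_pre, post = spec_post,
                                     board = spec_board),
                      e_s = e_s, brightness = brightness))
  })
}

# ROI spectra for a subject without cube synthesis/segmentation: the same
# stochastic model, sampled directly under the true wrist band.  Used by
# replicate-heavy simulation studies where cube I/O would dominate.
generate_subject_spectra <- function(model, scene, subject_id, seed,
                                     n_per_hand = 400L) {
  with_seed(seed, {
    wl <- scene$axis$wavelengths_nm
    e_s <- exp(stats::rnorm(1, 0, model$effect_sdlog))
    brightness <- exp(stats::rnorm(1, 0, model$noise_sd_subject))
    delta_s <- if (model$treatment_delta == 0) 0 else
      model$treatment_delta * e_s
    spec_pre <- model_spectrum(model, wl, 0)
    spec_post <- model_spectrum(model, wl, delta_s)
    gain <- brightness * (1 + stats::runif(n_per_hand * 2L, -0.05, 0.05))
    make <- function(spec) {
      S <- outer(gain, spec)
      S + matrix(stats::rnorm(length(S), 0, model$noise_sd_pixel),
                 nrow(S), ncol(S))
    }
    split_roi <- function(S) {
      list(L = fake_roi(S[seq_len(n_per_hand), , drop = FALSE], scene$axis),
           R = fake_roi(S[n_per_hand + seq_len(n_per_hand), ,
                          drop = FALSE], scene$axis))
    }
    list(subject_id = subject_id, e_s = e_s,
         rois = list(pre = split_roi(make(spec_pre)),
                     post = split_roi(make(spec_post))))
  })
}

# wrap a bare spectra matrix as a wrist_roi (1 x n mask layout)
fake_roi <- function(S, axis) {
  n <- nrow(S)
  structure(list(mask = matrix(TRUE, 1L, n), wrist_row = 1L,
                 extension_rows = 1L, spectra = S,
                 pixel_index = seq_len(n), n = n, axis = axis),
            class = "wrist_roi")
}

#' Generate a synthetic cohort
#'
#' m subjects x two hands x two visits, with clinical covariates whose
#' pre-to-post improvement is coupled to each subject's spectral
#' treatment effect, so the association between abundance-score change
#' and DAS28 change is recoverable.  Defaults mirror the clinical
#' anchors: DAS28 median near 4.8 falling by about 0.5, ESR near
#' 31 mm/h, CRP near 1.5 mg/dL, over m = 11 subjects.
#'
#' @param m Number of subjects (default 11).
#' @param model A [spectral_model()].
#' @param scene A [phantom_scene()].
#' @param effect_on_clinical Coupling of the subject spectral effect to
#'   clinical improvement; list with per-variable mean improvements
#'   (applied x subject effect) and noise SDs.
#' @param missing_das28_fraction Fraction of subjects whose DAS28 is
#'   missing at one visit (exercises exclusion logic; default 0).
#' @param seed Integer seed.
#' @param spectra_only If TRUE, skip cube synthesis and return ROI
#'   spectra directly from the same stochastic model (fast path for
#'   replicate-heavy studies).
#' @return List: `subjects` (per-subject outputs), `clinical`
#'   (wrist-level data.frame with DAS28/ESR/CRP), `m`, `seed`.
#' @export
generate_cohort <- function(m = 11L, model = spectral_model(),
                            scene = phantom_scene(),
                            effect_on_clinical = list(
                              das28 = 0.5, esr = 12, crp = 1.0,
                              sd_das28 = 0.3, sd_esr = 8, sd_crp = 0.4),
                            missing_das28_fraction = 0,
                            seed = 1L, spectra_only = FALSE) {
  stopifnot(m >= 2L)
  subj_seeds <- with_seed(seed, sample.int(2^30, m))
  ids <- sprintf("S%02d", seq_len(m))
  subjects <- lapply(seq_len(m), function(i) {
    if (spectra_only) {
      generate_subject_spectra(model, scene, ids[i], subj_seeds[i])
    } else {
      generate_subject(model, scene, ids[i], subj_seeds[i])
    }
  })
  names(subjects) <- ids
  e_s <- vapply(subjects, function(s)
    if (spectra_only) s$e_s else s$truth$e_s, numeric(1))
  rel <- if (model$treatment_delta == 0) rep(0, m) else e_s

  clinical <- with_seed(seed + 7L, {
    das28_pre <- stats::rnorm(m, 4.8, 0.8)
    das28_post <- das28_pre - (effect_on_clinical$das28 * rel +
                                 stats::rnorm(m, 0, effect_on_clinical$sd_das28))
    esr_pre <- pmax(stats::rnorm(m, 31, 15), 2)
    esr_post <- pmax(esr_pre - (effect_on_clinical$esr * rel +
                                  stats::rnorm(m, 0, effect_on_clinical$sd_esr)), 1)
    crp_pre <- pmax(stats::rnorm(m, 1.5, 0.8), 0.05)
    crp_post <- pmax(crp_pre - (effect_on_clinical$crp * rel +
                                  stats::rnorm(m, 0, effect_on_clinical$sd_crp)), 0)
    missing <- rep(FALSE, m)
    if (missing_das28_fraction > 0) {
      missing[sample.int(m, round(missing_das28_fraction * m))] <- TRUE
    }
    rows <- list()
    for (i in seq_len(m)) for (hand in c("L", "R")) {
      for (visit in c("pre", "post")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = ids[i], hand = hand, visit = visit,
          das28 = if (missing[i]) NA_real_ else
            if (visit == "pre") das28_pre[i] else das28_post[i],
          esr_mm_per_h = if (visit == "pre") esr_pre[i] else esr_post[i],
          crp_mg_per_dl = if (visit == "pre") crp_pre[i] else crp_post[i],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  list(subjects = subjects, clinical = clinical, m = m, seed = seed,
       model = model, scene = scene, spectra_only = spectra_only)
}

#' Generate a painted power-Doppler fixture
#'
#' Gray speckle background (achromatic, so red-dominance is zero) with
#' pure-red blobs of exactly the requested pixel areas grown inside the
#' polygon by breadth-first region growth.
#'
#' @param polygon Synovial polygon, matrix of (row, col) vertices.
#' @param blob_areas Integer vector of exact blob pixel areas.
#' @param shape Frame c(rows, cols) (default 120 x 160).
#' @param speckle_level SD of the gray speckle (default 25).
#' @param seed Integer seed.
#' @return List: `frame` (an `ultrasound_frame`), `roi` (the rasterized
#'   `synovial_roi`), `pd_truth_px` (= sum of blob areas), `blob_mask`.
#' @export
generate_pdus_fixture <- function(polygon, blob_areas = c(120L, 45L),
                                  shape = c(120L, 160L),
                                  speckle_level = 25, seed = 1L) {
  roi <- rasterize_roi(polygon = polygon, shape = shape)
  with_seed(seed, {
    nr <- shape[1L]; nc <- shape[2L]
    gray <- matrix(pmin(pmax(stats::rnorm(nr * nc, 120, speckle_level),
                             0), 210), nr, nc)
    blob <- matrix(FALSE, nr, nc)
    avail <- roi$mask
    for (a in blob_areas) {
      if (a <= 0L) next
      if (sum(avail) < a) stop("blob does not fit inside the polygon")
      seeds <- which(avail)
      start <- seeds[sample.int(length(seeds), 1L)]
      grown <- start
      avail[start] <- FALSE
      while (length(grown) < a) {
        r <- (grown - 1L) %% nr + 1L
        cl <- (grown - 1L) %/% nr + 1L
        nb <- unique(c(grown[r > 1L] - 1L, grown[r < nr] + 1L,
                       grown[cl > 1L] - nr, grown[cl < nc] + nr))
        nb <- nb[avail[nb]]
        if (length(nb) == 0L) stop("blob growth blocked; does not fit")
        take <- nb[seq_len(min(length(nb), a - length(grown)))]
        avail[take] <- FALSE
        grown <- c(grown, take)
      }
      blob[grown] <- TRUE
    }
    rgb <- array(0, dim = c(nr, nc, 3L))
    for (ch in 1:3) rgb[, , ch] <- gray
    rgb[, , 1L][blob] <- 255
    rgb[, , 2L][blob] <- 0
    rgb[, , 3L][blob] <- 0
    list(frame = ultrasound_frame(round(rgb)), roi = roi,
         pd_truth_px = sum(blob), blob_mask = blob)
  })
}
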