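# Synthetic paired HQ/LQ CT slices: elliptical organ-like regions with
# field-realistic mean HU values on an air background, plus additive
# dose-dependent Gaussian noise. A statistical stand-in for paired
# high/low-dose scans, not a CT physics simulator (no sinogram domain,
# no beam hardening, no streaks).

#' Describe one elliptical organ region
#'
#' @param name organ label.
#' @param center length-2 numeric, (row, col) center as fractions of the
#'   image extent in `(0, 1)`.
#' @param semi_axes_mm length-2 numeric, semi-axes in mm (row, col), > 0.
#' @param rotation_deg rotation of the ellipse, degrees counter-clockwise.
#' @param mean_hu mean attenuation of the region, HU.
#' @param texture_sd within-organ HU standard deviation at full dose, >= 0.
#' @return An object of class `organ_spec`.
#' @export
organ_spec <- function(name, center, semi_axes_mm, rotation_deg = 0,
                       mean_hu = 0, texture_sd = 0) {
  center <- as.numeric(center); semi_axes_mm <- as.numeric(semi_axes_mm)
  stopifnot(length(center) == 2L, length(semi_axes_mm) == 2L)
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be > 0", call. = FALSE)
  if (texture_sd < 0) stop("`texture_sd` must be >= 0", call. = FALSE)
  structure(list(name = as.character(name), center = center,
                 semi_axes_mm = semi_axes_mm, rotation_deg = rotation_deg,
                 mean_hu = mean_hu, texture_sd = texture_sd),
            class = "organ_spec")
}

#' Default five-organ phantom layout
#'
#' A soft-tissue body disk (0 HU) carrying five organ regions whose mean HU
#' values are typical low-dose in-vivo levels for vitreous body (18.75),
#' brain parenchyma (45.50), liver (59.00), spleen (54.61) and paravertebral
#' muscle (52.12).
#'
#' @param fov_mm field of view the layout is scaled to, mm.
#' @param texture_sd within-organ HU variation applied to each organ.
#' @return List of [organ_spec()]; the body disk comes first so organs
#'   drawn later win on overlap.
#' @export
default_organs <- function(fov_mm = 350, texture_sd = 3) {
  f <- fov_mm
  list(
    organ_spec("body",     c(0.50, 0.50), c(0.45 * f, 0.45 * f), 0,  0,     texture_sd),
    organ_spec("vitreous", c(0.22, 0.35), c(0.080 * f, 0.080 * f), 0, 18.75, texture_sd),
    organ_spec("brain",    c(0.22, 0.62), c(0.110 * f, 0.085 * f), 20, 45.50, texture_sd),
    organ_spec("liver",    c(0.55, 0.32), c(0.150 * f, 0.110 * f), -15, 59.00, texture_sd),
    organ_spec("spleen",   c(0.55, 0.68), c(0.085 * f, 0.070 * f), 10, 54.61, texture_sd),
    organ_spec("muscle",   c(0.80, 0.50), c(0.065 * f, 0.170 * f), 0, 52.12, texture_sd)
  )
}

#' Dose-dependent additive noise model
#'
#' Additive zero-mean Gaussian noise in HU whose standard deviation follows
#' the quantum-noise heuristic `sigma(f) = sigma_full / sqrt(f)` for dose
#' fraction `f`, so `sigma(1) = sigma_full` and noise grows as dose drops.
#'
#' The default `sigma_full` puts low-dose in-organ SDs near 17-26 HU at the
#' typical ~55% dose reduction.
#'
#' @param sigma_full noise SD in HU at full dose, > 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_full = 13.5) {
  if (!is.numeric(sigma_full) || sigma_full <= 0) {
    stop("`sigma_full` must be > 0", call. = FALSE)
  }
  structure(list(sigma_full = sigma_full,
                 sigma = function(f) sigma_full / sqrt(f)),
            class = "noise_model")
}

# pixel-center coordinates in mm for an m x n grid
phantom_grid_mm <- function(shape, spacing_mm) {
  list(r = (seq_len(shape[1]) - 0.5) * spacing_mm[1],
       c = (seq_len(shape[2]) - 0.5) * spacing_mm[2])
}

# logical mask of pixel centers inside a (rotated) ellipse
ellipse_mask <- function(organ, shape, spacing_mm) {
  g <- phantom_grid_mm(shape, spacing_mm)
  ext <- c(shape[1] * spacing_mm[1], shape[2] * spacing_mm[2])
  cr <- organ$center[1] * ext[1]
  cc <- organ$center[2] * ext[2]
  th <- organ$rotation_deg * pi / 180
  dr <- matrix(g$r - cr, shape[1], shape[2])
  dc <- matrix(g$c - cc, shape[1], shape[2], byrow = TRUE)
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  (u / organ$semi_axes_mm[1])^2 + (v / organ$semi_axes_mm[2])^2 <= 1
}

organ_in_bounds <- function(organ, shape, spacing_mm) {
  ext <- c(shape[1] * spacing_mm[1], shape[2] * spacing_mm[2])
  cr <- organ$center[1] * ext[1]; cc <- organ$center[2] * ext[2]
  rad <- max(organ$semi_axes_mm)
  cr - rad >= 0 && cr + rad <= ext[1] && cc - rad >= 0 && cc + rad <= ext[2]
}

#' Generate a noiseless reference phantom slice
#'
#' Paints the organ list onto a constant background; the later organ wins
#' where regions overlap. Within-organ texture (`texture_sd`) is drawn i.i.d.
#' Gaussian, so each pixel inside organ k has expectation `mean_hu(k)`.
#' Deterministic given `seed`.
#'
#' @param size_px length-2 integer, image dimensions (rows, cols).
#' @param spacing_mm length-2 numeric pixel spacing in mm; the default scales
#'   a 350 mm field of view to `size_px`.
#' @param organs non-empty list of [organ_spec()].
#' @param background_hu background level, HU (air by default).
#' @param seed integer seed for the texture draw.
#' @param patient_id,slice_index metadata stamped on the result.
#' @return List with `image` (a `ct_image`, dose tag `"HQ"`), `labels`
#'   (integer matrix, 0 = background, k = index of the owning organ) and
#'   `centers` (per-organ canonical ROI centers in 1-based pixel
#'   coordinates).
#' @export
make_phantom <- function(size_px = c(512, 512),
                         spacing_mm = 350 / size_px,
                         organs = default_organs(),
                         background_hu = -1000, seed = 1,
                         patient_id = "anon", slice_index = 0L) {
  size_px <- as.integer(size_px)
  if (length(size_px) == 1L) size_px <- rep(size_px, 2L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(organs) == 0L) stop("`organs` must be non-empty", call. = FALSE)
  for (og in organs) {
    if (!organ_in_bounds(og, size_px, spacing_mm)) {
      stop(sprintf("organ '%s' does not fit inside the image bounds", og$name),
           call. = FALSE)
    }
  }
  img <- matrix(background_hu, size_px[1], size_px[2])
  labels <- matrix(0L, size_px[1], size_px[2])
  withr::with_seed(seed, {
    for (k in seq_along(organs)) {
      og <- organs[[k]]
      msk <- ellipse_mask(og, size_px, spacing_mm)
      npx <- sum(msk)
      vals <- og$mean_hu
      if (og$texture_sd > 0) vals <- vals + stats::rnorm(npx, 0, og$texture_sd)
      img[msk] <- vals
      labels[msk] <- k
    }
  })
  ext <- c(size_px[1] * spacing_mm[1], size_px[2] * spacing_mm[2])
  centers <- data.frame(
    name = vapply(organs, `[[`, "", "name"),
    row = vapply(organs, function(o) o$center[1] * ext[1] / spacing_mm[1] + 0.5, 0),
    col = vapply(organs, function(o) o$center[2] * ext[2] / spacing_mm[2] + 0.5, 0)
  )
  list(image = ct_image(img, pixel_spacing = spacing_mm,
                        patient_id = patient_id, slice_index = slice_index,
                        dose_tag = "HQ"),
       labels = labels, centers = centers)
}

#' Simulate a low-dose acquisition of a slice
#'
#' Adds i.i.d. zero-mean Gaussian noise with SD `sigma_full / sqrt(f)` for
#' dose fraction `f`. Deterministic given `seed`.
#'
#' @param img a [ct_image()].
#' @param dose_fraction dose fraction `f` in `(0, 1]`.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return A `ct_image` with dose tag `"LQ"`.
#' @export
simulate_low_dose <- function(img, dose_fraction, noise = noise_model(),
                              seed = 1) {
  stopifnot(inherits(img, "ct_image"), inherits(noise, "noise_model"))
  if (!is.numeric(dose_fraction) || length(dose_fraction) != 1L ||
      dose_fraction <= 0 || dose_fraction > 1) {
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  }
  sd_f <- noise$sigma(dose_fraction)
  px <- img$pixels
  px <- px + withr::with_seed(seed, stats::rnorm(length(px), 0, sd_f))
  ct_image(matrix(px, nrow(img$pixels), ncol(img$pixels)),
           pixel_spacing = img$pixel_spacing, patient_id = img$patient_id,
           slice_index = img$slice_index, dose_tag = "LQ")
}

#' Generate a paired high/low-dose phantom dataset
#'
#' Emulates a paired-dose study: each synthetic patient receives one dose
#' reduction drawn uniformly from `dose_reduction_range` (dose fraction
#' `f = 1 - reduction`), slightly jittered organ geometry, and
#' `slices_per_patient` paired slices whose HQ reference is the noiseless
#' textured phantom and whose LQ arm adds dose-dependent noise. Fully
#' reproducible from `seed`.
#'
#' @param n_patients number of synthetic patients; at least 3 so a
#'   train/validation/test split by patient stays possible.
#' @param slices_per_patient slices per patient.
#' @param size_px image dimensions.
#' @param dose_reduction_range range the per-patient dose reduction is drawn
#'   from (defaults to 41-83%). Alternatively pass `dose_reductions`, one
#'   value per patient, to replay a known protocol exactly.
#' @param dose_reductions optional explicit per-patient dose reductions.
#' @param noise a [noise_model()].
#' @param seed integer master seed.
#' @return List of [image_pair()] grouped by patient (patients vary slowest),
#'   with attribute `"patients"` (data.frame of patient_id, dose_fraction).
#' @export
make_paired_dataset <- function(n_patients = 23, slices_per_patient = 10,
                                size_px = c(64, 64),
                                dose_reduction_range = c(0.41, 0.83),
                                dose_reductions = NULL,
                                noise = noise_model(), seed = 1) {
  if (n_patients < 3) {
    stop("`n_patients` must be >= 3 to allow a 3-way patient split",
         call. = FALSE)
  }
  if (!is.null(dose_reductions) && length(dose_reductions) != n_patients) {
    stop("`dose_reductions` must have one value per patient", call. = FALSE)
  }
  reductions <- if (is.null(dose_reductions)) {
    withr::with_seed(seed, stats::runif(n_patients, dose_reduction_range[1],
                                        dose_reduction_range[2]))
  } else as.numeric(dose_reductions)
  if (any(reductions <= 0) || any(reductions >= 1)) {
    stop("dose reductions must lie strictly inside (0, 1)", call. = FALSE)
  }

  pairs <- vector("list", n_patients * slices_per_patient)
  pat_ids <- sprintf("P%02d", seq_len(n_patients))
  i <- 0L
  for (p in seq_len(n_patients)) {
    f <- 1 - reductions[p]
    # per-patient geometry jitter: same organs across the patient's slices
    organs <- withr::with_seed(seed + 7919L * p, {
      lapply(default_organs(), function(og) {
        og$semi_axes_mm <- og$semi_axes_mm * stats::runif(2, 0.92, 1.05)
        og$center <- og$center + stats::runif(2, -0.015, 0.015)
        og
      })
    })
    for (s in seq_len(slices_per_patient)) {
      slice_seed <- seed + 100003L * p + 13L * s
      ph <- make_phantom(size_px = size_px, organs = organs,
                         seed = slice_seed, patient_id = pat_ids[p],
                         slice_index = s)
      lq <- simulate_low_dose(ph$image, f, noise, seed = slice_seed + 1L)
      i <- i + 1L
      pairs[[i]] <- image_pair(ph$image, lq, f)
    }
  }
  attr(pairs, "patients") <- data.frame(patient_id = pat_ids,
                                        dose_fraction = 1 - reductions)
  pairs
}
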