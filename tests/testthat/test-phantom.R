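test_that("phantom organ means hit their target HU levels", {
  # degenerate case: one full-frame organ, no texture -> constant image
  big <- organ_spec("all", c(0.5, 0.5), c(100, 100), 0, 70, 0)
  ph0 <- make_phantom(size_px = c(64, 64), spacing_mm = c(4, 4),
                      organs = list(big), seed = 1)
  expect_true(all(ph0$image$pixels[ph0$labels == 1L] == 70))

  # default five-organ phantom: per-organ pixel means within 0.5 HU of the
  # layout's target levels
  ph <- make_phantom(size_px = c(256, 256), seed = 42)
  organs <- default_organs()
  for (k in seq_along(organs)) {
    vals <- ph$image$pixels[ph$labels == k]
    expect_lt(abs(mean(vals) - organs[[k]]$mean_hu), 0.5)
  }
})

test_that("label map matches a brute-force point-in-ellipse count", {
  og <- organ_spec("e", c(0.5, 0.5), c(20, 12), 30, 50, 0)
  shape <- c(48, 48); sp <- c(2, 2)
  ph <- make_phantom(shape, sp, organs = list(og), seed = 1)
  # brute-force lattice count in physical coordinates
  th <- 30 * pi / 180
  cnt <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    dr <- (i - 0.5) * sp[1] - 0.5 * shape[1] * sp[1]
    dc <- (j - 0.5) * sp[2] - 0.5 * shape[2] * sp[2]
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    if ((u / 20)^2 + (v / 12)^2 <= 1) cnt <- cnt + 1L
  }
  expect_equal(sum(ph$labels == 1L), cnt)
  expect_error(make_phantom(c(16, 16), c(1, 1), organs = list(og)),
               "bounds")
})

test_that("low-dose noise SD follows sigma_full / sqrt(f)", {
  base <- ct_image(matrix(0, 350, 350))
  nm <- noise_model(sigma_full = 10)
  for (f in c(1, 0.25)) {
    lq <- simulate_low_dose(base, f, nm, seed = 7 + f * 100)
    expect_equal(sd(lq$pixels - base$pixels), 10 / sqrt(f),
                 tolerance = 0.02)
    # CLT bound on the mean of the added noise
    expect_lt(abs(mean(lq$pixels - base$pixels)),
              3 * (10 / sqrt(f)) / sqrt(length(base$pixels)))
  }
  expect_identical(lq$dose_tag, "LQ")
  expect_error(simulate_low_dose(base, 0, nm), "0, 1")
  expect_error(simulate_low_dose(base, 1.2, nm), "0, 1")
})

test_that("paired datasets are reproducible, grouped and dose-bounded", {
  ds1 <- make_paired_dataset(5, 4, size_px = c(32, 32), seed = 77)
  ds2 <- make_paired_dataset(5, 4, size_px = c(32, 32), seed = 77)
  expect_length(ds1, 20)
  expect_identical(ds1, ds2)   # bit-identical under the same seed
  ids <- vapply(ds1, function(p) p$hq$patient_id, "")
  expect_length(unique(ids), 5)
  fr <- vapply(ds1, `[[`, 0, "dose_fraction")
  expect_true(all(fr >= 1 - 0.83 & fr <= 1 - 0.41))
  # one dose fraction per patient
  expect_true(all(tapply(fr, ids, function(v) length(unique(v))) == 1))
  expect_error(make_paired_dataset(2, 4), ">= 3")
})

test_that("HQ slices do not depend on the dose fraction", {
  ph <- make_phantom(size_px = c(32, 32), seed = 5)
  lq_a <- simulate_low_dose(ph$image, 0.2, seed = 9)
  lq_b <- simulate_low_dose(ph$image, 0.9, seed = 9)
  # the HQ reference is untouched; only the noise draw differs
  expect_identical(ph$image$pixels,
                   make_phantom(size_px = c(32, 32), seed = 5)$image$pixels)
  expect_false(identical(lq_a$pixels, lq_b$pixels))
})

test_that("in-organ ROI SD at dose f matches the noise model within 5%", {
  og <- organ_spec("disk", c(0.5, 0.5), c(60, 60), 0, 50, 0)
  ph <- make_phantom(c(128, 128), c(1.5, 1.5), organs = list(og), seed = 3)
  f <- 0.45
  lq <- simulate_low_dose(ph$image, f, noise_model(13.5), seed = 4)
  st <- roi_stats(lq, roi_spec("disk", c(64.5, 64.5), radius_mm = 40))
  expect_gt(st$n_pixels, 2000)
  expect_equal(st$sd_hu, 13.5 / sqrt(f), tolerance = 0.05)
})
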