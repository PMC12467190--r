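test_that("circular masks match brute-force lattice counts", {
  # 8 mm radius on 1 mm isotropic spacing: lattice points with r^2 <= 64
  msk <- circular_mask(c(32, 32), 8, c(1, 1), c(64, 64))
  cnt <- 0L
  for (dx in -8:8) for (dy in -8:8) if (dx^2 + dy^2 <= 64) cnt <- cnt + 1L
  expect_equal(sum(msk), cnt)
  expect_equal(sum(msk), 197L)

  # radius below half the spacing keeps exactly the center pixel
  tiny <- circular_mask(c(10, 10), 0.4, c(1, 1), c(20, 20))
  expect_equal(sum(tiny), 1L)
  expect_true(tiny[10, 10])

  # anisotropic spacing halves the column extent: ellipse in pixel space
  an <- circular_mask(c(20, 20), 8, c(1, 2), c(40, 40))
  cnt2 <- 0L
  for (i in 1:40) for (j in 1:40) {
    if (((i - 20) * 1)^2 + ((j - 20) * 2)^2 <= 64) cnt2 <- cnt2 + 1L
  }
  expect_equal(sum(an), cnt2)
  expect_error(circular_mask(c(3, 32), 8, c(1, 1), c(64, 64)), "bounds")
})

test_that("mask pixel count approaches the continuum area", {
  for (r in c(8, 12, 20)) {
    msk <- circular_mask(c(64, 64), r, c(1, 1), c(128, 128))
    expect_equal(sum(msk), pi * r^2, tolerance = 0.05)
  }
})

test_that("roi statistics are exact on constants and match loop oracles", {
  img <- flat_ct(50, 40, 40)
  st <- roi_stats(img, roi_spec("c", c(20, 20), 8))
  expect_equal(st$mean_hu, 50)
  expect_equal(st$sd_hu, 0)
  expect_equal(st$n_pixels, 197L)

  rnd <- ct_image(rand_mat(40, 40, -100, 100, seed = 3))
  roi <- roi_spec("r", c(20, 20), 6)
  st2 <- roi_stats(rnd, roi)
  msk <- circular_mask(c(20, 20), 6, c(1, 1), c(40, 40))
  vals <- c()
  for (i in 1:40) for (j in 1:40) if (msk[i, j]) vals <- c(vals, rnd$pixels[i, j])
  expect_equal(st2$n_pixels, length(vals))
  expect_equal(st2$mean_hu, sum(vals) / length(vals))
  expect_equal(st2$sd_hu, sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)))
})

test_that("roi statistics ignore content outside the mask", {
  base <- rand_mat(40, 40, 0, 10, seed = 4)
  img1 <- ct_image(base)
  out <- base
  msk <- circular_mask(c(20, 20), 6, c(1, 1), c(40, 40))
  out[!msk] <- out[!msk] + 5000
  img2 <- ct_image(out)
  roi <- roi_spec("r", c(20, 20), 6)
  expect_equal(roi_stats(img1, roi)$mean_hu, roi_stats(img2, roi)$mean_hu)
  expect_equal(roi_stats(img1, roi)$sd_hu, roi_stats(img2, roi)$sd_hu)
})

test_that("roi SD recovers an injected noise level", {
  og <- organ_spec("disk", c(0.5, 0.5), c(30, 30), 0, 40, 0)
  ph <- make_phantom(c(96, 96), c(1, 1), organs = list(og), seed = 5)
  lq <- simulate_low_dose(ph$image, 0.5, noise_model(12), seed = 6)
  st <- roi_stats(lq, roi_spec("disk", c(48.5, 48.5), 8))
  expect_gte(st$n_pixels, 150)
  expect_equal(st$sd_hu, 12 / sqrt(0.5), tolerance = 0.10)
})

test_that("percent SD reduction matches the organ-table arithmetic", {
  expect_equal(round(sd_reduction_pct(18.85, 15.40), 2), 18.30)
  expect_equal(round(sd_reduction_pct(17.60, 16.20), 2), 7.95)
  expect_equal(sd_reduction_pct(5, 5), 0)
  expect_error(sd_reduction_pct(0, 1), "> 0")
})

test_that("roi comparison table and roi csv round-trip work", {
  og <- organ_spec("disk", c(0.5, 0.5), c(30, 30), 0, 40, 0)
  ph <- make_phantom(c(96, 96), c(1, 1), organs = list(og), seed = 8)
  lq <- simulate_low_dose(ph$image, 0.5, noise_model(12), seed = 9)
  rois <- list(roi_spec("disk", c(48.5, 48.5), 8))
  tab <- roi_compare(lq, ph$image, rois)
  expect_equal(nrow(tab), 2)
  lq_sd <- tab$sd_hu[tab$arm == "LQ"]
  out_sd <- tab$sd_hu[tab$arm == "output"]
  expect_equal(tab$sd_reduction_pct[tab$arm == "LQ"],
               100 * (lq_sd - out_sd) / lq_sd)
  f <- tempfile(fileext = ".csv")
  write_rois(rois, f)
  back <- read_rois(f)
  expect_equal(back[[1]]$center, rois[[1]]$center)
  expect_equal(back[[1]]$radius_mm, 8)
})
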