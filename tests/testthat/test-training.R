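test_that("patient-level splitting partitions patients exactly", {
  pairs <- make_paired_dataset(23, 2, size_px = c(16, 16), seed = 31)
  sp <- split_by_patient(pairs, c(15, 4, 4), seed = 1)
  ids <- lapply(sp, function(g) unique(vapply(g, function(p) p$hq$patient_id, "")))
  expect_length(ids$train, 15)
  expect_length(ids$val, 4)
  expect_length(ids$test, 4)
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  sp2 <- split_by_patient(pairs, c(15, 4, 4), seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_by_patient(pairs, c(20, 2, 2)), "sum")
})

test_that("rotation resampler behaves like the exact index permutations", {
  x <- rand_mat(21, 21, -100, 100, seed = 41)
  expect_identical(rotate_image(x, 0), x)
  # 90 degrees counter-clockwise about the center = transpose + row flip
  r90 <- rotate_image(x, 90, fill = -1000)
  expect_equal(r90, t(x)[nrow(x):1, ], tolerance = 1e-9)
  # rotating forth and back restores the interior
  fb <- rotate_image(rotate_image(x, 7, fill = 0), -7, fill = 0)
  core <- 8:14
  expect_equal(fb[core, core], x[core, core], tolerance = 2)
})

test_that("augmentation applies one common transform to both arms", {
  ph <- make_phantom(size_px = c(24, 24), seed = 51)
  lq <- simulate_low_dose(ph$image, 0.5, seed = 52)
  pair <- image_pair(ph$image, lq, 0.5)

  # identity transform reproduces the input pair
  aug0 <- augment_pair(pair, factor = 1, rotation_range_deg = 0,
                       flip_prob = 0, seed = 1)
  expect_equal(aug0[[1]]$hq$pixels, pair$hq$pixels)
  expect_equal(aug0[[1]]$lq$pixels, pair$lq$pixels)
  expect_true(isTRUE(attr(aug0[[1]], "augmented")))

  # forced horizontal flip reverses column order in BOTH arms
  augf <- augment_pair(pair, factor = 1, rotation_range_deg = 0,
                       flip_prob = 1, seed = 2)
  # flip_prob = 1 applies both flips; undo the vertical one for the check
  px <- augf[[1]]$hq$pixels[nrow(ph$image$pixels):1, ]
  expect_equal(px, pair$hq$pixels[, ncol(pair$hq$pixels):1])
  pxl <- augf[[1]]$lq$pixels[nrow(ph$image$pixels):1, ]
  expect_equal(pxl, pair$lq$pixels[, ncol(pair$lq$pixels):1])

  # the derived noise field moves with the geometry: hq - lq is the same
  # transform of the original residual
  aug <- augment_pair(pair, factor = 4, seed = 3)
  expect_length(aug, 4)
  for (a in aug) {
    expect_equal(dim(a$hq$pixels), dim(pair$hq$pixels))
    expect_equal(a$dose_fraction, pair$dose_fraction)
  }
})

test_that("a 15-patient x 10-slice set with factor 4 yields 600 derived pairs", {
  pairs <- make_paired_dataset(23, 10, size_px = c(16, 16), seed = 61)
  sp <- split_by_patient(pairs, c(15, 4, 4), seed = 61)
  aug <- unlist(lapply(seq_along(sp$train), function(i) {
    augment_pair(sp$train[[i]], factor = 4, seed = i)
  }), recursive = FALSE)
  expect_length(aug, 600)
  expect_true(all(vapply(aug, function(p) isTRUE(attr(p, "augmented")), TRUE)))
})

test_that("training bookkeeping and data hygiene hold", {
  pairs <- make_paired_dataset(4, 2, size_px = c(16, 16), seed = 71)
  sp <- split_by_patient(pairs, c(2, 1, 1), seed = 71)
  m <- build_denoiser(tiny_config(), seed = 7)
  tc <- train_config(batch_size = 2, learning_rate = 1e-3, epochs = 3,
                     augmentation_factor = 2, seed = 8)
  fit <- train_denoiser(m, sp$train, sp$val, tc)
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$history$epoch, 1:3)
  expect_true(all(is.finite(fit$history$val_loss)))
  # augmented pairs are rejected as validation data
  bad <- augment_pair(sp$val[[1]], factor = 1, seed = 1)
  expect_error(train_denoiser(m, sp$train, bad, tc), "augmented")
})

test_that("random search respects its space, budget and selection contract", {
  # budget 1 returns the single sampled config
  obj <- function(cf) cf$learning_rate
  sp1 <- list(learning_rate = c(0.1))
  r1 <- hyperparameter_search(sp1, budget = 1, objective = obj, seed = 1)
  expect_equal(r1$best$learning_rate, 0.1)
  expect_equal(nrow(r1$trials), 1)

  # every sampled learning rate stays inside the log-uniform bounds
  spc <- search_space()
  r <- hyperparameter_search(spc, budget = 12,
                             objective = function(cf) cf$dropout, seed = 2)
  expect_true(all(r$trials$learning_rate >= 1e-5 &
                    r$trials$learning_rate <= 1e-4))
  expect_true(all(r$trials$dropout >= 0.4 & r$trials$dropout <= 0.5))
  expect_true(all(r$trials$dncnn_blocks %in% c(3, 4, 5)))
  expect_true(all(r$trials$batch_size %in% c(4, 6, 8)))

  # a 2-point space with a provably better point is resolved by budget >= 4
  sp2 <- list(learning_rate = c(0.5, 0.01))
  r2 <- hyperparameter_search(sp2, budget = 4,
                              objective = function(cf) abs(cf$learning_rate),
                              seed = 3)
  expect_equal(r2$best$learning_rate, 0.01)

  # the running best is non-increasing and the log replays from the seed
  expect_true(all(diff(r$trials$best_so_far) <= 0))
  r_replay <- hyperparameter_search(spc, budget = 12,
                                    objective = function(cf) cf$dropout,
                                    seed = 2)
  expect_identical(r$trials, r_replay$trials)
  expect_error(hyperparameter_search(list(), 2, obj), "empty")
})
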