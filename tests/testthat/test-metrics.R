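test_that("mse matches hand values and the loop oracle", {
  a <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(mse(a, a), 0)
  b <- a; b[2, 2] <- 0
  expect_equal(mse(a, b), 16 / 4)
  for (s in 1:4) {
    x <- rand_mat(8, 8, seed = s); y <- rand_mat(8, 8, seed = 50 + s)
    expect_equal(mse(x, y), oracle_mse(x, y), tolerance = 1e-12)
  }
  expect_error(mse(rand_mat(4), rand_mat(5)), "dimensions")
})

test_that("psnr is the log of the peak-to-mse ratio", {
  a <- matrix(0, 4, 4)
  b <- matrix(255, 4, 4)           # MSE = L^2
  expect_equal(psnr(a, b), 0)
  # analytic: MSE = L^2/1000 -> 30 dB
  d <- sqrt(255^2 / 1000)
  expect_equal(psnr(a, matrix(d, 4, 4)), 30)
  expect_identical(psnr(a, a), Inf)
  # strictly decreasing in mse for fixed L
  ms <- c(1, 10, 100)
  ps <- vapply(ms, function(m) psnr(a, matrix(sqrt(m), 4, 4)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("ssim matches its formula oracle and known constants", {
  x <- rand_mat(16, 16, seed = 1)
  expect_equal(ssim(x, x, mode = "global"), 1)
  expect_equal(ssim(x, x, mode = "windowed"), 1)
  # constant 0 vs constant 255: zero variances leave C1/(255^2 + C1)
  C1 <- (0.01 * 255)^2
  expect_equal(ssim(matrix(0, 12, 12), matrix(255, 12, 12), mode = "global"),
               C1 / (255^2 + C1))
  for (s in 1:5) {
    a <- rand_mat(10, 10, seed = s); b <- rand_mat(10, 10, seed = 60 + s)
    expect_equal(ssim(a, b, mode = "global"), oracle_ssim_global(a, b),
                 tolerance = 1e-12)
    expect_equal(ssim(a, b, mode = "global"), ssim(b, a, mode = "global"))
  }
  expect_error(ssim(rand_mat(8), rand_mat(8), mode = "windowed"),
               "window larger")
})

test_that("windowed ssim equals a direct sliding-window computation", {
  a <- rand_mat(14, 14, seed = 3); b <- rand_mat(14, 14, seed = 4)
  # direct oracle: loop windows, Gaussian-weighted moments
  g1 <- exp(-(seq(-5, 5)^2) / (2 * 1.5^2)); w <- outer(g1, g1); w <- w / sum(w)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  vals <- c()
  for (i in 1:4) for (j in 1:4) {
    wa <- a[i:(i + 10), j:(j + 10)]; wb <- b[i:(i + 10), j:(j + 10)]
    mx <- sum(w * wa); my <- sum(w * wb)
    vx <- sum(w * wa^2) - mx^2; vy <- sum(w * wb^2) - my^2
    cxy <- sum(w * wa * wb) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(ssim(a, b, mode = "windowed"), mean(vals), tolerance = 1e-12)
})

test_that("vif is 1 at identity and decreases with distortion", {
  ref <- rand_mat(64, 64, seed = 9)
  expect_equal(vif(ref, ref), 1, tolerance = 1e-6)
  n5 <- ref + rand_mat(64, 64, -5 * sqrt(3), 5 * sqrt(3), seed = 10)
  n30 <- ref + rand_mat(64, 64, -30 * sqrt(3), 30 * sqrt(3), seed = 11)
  expect_lt(vif(ref, n30), vif(ref, n5))
  expect_error(vif(matrix(5, 8, 8), rand_mat(8)), "constant reference")
})

test_that("single-scale vif equals the closed-form information ratio", {
  prm <- metric_params(vif_scales = 1, vif_noise_var = 2)
  # independent transcription: same 17x17 Gaussian window, explicit
  # gain/visual-noise channel terms, summed over all window positions
  g1 <- exp(-(seq(-8, 8)^2) / (2 * (17 / 5)^2)); w <- outer(g1, g1)
  w <- w / sum(w)
  num <- 0; den <- 0
  ref <- rand_mat(24, 24, seed = 13)
  dst <- ref * 0.8 + rand_mat(24, 24, -4, 4, seed = 14)
  for (i in 1:8) for (j in 1:8) {
    wr <- ref[i:(i + 16), j:(j + 16)]; wd <- dst[i:(i + 16), j:(j + 16)]
    m1 <- sum(w * wr); m2 <- sum(w * wd)
    s1 <- max(sum(w * wr^2) - m1^2, 0)
    s2 <- max(sum(w * wd^2) - m2^2, 0)
    s12 <- sum(w * wr * wd) - m1 * m2
    g <- if (s1 < 1e-10) 0 else s12 / (s1 + 1e-10)
    sv <- if (s1 < 1e-10) s2 else s2 - g * s12
    sv <- max(sv, 1e-10)
    num <- num + log10(1 + g^2 * s1 / (sv + 2))
    den <- den + log10(1 + s1 / 2)
  }
  expect_equal(vif(ref, dst, prm), num / den, tolerance = 1e-9)
})

test_that("epi matches its two definitions", {
  ref <- rand_mat(4, 4, seed = 21)
  expect_equal(epi(ref, ref, mode = "ratio"), 0)
  expect_equal(epi(ref, ref, mode = "correlation"), 1)
  for (s in 1:5) {
    a <- rand_mat(4, 4, seed = s); b <- rand_mat(4, 4, seed = 80 + s)
    expect_equal(epi(a, b, mode = "ratio"), oracle_epi_ratio(a, b),
                 tolerance = 1e-12)
  }
  expect_error(epi(matrix(3, 4, 4), rand_mat(4), mode = "ratio"), "flat")
})

test_that("noise variance is the population variance as printed", {
  expect_equal(noise_variance(matrix(7, 5, 5)), 0)
  expect_equal(noise_variance(matrix(c(0, 0, 2, 2), 2)), 1)
  x <- rand_mat(9, 9, seed = 31)
  expect_equal(noise_variance(x), oracle_nv(x), tolerance = 1e-12)
})

test_that("global metrics are permutation-invariant; vif and epi are anchored", {
  a <- rand_mat(8, 8, seed = 41); b <- rand_mat(8, 8, seed = 42)
  perm <- withr::with_seed(43, sample(64))
  ap <- matrix(a[perm], 8); bp <- matrix(b[perm], 8)
  expect_equal(mse(ap, bp), mse(a, b))
  expect_equal(ssim(ap, bp, mode = "global"), ssim(a, b, mode = "global"))
  expect_equal(noise_variance(ap), noise_variance(a))
  # reference-anchored metrics are not symmetric
  big <- rand_mat(32, 32, 0, 255, seed = 44)
  noisy <- pmin(pmax(big + rand_mat(32, 32, -40, 40, seed = 45), 0), 255)
  expect_false(isTRUE(all.equal(epi(big, noisy, mode = "ratio"),
                                epi(noisy, big, mode = "ratio"))))
  expect_false(isTRUE(all.equal(vif(big, noisy), vif(noisy, big))))
})

test_that("evaluate_dataset reports per-pair metrics and exact aggregates", {
  pairs <- make_paired_dataset(3, 2, size_px = c(32, 32), seed = 51)
  # a perfect denoiser: outputs equal the HQ references
  rep_perfect <- evaluate_dataset(pairs, outputs = lapply(pairs, `[[`, "hq"))
  out_rows <- rep_perfect$per_pair[rep_perfect$per_pair$arm == "output", ]
  expect_true(all(out_rows$mse == 0))
  expect_true(all(out_rows$ssim == 1))
  expect_true(all(is.infinite(out_rows$psnr)))
  # outputs := LQ makes both arms identical
  rep_id <- evaluate_dataset(pairs, outputs = lapply(pairs, `[[`, "lq"))
  lq <- rep_id$per_pair[rep_id$per_pair$arm == "LQ",
                        c("mse", "psnr", "ssim", "vif", "epi", "nv")]
  ou <- rep_id$per_pair[rep_id$per_pair$arm == "output",
                        c("mse", "psnr", "ssim", "vif", "epi", "nv")]
  expect_equal(unname(as.matrix(lq)), unname(as.matrix(ou)))
  # aggregates recompute from the per-pair records
  for (k in seq_len(nrow(rep_id$aggregate))) {
    row <- rep_id$aggregate[k, ]
    v <- rep_id$per_pair[rep_id$per_pair$arm == row$arm, row$metric]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
    expect_equal(row$median, median(v))
    expect_equal(row$min, min(v))
    expect_equal(row$max, max(v))
  }
  # csv export round-trips the aggregate recomputation
  f <- tempfile(fileext = ".csv")
  write_metric_report(rep_id, csv_path = f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(rep_id$per_pair))
  expect_equal(back$mse, rep_id$per_pair$mse)
})
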