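# Paired image-quality metrics: MSE, PSNR, SSIM (global single-statistic
# and windowed Gaussian variants), pixel-domain multi-scale VIF, edge
# preservation index (literal quotient and gradient-correlation variants),
# and noise variance. Metrics operate on 8-bit arrays (L = 255), the
# domain the network sees; pass plain matrices for other scales.

as_px <- function(x) {
  if (inherits(x, "image8")) return(x$pixels)
  if (inherits(x, "ct_image")) return(x$pixels)
  if (is.matrix(x)) return(x)
  stop("expected an image8, ct_image or matrix", call. = FALSE)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images must share dimensions", call. = FALSE)
  }
}

#' Metric parameters
#'
#' @param L peak value of the pixel scale (255 for 8-bit images).
#' @param ssim_c1,ssim_c2 SSIM stabilization constants; default
#'   `(0.01 L)^2` and `(0.03 L)^2`.
#' @param ssim_mode `"windowed"` (mean of the SSIM statistic over sliding
#'   11x11 Gaussian windows, the variant whose scale matches commonly
#'   reported values) or `"global"` (the single whole-image statistic).
#' @param epi_mode `"correlation"` (normalized cross-correlation of gradient
#'   magnitudes; 1 means edges perfectly preserved) or `"ratio"` (the
#'   literal squared-gradient-difference quotient; 0 means perfectly
#'   preserved).
#' @param vif_scales number of sub-band scales for VIF.
#' @param vif_noise_var visual-noise variance of the VIF channel model.
#' @return An object of class `metric_params`.
#' @export
metric_params <- function(L = 255, ssim_c1 = (0.01 * L)^2,
                          ssim_c2 = (0.03 * L)^2,
                          ssim_mode = c("windowed", "global"),
                          epi_mode = c("correlation", "ratio"),
                          vif_scales = 4, vif_noise_var = 2.0) {
  ssim_mode <- match.arg(ssim_mode)
  epi_mode <- match.arg(epi_mode)
  stopifnot(L > 0, ssim_c1 > 0, ssim_c2 > 0, vif_scales >= 1,
            vif_noise_var > 0)
  structure(list(L = L, ssim_c1 = ssim_c1, ssim_c2 = ssim_c2,
                 ssim_mode = ssim_mode, epi_mode = epi_mode,
                 vif_scales = as.integer(vif_scales),
                 vif_noise_var = vif_noise_var),
            class = "metric_params")
}

#' Mean squared error between two images
#'
#' `(1/mn) * sum((a - b)^2)`.
#'
#' @param a,b images of identical dimensions ([image8()], [ct_image()] or
#'   matrices).
#' @export
mse <- function(a, b) {
  a <- as_px(a); b <- as_px(b)
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio, dB
#'
#' `10 log10(L^2 / MSE)`; identical images (MSE 0) return `Inf`, which
#' serializes as the string `"inf"` in exports.
#'
#' @inheritParams mse
#' @param params a [metric_params()] supplying the peak value `L`.
#' @export
psnr <- function(a, b, params = metric_params()) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(params$L^2 / m)
}

# valid-region 2-D correlation with a small kernel (loop over kernel taps;
# kernels here are at most 17x17 so this stays cheap and exact)
filter2_valid <- function(x, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  m <- nrow(x); n <- ncol(x)
  if (kr > m || kc > n) stop("window larger than image", call. = FALSE)
  out <- matrix(0, m - kr + 1L, n - kc + 1L)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (kern[i, j] == 0) next
    out <- out + kern[i, j] * x[i:(m - kr + i), j:(n - kc + j)]
  }
  out
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index
#'
#' Global mode evaluates the SSIM statistic
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) / ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' once over the whole image (population moments). Windowed mode averages
#' the same statistic over sliding Gaussian windows (11x11, sigma 1.5),
#' the form whose values are usually reported.
#'
#' @inheritParams psnr
#' @param mode overrides `params$ssim_mode`.
#' @param window_size,window_sigma Gaussian window for windowed mode.
#' @return A value in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(a, b, params = metric_params(), mode = NULL,
                 window_size = 11, window_sigma = 1.5) {
  a <- as_px(a); b <- as_px(b)
  check_same_shape(a, b)
  mode <- if (is.null(mode)) params$ssim_mode else
    match.arg(mode, c("windowed", "global"))
  C1 <- params$ssim_c1; C2 <- params$ssim_c2
  if (mode == "global") {
    mux <- mean(a); muy <- mean(b)
    vx <- mean((a - mux)^2); vy <- mean((b - muy)^2)
    cxy <- mean((a - mux) * (b - muy))
    return(((2 * mux * muy + C1) * (2 * cxy + C2)) /
             ((mux^2 + muy^2 + C1) * (vx + vy + C2)))
  }
  w <- gaussian_kernel(window_size, window_sigma)
  mux <- filter2_valid(a, w)
  muy <- filter2_valid(b, w)
  vx <- filter2_valid(a * a, w) - mux^2
  vy <- filter2_valid(b * b, w) - muy^2
  cxy <- filter2_valid(a * b, w) - mux * muy
  mean(((2 * mux * muy + C1) * (2 * cxy + C2)) /
         ((mux^2 + muy^2 + C1) * (vx + vy + C2)))
}

# Gaussian smoothing + 2x decimation for the VIF scale pyramid
vif_downsample <- function(x, kern) {
  sm <- filter2_valid(x, kern)
  sm[seq(1, nrow(sm), 2), seq(1, ncol(sm), 2), drop = FALSE]
}

#' Visual information fidelity (pixel domain)
#'
#' Multi-scale pixel-domain realization of the information quotient
#' `VIF = sum_s I(W_s; out | F_s) / sum_s I(W_s; ref | F_s)`: at each scale
#' local Gaussian-window statistics define a gain-plus-additive-noise
#' channel `out = g * ref + v`, and the two mutual-information terms are
#' accumulated with the same visual-noise variance in both. Equals 1 when
#' the distorted image is the reference, decreases with distortion.
#'
#' @param ref reference image (must not be constant).
#' @param dist distorted/processed image.
#' @inheritParams psnr
#' @export
vif <- function(ref, dist, params = metric_params()) {
  ref <- as_px(ref); dist <- as_px(dist)
  check_same_shape(ref, dist)
  if (stats::var(as.vector(ref)) == 0) {
    stop("VIF is undefined for a constant reference image", call. = FALSE)
  }
  sigma_nsq <- params$vif_noise_var
  eps <- 1e-10
  num <- 0; den <- 0
  for (s in seq_len(params$vif_scales)) {
    size <- max(2^(4 - s + 1) + 1, 3)   # 17, 9, 5, 3 at scales 1..4
    kern <- gaussian_kernel(size, size / 5)
    if (s > 1) {
      ref <- vif_downsample(ref, kern)
      dist <- vif_downsample(dist, kern)
      if (nrow(ref) < size || ncol(ref) < size) break
    }
    mu1 <- filter2_valid(ref, kern)
    mu2 <- filter2_valid(dist, kern)
    s1 <- filter2_valid(ref * ref, kern) - mu1^2
    s2 <- filter2_valid(dist * dist, kern) - mu2^2
    s12 <- filter2_valid(ref * dist, kern) - mu1 * mu2
    s1[s1 < 0] <- 0
    s2[s2 < 0] <- 0
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0
    sv[s1 < eps] <- s2[s1 < eps]
    sv[sv < eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

# forward differences, edge-replicated (last row/column gradient 0)
grad_xy <- function(x) {
  m <- nrow(x); n <- ncol(x)
  gx <- cbind(x[, -1, drop = FALSE] - x[, -n, drop = FALSE], rep(0, m))
  gy <- rbind(x[-1, , drop = FALSE] - x[-m, , drop = FALSE], rep(0, n))
  list(gx = gx, gy = gy)
}

#' Edge preservation index
#'
#' Ratio mode is the literal quotient
#' `sum((gx_ref - gx_out)^2 + (gy_ref - gy_out)^2) / sum(gx_ref^2 + gy_ref^2)`
#' with forward differences: 0 means edges perfectly preserved.
#' Correlation mode (the default for reports, whose scale matches commonly
#' reported values near 1) is the normalized cross-correlation of the two
#' gradient-magnitude images: 1 means perfectly preserved.
#'
#' @param ref reference image; must not be flat (zero gradients everywhere).
#' @param out processed image.
#' @inheritParams psnr
#' @param mode overrides `params$epi_mode`.
#' @export
epi <- function(ref, out, params = metric_params(), mode = NULL) {
  ref <- as_px(ref); out <- as_px(out)
  check_same_shape(ref, out)
  if (nrow(ref) < 2 || ncol(ref) < 2) {
    stop("images must be at least 2x2", call. = FALSE)
  }
  mode <- if (is.null(mode)) params$epi_mode else
    match.arg(mode, c("correlation", "ratio"))
  gr <- grad_xy(ref); go <- grad_xy(out)
  if (mode == "ratio") {
    den <- sum(gr$gx^2 + gr$gy^2)
    if (den == 0) stop("EPI is undefined for a flat reference image",
                       call. = FALSE)
    return(sum((gr$gx - go$gx)^2 + (gr$gy - go$gy)^2) / den)
  }
  mr <- sqrt(gr$gx^2 + gr$gy^2)
  mo <- sqrt(go$gx^2 + go$gy^2)
  dr <- mr - mean(mr)
  do_ <- mo - mean(mo)
  den <- sqrt(sum(dr^2) * sum(do_^2))
  if (den == 0) {
    if (sum(dr^2) == 0) stop("EPI is undefined for a flat reference image",
                             call. = FALSE)
    return(0)
  }
  sum(dr * do_) / den
}

#' Noise variance of a single image
#'
#' Population variance `(1/mn) * sum((I - mu)^2)`.
#'
#' @param img an image ([image8()], [ct_image()] or matrix).
#' @export
noise_variance <- function(img) {
  x <- as_px(img)
  mean((x - mean(x))^2)
}

metric_row <- function(hq, other, params) {
  one <- function(f) tryCatch(f(), error = function(e) NA_real_)
  data.frame(
    mse = one(function() mse(hq, other)),
    psnr = one(function() psnr(hq, other, params)),
    ssim = one(function() ssim(hq, other, params)),
    vif = one(function() vif(hq, other, params)),
    epi = one(function() epi(hq, other, params)),
    nv = one(function() noise_variance(other))
  )
}

#' Evaluate a paired dataset
#'
#' Computes the six metrics per pair for both arms — the low-dose input
#' against the HQ reference, and the denoised output against the HQ
#' reference — and aggregates mean/SD/median/min/max per metric and arm.
#' A pair failing a metric precondition yields `NA` for that entry (and a
#' reason column), never a silent drop.
#'
#' @param pairs list of [image_pair()].
#' @param model optional `ct_denoiser` used to produce the outputs.
#' @param outputs optional precomputed outputs (list of [image8()] or
#'   `ct_image`), one per pair; exactly one of `model`/`outputs` must be
#'   given unless you only want the LQ arm.
#' @param params a [metric_params()].
#' @param window HU window applied before metric computation.
#' @return An object of class `metric_report`: list with `per_pair` and
#'   `aggregate` data.frames.
#' @export
evaluate_dataset <- function(pairs, model = NULL, outputs = NULL,
                             params = metric_params(), window = c(40, 400)) {
  stopifnot(length(pairs) > 0)
  if (!is.null(model) && !is.null(outputs)) {
    stop("supply `model` or `outputs`, not both", call. = FALSE)
  }
  if (!is.null(model)) window <- model$config$window
  rows <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    hq8 <- hu_to_uint8(pr$hq, window)
    lq8 <- hu_to_uint8(pr$lq, window)
    out8 <- NULL
    if (!is.null(model)) out8 <- denoise(model, lq8)
    if (!is.null(outputs)) {
      o <- outputs[[i]]
      out8 <- if (inherits(o, "image8")) o else hu_to_uint8(o, window)
    }
    base <- data.frame(pair = i, patient_id = pr$hq$patient_id,
                       slice_index = pr$hq$slice_index)
    rows[[length(rows) + 1L]] <-
      cbind(base, arm = "LQ", metric_row(hq8, lq8, params))
    if (!is.null(out8)) {
      rows[[length(rows) + 1L]] <-
        cbind(base, arm = "output", metric_row(hq8, out8, params))
    }
  }
  per_pair <- do.call(rbind, rows)

  metrics <- c("mse", "psnr", "ssim", "vif", "epi", "nv")
  agg <- do.call(rbind, lapply(split(per_pair, per_pair$arm), function(df) {
    do.call(rbind, lapply(metrics, function(mname) {
      v <- df[[mname]]
      data.frame(arm = df$arm[1], metric = mname,
                 mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE),
                 median = stats::median(v, na.rm = TRUE),
                 min = suppressWarnings(min(v, na.rm = TRUE)),
                 max = suppressWarnings(max(v, na.rm = TRUE)),
                 n_missing = sum(is.na(v)))
    }))
  }))
  rownames(agg) <- NULL
  structure(list(per_pair = per_pair, aggregate = agg, params = params),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d pairs, arms: %s\n",
              length(unique(x$per_pair$pair)),
              paste(unique(x$per_pair$arm), collapse = ", ")))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Export a metric report
#'
#' Writes the per-pair records as CSV and/or the aggregate block as JSON.
#' Infinite PSNR values are serialized as the string `"inf"`.
#'
#' @param report a `metric_report`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path)) {
    df <- report$per_pair
    df$psnr <- ifelse(is.infinite(df$psnr), "inf", as.character(df$psnr))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    agg <- report$aggregate
    for (cn in c("mean", "sd", "median", "min", "max")) {
      agg[[cn]] <- ifelse(is.infinite(agg[[cn]]), "inf", agg[[cn]])
    }
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
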