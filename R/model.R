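# The denoising network: a two-stage convolutional encoder (conv/ReLU/pool),
# a bottleneck conv with dropout, a decoder of two x2 transposed-convolution
# stages with encoder skip connections (channel concatenation), a stack of
# DnCNN-style refinement blocks (conv -> batch norm -> ReLU -> dropout) at
# full resolution, and a single-filter reconstruction conv. Inputs are
# 1-channel 8-bit images scaled to [0, 1]; two pooling stages mean H and W
# must be divisible by 4.

#' Network configuration
#'
#' Defaults are the full-size configuration: encoder stages with 64 and 96
#' filters, a 112-channel bottleneck, a 96-channel decoder, 4 refinement
#' blocks and dropout 0.5. A single integer passed for `enc_channels`
#' expands to two equal stages.
#'
#' @param enc_channels length-2 integer (or single int), encoder stage widths.
#' @param mid_channels bottleneck width.
#' @param dec_channels decoder width.
#' @param n_dncnn_blocks number of refinement blocks, >= 1.
#' @param dropout_rate drop probability in `[0, 1)`.
#' @param kernel_size odd conv kernel edge.
#' @param bn_eps batch-norm stabilization constant, > 0.
#' @param use_global_residual if `TRUE` the network predicts a correction
#'   added to its input instead of the image directly.
#' @param window HU display window `(center, width)` used when the model is
#'   applied to CT slices.
#' @return An object of class `denoiser_config`.
#' @export
denoiser_config <- function(enc_channels = c(64, 96), mid_channels = 112,
                            dec_channels = 96, n_dncnn_blocks = 4,
                            dropout_rate = 0.5, kernel_size = 3,
                            bn_eps = 1e-5, use_global_residual = FALSE,
                            window = c(40, 400)) {
  if (length(enc_channels) == 1L) enc_channels <- rep(enc_channels, 2L)
  enc_channels <- as.integer(enc_channels)
  stopifnot(length(enc_channels) == 2L)
  if (any(c(enc_channels, mid_channels, dec_channels) < 1L)) {
    stop("all channel counts must be >= 1", call. = FALSE)
  }
  if (n_dncnn_blocks < 1L) stop("`n_dncnn_blocks` must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd", call. = FALSE)
  if (bn_eps <= 0) stop("`bn_eps` must be > 0", call. = FALSE)
  structure(list(enc_channels = enc_channels,
                 mid_channels = as.integer(mid_channels),
                 dec_channels = as.integer(dec_channels),
                 n_dncnn_blocks = as.integer(n_dncnn_blocks),
                 dropout_rate = dropout_rate,
                 kernel_size = as.integer(kernel_size),
                 bn_eps = bn_eps,
                 use_global_residual = isTRUE(use_global_residual),
                 window = as.numeric(window)),
            class = "denoiser_config")
}

# He-uniform initialization for a conv weight [k, k, Cin, Cout]
he_conv <- function(k, cin, cout) {
  limit <- sqrt(6 / (k * k * cin))
  array(stats::runif(k * k * cin * cout, -limit, limit), c(k, k, cin, cout))
}

# the layer plan as (kind, cin, cout) rows; single source of truth for
# initialization and parameter counting
denoiser_plan <- function(config) {
  e1 <- config$enc_channels[1]; e2 <- config$enc_channels[2]
  md <- config$mid_channels; dc <- config$dec_channels
  plan <- list(
    list(name = "enc1", kind = "conv", cin = 1L, cout = e1),
    list(name = "enc2", kind = "conv", cin = e1, cout = e2),
    list(name = "mid", kind = "conv", cin = e2, cout = md),
    list(name = "up1", kind = "tconv", cin = md, cout = dc),
    list(name = "dec1", kind = "conv", cin = dc + e2, cout = dc),
    list(name = "up2", kind = "tconv", cin = dc, cout = dc),
    list(name = "dec2", kind = "conv", cin = dc + e1, cout = dc)
  )
  for (i in seq_len(config$n_dncnn_blocks)) {
    plan <- c(plan, list(list(name = sprintf("dn%d", i), kind = "dncnn",
                              cin = dc, cout = dc)))
  }
  c(plan, list(list(name = "final", kind = "conv", cin = dc, cout = 1L)))
}

#' Build a denoising network
#'
#' Initializes all parameters (He-uniform convolutions, batch-norm scale 1 /
#' shift 0) deterministically from `seed`.
#'
#' @param config a [denoiser_config()].
#' @param seed integer seed for the initialization draw.
#' @return An object of class `ct_denoiser`: the config plus named parameter
#'   and batch-norm buffer lists.
#' @export
build_denoiser <- function(config = denoiser_config(), seed = 1) {
  stopifnot(inherits(config, "denoiser_config"))
  k <- config$kernel_size
  params <- list()
  buffers <- list()
  withr::with_seed(seed, {
    for (layer in denoiser_plan(config)) {
      nm <- layer$name
      if (layer$kind == "tconv") {
        limit <- sqrt(6 / (4 * layer$cin))
        params[[paste0(nm, "_W")]] <-
          array(stats::runif(4 * layer$cin * layer$cout, -limit, limit),
                c(2L, 2L, layer$cin, layer$cout))
      } else {
        params[[paste0(nm, "_W")]] <- he_conv(k, layer$cin, layer$cout)
      }
      params[[paste0(nm, "_b")]] <- numeric(layer$cout)
      if (layer$kind == "dncnn") {
        params[[paste0(nm, "_gamma")]] <- rep(1, layer$cout)
        params[[paste0(nm, "_beta")]] <- numeric(layer$cout)
        buffers[[paste0(nm, "_rmean")]] <- numeric(layer$cout)
        buffers[[paste0(nm, "_rvar")]] <- rep(1, layer$cout)
      }
    }
  })
  structure(list(config = config, params = params, buffers = buffers,
                 seed = seed),
            class = "ct_denoiser")
}

#' @export
print.ct_denoiser <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ct_denoiser> enc (%d, %d) | mid %d | dec %d | %d refinement blocks\n",
              cfg$enc_channels[1], cfg$enc_channels[2], cfg$mid_channels,
              cfg$dec_channels, cfg$n_dncnn_blocks))
  cat(sprintf("  %s trainable parameters, dropout %.2f, kernel %dx%d\n",
              format(count_parameters(x), big.mark = ","), cfg$dropout_rate,
              cfg$kernel_size, cfg$kernel_size))
  invisible(x)
}

#' Count trainable parameters
#'
#' A pure function of the configuration: each k x k convolution contributes
#' `k^2 * c_in * c_out + c_out`, each 2 x 2 transposed convolution
#' `4 * c_in * c_out + c_out`, each batch norm `2 * c` (scale and shift;
#' running statistics are buffers, not trainable parameters).
#'
#' @param x a `ct_denoiser` or a [denoiser_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  config <- if (inherits(x, "ct_denoiser")) x$config else x
  stopifnot(inherits(config, "denoiser_config"))
  k <- config$kernel_size
  total <- 0
  for (layer in denoiser_plan(config)) {
    total <- total + switch(layer$kind,
      conv = k * k * layer$cin * layer$cout + layer$cout,
      tconv = 4 * layer$cin * layer$cout + layer$cout,
      dncnn = k * k * layer$cin * layer$cout + layer$cout + 2 * layer$cout)
  }
  as.integer(total)
}

check_divisible <- function(H, W) {
  if (H %% 4L != 0L || W %% 4L != 0L) {
    stop(sprintf(paste0("input dimensions must be divisible by 4 ",
                        "(two 2x2 pooling stages); got %d x %d"), H, W),
         call. = FALSE)
  }
}

# full forward pass; x is [H, W, N, 1] in [0, 1].
# training = TRUE uses batch statistics, applies dropout (drawing masks from
# the current RNG stream) and caches every intermediate for the backward
# pass; training = FALSE uses running statistics and caches nothing.
denoiser_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  check_divisible(d[1], d[2])
  cache <- if (training) list() else NULL
  keep <- training

  # drop references the inference path no longer needs so large activations
  # can be collected mid-pass (the training path must keep everything)
  free <- function(...) if (!keep) rm(list = c(...), envir = parent.frame())

  c_enc1 <- nn_conv_fwd(x, p$enc1_W, p$enc1_b, want_cache = keep)
  r_enc1 <- nn_relu_fwd(c_enc1$y)            # skip features s1
  free("c_enc1")
  p1 <- nn_pool_fwd(r_enc1$y)
  c_enc2 <- nn_conv_fwd(p1$y, p$enc2_W, p$enc2_b, want_cache = keep)
  free("p1")
  r_enc2 <- nn_relu_fwd(c_enc2$y)            # skip features s2
  free("c_enc2")
  p2 <- nn_pool_fwd(r_enc2$y)

  c_mid <- nn_conv_fwd(p2$y, p$mid_W, p$mid_b, want_cache = keep)
  free("p2")
  r_mid <- nn_relu_fwd(c_mid$y)
  free("c_mid")
  do_mid <- nn_dropout_fwd(r_mid$y, cfg$dropout_rate, training)
  free("r_mid")

  t_up1 <- nn_tconv_fwd(do_mid$y, p$up1_W, p$up1_b, want_cache = keep)
  free("do_mid")
  cat1 <- nn_concat(t_up1$y, r_enc2$y)
  free("t_up1", "r_enc2")
  c_dec1 <- nn_conv_fwd(cat1, p$dec1_W, p$dec1_b, want_cache = keep)
  free("cat1")
  r_dec1 <- nn_relu_fwd(c_dec1$y)
  free("c_dec1")
  t_up2 <- nn_tconv_fwd(r_dec1$y, p$up2_W, p$up2_b, want_cache = keep)
  free("r_dec1")
  cat2 <- nn_concat(t_up2$y, r_enc1$y)
  free("t_up2", "r_enc1")
  c_dec2 <- nn_conv_fwd(cat2, p$dec2_W, p$dec2_b, want_cache = keep)
  free("cat2")
  r_dec2 <- nn_relu_fwd(c_dec2$y)
  free("c_dec2")

  h <- r_dec2$y
  free("r_dec2")
  dn_caches <- list()
  new_buffers <- model$buffers
  for (i in seq_len(cfg$n_dncnn_blocks)) {
    nm <- sprintf("dn%d", i)
    cv <- nn_conv_fwd(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                      want_cache = keep)
    bn <- nn_bn_fwd(cv$y, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                    new_buffers[[paste0(nm, "_rmean")]],
                    new_buffers[[paste0(nm, "_rvar")]],
                    cfg$bn_eps, training)
    new_buffers[[paste0(nm, "_rmean")]] <- bn$rmean
    new_buffers[[paste0(nm, "_rvar")]] <- bn$rvar
    rl <- nn_relu_fwd(bn$y)
    dro <- nn_dropout_fwd(rl$y, cfg$dropout_rate, training)
    if (keep) dn_caches[[i]] <- list(cv = cv, bn = bn, rl = rl, dro = dro)
    h <- dro$y
  }

  c_fin <- nn_conv_fwd(h, p$final_W, p$final_b, want_cache = keep)
  y <- c_fin$y
  if (cfg$use_global_residual) y <- y + x

  if (keep) {
    cache <- list(c_enc1 = c_enc1, r_enc1 = r_enc1, p1 = p1,
                  c_enc2 = c_enc2, r_enc2 = r_enc2, p2 = p2,
                  c_mid = c_mid, r_mid = r_mid, do_mid = do_mid,
                  t_up1 = t_up1, c_dec1 = c_dec1, r_dec1 = r_dec1,
                  t_up2 = t_up2, c_dec2 = c_dec2, r_dec2 = r_dec2,
                  dn = dn_caches, c_fin = c_fin)
  }
  list(y = y, cache = cache, buffers = new_buffers)
}

# gradients of the scalar loss wrt every parameter, given dL/dy
denoiser_backward <- function(model, cache, dy) {
  cfg <- model$config
  p <- model$params
  g <- list()

  bk <- nn_conv_bwd(dy, cache$c_fin, p$final_W)
  g$final_W <- bk$dW; g$final_b <- bk$db
  dh <- bk$dx

  for (i in rev(seq_len(cfg$n_dncnn_blocks))) {
    nm <- sprintf("dn%d", i)
    cc <- cache$dn[[i]]
    dh <- nn_dropout_bwd(dh, cc$dro)
    dh <- nn_relu_bwd(dh, cc$rl)
    bnb <- nn_bn_bwd(dh, cc$bn, p[[paste0(nm, "_gamma")]])
    g[[paste0(nm, "_gamma")]] <- bnb$dgamma
    g[[paste0(nm, "_beta")]] <- bnb$dbeta
    cvb <- nn_conv_bwd(bnb$dx, cc$cv, p[[paste0(nm, "_W")]])
    g[[paste0(nm, "_W")]] <- cvb$dW
    g[[paste0(nm, "_b")]] <- cvb$db
    dh <- cvb$dx
  }

  dh <- nn_relu_bwd(dh, cache$r_dec2)
  bk <- nn_conv_bwd(dh, cache$c_dec2, p$dec2_W)
  g$dec2_W <- bk$dW; g$dec2_b <- bk$db
  e1 <- cfg$enc_channels[1]; e2 <- cfg$enc_channels[2]
  dc <- cfg$dec_channels
  dcat2 <- bk$dx
  d_up2 <- dcat2[, , , seq_len(dc), drop = FALSE]
  d_s1 <- dcat2[, , , dc + seq_len(e1), drop = FALSE]

  bk <- nn_tconv_bwd(d_up2, cache$t_up2, p$up2_W)
  g$up2_W <- bk$dW; g$up2_b <- bk$db
  dh <- nn_relu_bwd(bk$dx, cache$r_dec1)
  bk <- nn_conv_bwd(dh, cache$c_dec1, p$dec1_W)
  g$dec1_W <- bk$dW; g$dec1_b <- bk$db
  dcat1 <- bk$dx
  d_up1 <- dcat1[, , , seq_len(dc), drop = FALSE]
  d_s2 <- dcat1[, , , dc + seq_len(e2), drop = FALSE]

  bk <- nn_tconv_bwd(d_up1, cache$t_up1, p$up1_W)
  g$up1_W <- bk$dW; g$up1_b <- bk$db
  dh <- nn_dropout_bwd(bk$dx, cache$do_mid)
  dh <- nn_relu_bwd(dh, cache$r_mid)
  bk <- nn_conv_bwd(dh, cache$c_mid, p$mid_W)
  g$mid_W <- bk$dW; g$mid_b <- bk$db

  dh <- nn_pool_bwd(bk$dx, cache$p2)
  dh <- dh + d_s2                      # skip connection gradient re-enters
  dh <- nn_relu_bwd(dh, cache$r_enc2)
  bk <- nn_conv_bwd(dh, cache$c_enc2, p$enc2_W)
  g$enc2_W <- bk$dW; g$enc2_b <- bk$db

  dh <- nn_pool_bwd(bk$dx, cache$p1)
  dh <- dh + d_s1
  dh <- nn_relu_bwd(dh, cache$r_enc1)
  bk <- nn_conv_bwd(dh, cache$c_enc1, p$enc1_W)
  g$enc1_W <- bk$dW; g$enc1_b <- bk$db

  g
}

#' Denoise an 8-bit image
#'
#' Runs the network in inference mode (dropout off, batch norm using running
#' statistics); the output is clipped to `[0, 255]` and quantized half-up,
#' so repeated calls on the same input are bit-identical.
#'
#' @param model a trained (or freshly built) `ct_denoiser`.
#' @param img8 an [image8()] whose dimensions are divisible by 4.
#' @return An [image8()] carrying the same window.
#' @export
denoise <- function(model, img8) {
  stopifnot(inherits(model, "ct_denoiser"), inherits(img8, "image8"))
  d <- dim(img8$pixels)
  check_divisible(d[1], d[2])
  x <- array(img8$pixels / 255, c(d[1], d[2], 1L, 1L))
  y <- denoiser_forward(model, x, training = FALSE)$y[, , 1L, 1L]
  y <- round_half_up(y * 255)
  y[y < 0] <- 0
  y[y > 255] <- 255
  image8(matrix(y, d[1], d[2]), img8$window)
}

#' Denoise a CT slice in Hounsfield units
#'
#' Windows the slice with the model's configured window, denoises the 8-bit
#' image, and maps the result back to HU (exact up to the window clipping
#' and 8-bit quantization).
#'
#' @param model a `ct_denoiser`.
#' @param ct a [ct_image()].
#' @return A `ct_image` with dose tag `"OUTPUT"`.
#' @export
denoise_ct <- function(model, ct) {
  stopifnot(inherits(ct, "ct_image"))
  out8 <- denoise(model, hu_to_uint8(ct, model$config$window))
  uint8_to_hu(out8, template = ct, dose_tag = "OUTPUT")
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores weights, batch-norm buffers, the configuration and
#' the initialization seed under a versioned schema.
#'
#' @param model a `ct_denoiser`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `ct_denoiser`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ct_denoiser"))
  saveRDS(list(schema = "ct_denoiser/1", config = unclass(model$config),
               params = model$params, buffers = model$buffers,
               seed = model$seed), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "ct_denoiser/1")) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  cfg <- obj$config
  config <- denoiser_config(cfg$enc_channels, cfg$mid_channels,
                            cfg$dec_channels, cfg$n_dncnn_blocks,
                            cfg$dropout_rate, cfg$kernel_size, cfg$bn_eps,
                            cfg$use_global_residual, cfg$window)
  structure(list(config = config, params = obj$params,
                 buffers = obj$buffers, seed = obj$seed),
            class = "ct_denoiser")
}
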