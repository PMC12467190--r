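# Patient-level splitting, paired geometric augmentation, and the MSE
# training loop (Adam, best-on-validation checkpointing).

#' Training configuration
#'
#' Defaults follow the study protocol this package emulates: batch size 6,
#' learning rate 0.003, augmentation factor 4 with rotations within +/-10
#' degrees and flips at probability 0.5, and a 15/4/4 patient split. Note
#' the printed final learning rate (0.003) sits above the fine-tuning search
#' interval (1e-5 to 1e-4); desk-scale runs are typically stabler around
#' 1e-3 to 1e-4.
#'
#' @param batch_size images per optimization step, >= 1.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training set.
#' @param augmentation_factor derived pairs per training pair.
#' @param rotation_range_deg rotations drawn uniformly in +/- this range.
#' @param flip_prob probability of each of horizontal and vertical flips.
#' @param split_counts patients in (train, validation, test).
#' @param seed master seed for shuffling, augmentation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 6, learning_rate = 3e-3, epochs = 10,
                         augmentation_factor = 4, rotation_range_deg = 10,
                         flip_prob = 0.5, split_counts = c(15, 4, 4),
                         seed = 1) {
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (flip_prob < 0 || flip_prob > 1) {
    stop("`flip_prob` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 augmentation_factor = as.integer(augmentation_factor),
                 rotation_range_deg = rotation_range_deg,
                 flip_prob = flip_prob,
                 split_counts = as.integer(split_counts),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split a paired dataset by patient
#'
#' Shuffles patient ids and assigns whole patients to the train, validation
#' and test subsets, so no subject contributes slices to two subsets.
#' Deterministic given `seed`.
#'
#' @param pairs list of [image_pair()].
#' @param split_counts integer (train, val, test) patient counts; must sum
#'   to the number of distinct patients.
#' @param seed integer seed.
#' @return List with elements `train`, `val`, `test` (lists of pairs).
#' @export
split_by_patient <- function(pairs, split_counts = c(15, 4, 4), seed = 1) {
  ids <- vapply(pairs, function(p) p$hq$patient_id, "")
  patients <- unique(ids)
  split_counts <- as.integer(split_counts)
  if (length(split_counts) != 3L || sum(split_counts) != length(patients)) {
    stop(sprintf("split counts must sum to the %d patients present",
                 length(patients)), call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(patients))
  grp <- rep(c("train", "val", "test"), times = split_counts)
  assignment <- stats::setNames(grp, shuffled)
  list(train = pairs[assignment[ids] == "train"],
       val = pairs[assignment[ids] == "val"],
       test = pairs[assignment[ids] == "test"])
}

#' Rotate an image about its center with bilinear interpolation
#'
#' Inverse-mapping resampler: each output pixel looks up its rotated source
#' position and interpolates bilinearly; positions falling outside the
#' support take `fill` (air, for CT).
#'
#' @param mat numeric matrix.
#' @param angle_deg rotation angle, degrees counter-clockwise.
#' @param fill value used outside the source support.
#' @return Matrix of the same size.
#' @export
rotate_image <- function(mat, angle_deg, fill = -1000) {
  if (angle_deg == 0) return(mat)
  m <- nrow(mat); n <- ncol(mat)
  th <- angle_deg * pi / 180
  cr <- (m + 1) / 2; cc <- (n + 1) / 2
  r <- matrix(seq_len(m) - cr, m, n)
  cl <- matrix(seq_len(n) - cc, m, n, byrow = TRUE)
  # inverse rotation of output coordinates into the source frame
  sr <- cos(th) * r + sin(th) * cl + cr
  sc <- -sin(th) * r + cos(th) * cl + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inside <- sr >= 1 & sr <= m & sc >= 1 & sc <= n
  # clamp neighbor indices: where a source coordinate is exactly integral
  # (or on the last row/col) the clamped neighbor carries zero weight
  r0c <- pmin(pmax(r0, 1), m); r1c <- pmin(r0 + 1, m)
  c0c <- pmin(pmax(c0, 1), n); c1c <- pmin(c0 + 1, n)
  get_px <- function(ri, ci) {
    v <- matrix(fill, m, n)
    v[inside] <- mat[cbind(ri[inside], ci[inside])]
    v
  }
  v00 <- get_px(r0c, c0c); v10 <- get_px(r1c, c0c)
  v01 <- get_px(r0c, c1c); v11 <- get_px(r1c, c1c)
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  out[!inside] <- fill
  out
}

apply_geom <- function(px, angle, hflip, vflip, fill) {
  if (angle != 0) px <- rotate_image(px, angle, fill)
  if (hflip) px <- px[, ncol(px):1, drop = FALSE]
  if (vflip) px <- px[nrow(px):1, , drop = FALSE]
  px
}

#' Derive augmented copies of a training pair
#'
#' Draws `factor` random geometric transforms (rotation uniform in
#' `+/-rotation_range_deg`, horizontal and vertical flips each with
#' probability `flip_prob`) and applies each transform identically to the HQ
#' and LQ slices, so paired supervision stays aligned. Derived pairs carry
#' the attribute `augmented = TRUE` for data-hygiene checks.
#'
#' @param pair an [image_pair()].
#' @param factor number of derived pairs.
#' @param rotation_range_deg,flip_prob transform distribution parameters.
#' @param fill_hu fill value outside the rotated support.
#' @param seed integer seed.
#' @return List of `factor` derived [image_pair()]s.
#' @export
augment_pair <- function(pair, factor = 4, rotation_range_deg = 10,
                         flip_prob = 0.5, fill_hu = -1000, seed = 1) {
  stopifnot(inherits(pair, "image_pair"))
  draws <- withr::with_seed(seed, {
    data.frame(angle = stats::runif(factor, -rotation_range_deg,
                                    rotation_range_deg),
               hflip = stats::runif(factor) < flip_prob,
               vflip = stats::runif(factor) < flip_prob)
  })
  lapply(seq_len(factor), function(i) {
    hq_px <- apply_geom(pair$hq$pixels, draws$angle[i], draws$hflip[i],
                        draws$vflip[i], fill_hu)
    lq_px <- apply_geom(pair$lq$pixels, draws$angle[i], draws$hflip[i],
                        draws$vflip[i], fill_hu)
    mk <- function(px, tmpl, tag) ct_image(px, tmpl$pixel_spacing,
                                           tmpl$patient_id, tmpl$slice_index,
                                           tag)
    out <- image_pair(mk(hq_px, pair$hq, "HQ"), mk(lq_px, pair$lq, "LQ"),
                      pair$dose_fraction)
    attr(out, "augmented") <- TRUE
    out
  })
}

# stack pairs into [H, W, N, 1] input/target arrays in [0, 1]
pairs_to_arrays <- function(pairs, window) {
  d <- dim(pairs[[1]]$hq$pixels)
  n <- length(pairs)
  x <- array(0, c(d[1], d[2], n, 1L))
  y <- array(0, c(d[1], d[2], n, 1L))
  for (i in seq_len(n)) {
    x[, , i, 1L] <- hu_to_uint8(pairs[[i]]$lq, window)$pixels / 255
    y[, , i, 1L] <- hu_to_uint8(pairs[[i]]$hq, window)$pixels / 255
  }
  list(x = x, y = y)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a denoising network on paired slices
#'
#' Minimizes the mean squared error between the network output and the HQ
#' reference with Adam, evaluating the validation loss every epoch and
#' returning the parameters that achieved the best validation loss.
#' Augmentation (if `cfg$augmentation_factor > 1`) is applied to the
#' training pairs only. Aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param model a freshly built (or warm) `ct_denoiser`.
#' @param train_pairs,val_pairs lists of [image_pair()]; validation pairs
#'   must not carry the `augmented` attribute.
#' @param cfg a [train_config()].
#' @param augment apply paired augmentation to the training set.
#' @param verbose print per-epoch losses.
#' @return List with `model` (best-on-validation) and `history` (data.frame
#'   of epoch, train_loss, val_loss).
#' @export
train_denoiser <- function(model, train_pairs, val_pairs,
                           cfg = train_config(), augment = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(model, "ct_denoiser"), length(train_pairs) > 0,
            length(val_pairs) > 0)
  if (any(vapply(val_pairs, function(p) isTRUE(attr(p, "augmented")), TRUE))) {
    stop("validation pairs must not be augmented", call. = FALSE)
  }
  if (augment && cfg$augmentation_factor > 1) {
    train_pairs <- unlist(lapply(seq_along(train_pairs), function(i) {
      augment_pair(train_pairs[[i]], cfg$augmentation_factor,
                   cfg$rotation_range_deg, cfg$flip_prob,
                   seed = cfg$seed + i)
    }), recursive = FALSE)
  }
  window <- model$config$window
  tr <- pairs_to_arrays(train_pairs, window)
  va <- pairs_to_arrays(val_pairs, window)
  n <- dim(tr$x)[3]

  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = model$params, buffers = model$buffers)

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (i0 in seq(1L, n, cfg$batch_size)) {
        idx <- ord[i0:min(i0 + cfg$batch_size - 1L, n)]
        xb <- tr$x[, , idx, , drop = FALSE]
        yb <- tr$y[, , idx, , drop = FALSE]
        fwd <- denoiser_forward(model, xb, training = TRUE)
        model$buffers <- fwd$buffers
        resid <- fwd$y - yb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged at epoch %d (non-finite loss); try a smaller learning rate",
                       epoch), call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- denoiser_backward(model, fwd$cache,
                                   2 * resid / length(resid))
        upd <- adam_step(model$params, grads, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      vl <- mean((denoiser_forward(model, va$x, training = FALSE)$y - va$y)^2)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / n,
                                  val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %2d  train %.6f  val %.6f", epoch,
                        ep_loss / n, vl))
      }
      if (vl < best$loss) {
        best <- list(loss = vl, params = model$params,
                     buffers = model$buffers)
      }
    }
  })
  model$params <- best$params
  model$buffers <- best$buffers
  list(model = model, history = history)
}
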