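# Layer kernels for the denoising network. Activations are 4-D arrays laid
# out [H, W, N, C] (batch in the third slot) so that a column-major flatten
# is directly the (pixel, sample) x channel matrix BLAS wants. Convolutions
# go through im2col + one matrix product; backward passes are exact
# analytic gradients (finite-difference checked in the test suite).

# ---- simple 2-D kernels exposed for unit testing ---------------------------

#' 2-D convolution of a single-channel image
#'
#' Cross-correlation (the deep-learning convention: the kernel is not
#' flipped) with zero padding preserving the spatial size for odd kernels.
#'
#' @param x numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @param bias scalar added to every output.
#' @return Matrix of the same size as `x`.
#' @export
conv2d <- function(x, kernel, bias = 0) {
  k <- dim(kernel)
  if (any(k %% 2L == 0L)) stop("kernel dimensions must be odd", call. = FALSE)
  if (any(k > dim(x) + k - 1)) stop("kernel larger than padded input", call. = FALSE)
  x4 <- array(x, c(nrow(x), ncol(x), 1L, 1L))
  w4 <- array(kernel, c(k[1], k[2], 1L, 1L))
  nn_conv_fwd(x4, w4, bias)$y[, , 1L, 1L]
}

#' Rectified linear unit, `max(0, x)`
#' @param x numeric array.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' 2-D max pooling with a square window and matching stride
#'
#' @param x numeric matrix with dimensions divisible by `size`.
#' @param size pooling window edge (and stride).
#' @export
maxpool2d <- function(x, size = 2L) {
  d <- dim(x)
  if (any(d %% size != 0L)) {
    stop(sprintf("input dimensions must be divisible by %d", size), call. = FALSE)
  }
  out <- matrix(-Inf, d[1] %/% size, d[2] %/% size)
  for (di in seq_len(size)) for (dj in seq_len(size)) {
    out <- pmax(out, x[seq(di, d[1], size), seq(dj, d[2], size), drop = FALSE])
  }
  out
}

#' Batch normalization of a matrix (batch statistics)
#'
#' Normalizes with the batch mean and (population) variance:
#' `(x - mu) / sqrt(var + eps)`, then applies scale and shift.
#'
#' @param x numeric vector/matrix treated as one activation channel.
#' @param gamma,beta scale and shift.
#' @param eps stabilization constant.
#' @export
batchnorm <- function(x, gamma = 1, beta = 0, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  gamma * (x - mu) / sqrt(v + eps) + beta
}

#' Inverted-dropout mask
#'
#' Binary keep mask scaled by `1/(1-rate)` so activation expectations are
#' unchanged; multiply activations by the mask during training.
#'
#' @param n number of mask entries.
#' @param rate drop probability in `[0, 1)`.
#' @param seed optional seed for a reproducible mask.
#' @export
dropout_mask <- function(n, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)", call. = FALSE)
  draw <- function() (stats::runif(n) >= rate) / (1 - rate)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# ---- batched internal layers ----------------------------------------------

# forward conv, same padding; x [H,W,N,C], ww [k,k,Cin,Cout], b length Cout.
# Xcol keeps one contiguous block of C columns per kernel offset (channel
# fastest within a block), so the weight matrix is the (cin, di, dj)
# permutation of ww. Banded evaluation keeps peak memory bounded for large
# single-image inference.
.im2col_cache <- new.env(parent = emptyenv())

# linear gather indices mapping a padded [Hp, Wp, N, C] array to the im2col
# matrix (rows: pixels x samples; cols: C channels per kernel offset);
# cached per geometry since training reuses a handful of shapes constantly
im2col_idx <- function(H, Wd, N, C, k) {
  key <- paste(H, Wd, N, C, k, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  rowbase <- as.double(seq_len(H)) +
    rep((seq_len(Wd) - 1) * Hp, each = H)
  rowbase <- rep(rowbase, times = N) +
    rep((seq_len(N) - 1) * (Hp * Wp), each = H * Wd)
  offs <- as.vector(vapply(0:(k - 1L), function(dj) {
    vapply(0:(k - 1L), function(di) {
      di + dj * Hp + (seq_len(C) - 1) * (Hp * Wp * N)
    }, numeric(C))
  }, matrix(0, C, k)))
  idx <- outer(rowbase, offs, `+`)
  storage.mode(idx) <- "integer"   # integer indexing takes R's fast path
  # unbounded shapes (large one-off inferences) are not worth caching
  if (length(idx) <= 3e7) .im2col_cache[[key]] <- idx
  idx
}

nn_conv_fwd <- function(x, ww, b, want_cache = FALSE, max_elems = 2e7) {
  dm <- dim(x); H <- dm[1]; Wd <- dm[2]; N <- dm[3]; C <- dm[4]
  k <- dim(ww)[1]; Cout <- dim(ww)[4]
  p <- (k - 1L) %/% 2L
  k2 <- k * k
  Wm <- matrix(aperm(ww, c(3L, 1L, 2L, 4L)), k2 * C, Cout)

  xp <- array(0, c(H + 2L * p, Wd + 2L * p, N, C))
  xp[(p + 1L):(p + H), (p + 1L):(p + Wd), , ] <- x

  build_cols <- function(j1, j2) {
    wdb <- j2 - j1 + 1L
    Xcol <- matrix(0, H * wdb * N, k2 * C)
    for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
      o <- dj * k + di
      Xcol[, (o * C + 1L):(o * C + C)] <-
        xp[(di + 1L):(di + H), (dj + j1):(dj + j2), , , drop = FALSE]
    }
    Xcol
  }

  if (!want_cache && as.double(H) * Wd * N * k2 * C > max_elems && N == 1L) {
    # banded over columns (contiguous in memory when N == 1)
    y <- array(0, c(H, Wd, N, Cout))
    nb <- ceiling(as.double(H) * Wd * k2 * C / max_elems)
    bounds <- unique(round(seq(0L, Wd, length.out = nb + 1L)))
    for (bi in seq_len(length(bounds) - 1L)) {
      j1 <- bounds[bi] + 1L; j2 <- bounds[bi + 1L]
      yb <- build_cols(j1, j2) %*% Wm
      yb <- yb + rep(b, each = nrow(yb))
      y[, j1:j2, , ] <- array(yb, c(H, j2 - j1 + 1L, N, Cout))
    }
    return(list(y = y))
  }

  idx <- im2col_idx(H, Wd, N, C, k)
  Xcol <- xp[idx]
  dim(Xcol) <- dim(idx)
  y <- Xcol %*% Wm
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(H, Wd, N, Cout)
  if (want_cache) list(y = y, Xcol = Xcol, in_dim = dm) else list(y = y)
}

nn_conv_bwd <- function(dy, cache, ww) {
  dm <- cache$in_dim
  k <- dim(ww)[1]; Cout <- dim(ww)[4]; C <- dm[4]
  dY <- matrix(dy, prod(dm[1:3]), Cout)
  dWm <- crossprod(cache$Xcol, dY)        # rows ordered (cin, di, dj)
  dW <- aperm(array(dWm, c(C, k, k, Cout)), c(2L, 3L, 1L, 4L))
  db <- colSums(dY)
  # input gradient of a same-padded correlation: correlate dy with the
  # spatially flipped kernel, input/output channels swapped
  wT <- aperm(ww[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  dx <- nn_conv_fwd(dy, wT, numeric(C))$y
  list(dx = dx, dW = dW, db = db)
}

# transposed conv, kernel 2, stride 2 (exact x2 upsampling, no overlap)
nn_tconv_fwd <- function(x, ww, b, want_cache = FALSE) {
  dm <- dim(x); H <- dm[1]; Wd <- dm[2]; N <- dm[3]; C <- dm[4]
  Cout <- dim(ww)[4]
  Xmat <- matrix(x, H * Wd * N, C)
  y <- array(0, c(2L * H, 2L * Wd, N, Cout))
  for (dj in 1:2) for (di in 1:2) {
    Wo <- matrix(ww[di, dj, , ], C, Cout)
    yo <- Xmat %*% Wo
    yo <- yo + rep(b, each = nrow(yo))
    y[seq(di, 2L * H, 2L), seq(dj, 2L * Wd, 2L), , ] <-
      array(yo, c(H, Wd, N, Cout))
  }
  if (want_cache) list(y = y, Xmat = Xmat, in_dim = dm) else list(y = y)
}

nn_tconv_bwd <- function(dy, cache, ww) {
  dm <- cache$in_dim; H <- dm[1]; Wd <- dm[2]; N <- dm[3]; C <- dm[4]
  Cout <- dim(ww)[4]
  dW <- array(0, dim(ww))
  db <- numeric(Cout)
  dXmat <- matrix(0, H * Wd * N, C)
  for (dj in 1:2) for (di in 1:2) {
    dYo <- matrix(dy[seq(di, 2L * H, 2L), seq(dj, 2L * Wd, 2L), , , drop = FALSE],
                  H * Wd * N, Cout)
    Wo <- matrix(ww[di, dj, , ], C, Cout)
    dW[di, dj, , ] <- crossprod(cache$Xmat, dYo)
    db <- db + colSums(dYo)
    dXmat <- dXmat + tcrossprod(dYo, Wo)
  }
  list(dx = array(dXmat, dm), dW = dW, db = db)
}

nn_pool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, Wd, 2L)
  a <- x[io, jo, , , drop = FALSE]
  b <- x[io + 1L, jo, , , drop = FALSE]
  cc <- x[io, jo + 1L, , , drop = FALSE]
  dd <- x[io + 1L, jo + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  wa <- y == a
  wb <- (y == b) & !wa
  wc <- (y == cc) & !wa & !wb
  wd <- !(wa | wb | wc)
  list(y = y, masks = list(wa, wb, wc, wd), in_dim = d)
}

nn_pool_bwd <- function(dy, cache) {
  d <- cache$in_dim; H <- d[1]; Wd <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, Wd, 2L)
  m <- cache$masks
  dx <- array(0, d)
  dx[io, jo, , ] <- dy * m[[1]]
  dx[io + 1L, jo, , ] <- dy * m[[2]]
  dx[io, jo + 1L, , ] <- dy * m[[3]]
  dx[io + 1L, jo + 1L, , ] <- dy * m[[4]]
  dx
}

nn_relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, mask = x > 0)
}

nn_relu_bwd <- function(dy, cache) dy * cache$mask

# per-channel batch norm over (H, W, N); biased variance for normalization,
# running stats (momentum 0.1) for inference
nn_bn_fwd <- function(x, gamma, beta, rmean, rvar, eps, training,
                      momentum = 0.1) {
  d <- dim(x); C <- d[4]
  Xm <- matrix(x, prod(d[1:3]), C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm * Xm) - mu^2
    v[v < 0] <- 0
    new_rmean <- (1 - momentum) * rmean + momentum * mu
    new_rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar
    new_rmean <- rmean; new_rvar <- rvar
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (Xm - rep(mu, each = nrow(Xm))) * rep(inv_sd, each = nrow(Xm))
  y <- xhat * rep(gamma, each = nrow(Xm)) + rep(beta, each = nrow(Xm))
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd = inv_sd, in_dim = d,
       rmean = new_rmean, rvar = new_rvar)
}

nn_bn_bwd <- function(dy, cache, gamma) {
  d <- cache$in_dim; C <- d[4]
  M <- prod(d[1:3])
  dY <- matrix(dy, M, C)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = M)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- (dxhat - rep(s1 / M, each = M) -
           cache$xhat * rep(s2 / M, each = M)) * rep(cache$inv_sd, each = M)
  list(dx = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

nn_dropout_fwd <- function(x, rate, training) {
  if (!training || rate == 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

nn_dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# channel concatenation (channel is the last dimension, so this is a
# straight memory concatenation)
nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3], da[4] + db[4]))
}
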