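# Shared fixtures: tiny configurations and small random images built in code.

tiny_config <- function(dropout = 0) {
  denoiser_config(enc_channels = c(2, 3), mid_channels = 4, dec_channels = 3,
                  n_dncnn_blocks = 1, dropout_rate = dropout)
}

desk_config <- function() {
  denoiser_config(enc_channels = c(6, 8), mid_channels = 10, dec_channels = 8,
                  n_dncnn_blocks = 2, dropout_rate = 0.1)
}

rand_mat <- function(m, n = m, lo = 0, hi = 255, seed = NULL) {
  draw <- function() matrix(runif(m * n, lo, hi), m, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

flat_ct <- function(value = 0, m = 32, n = 32, spacing = c(1, 1)) {
  ct_image(matrix(value, m, n), pixel_spacing = spacing)
}

table5_summaries <- function() load_reader_summaries()

# brute-force double-loop oracles, kept deliberately naive
oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    s <- s + (a[i, j] - b[i, j])^2
  }
  s / (nrow(a) * ncol(a))
}

oracle_conv2d <- function(x, kern, bias = 0) {
  k <- nrow(kern)
  p <- (k - 1) / 2
  m <- nrow(x); n <- ncol(x)
  xp <- matrix(0, m + 2 * p, n + 2 * p)
  xp[(p + 1):(p + m), (p + 1):(p + n)] <- x
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      acc <- acc + xp[i + a - 1, j + b - 1] * kern[a, b]
    }
    out[i, j] <- acc + bias
  }
  out
}

oracle_ssim_global <- function(a, b, C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2) {
  mux <- mean(a); muy <- mean(b)
  vx <- mean((a - mux)^2); vy <- mean((b - muy)^2)
  cxy <- mean((a - mux) * (b - muy))
  ((2 * mux * muy + C1) * (2 * cxy + C2)) /
    ((mux^2 + muy^2 + C1) * (vx + vy + C2))
}

oracle_epi_ratio <- function(ref, out) {
  m <- nrow(ref); n <- ncol(ref)
  gx <- function(x, i, j) if (j < n) x[i, j + 1] - x[i, j] else 0
  gy <- function(x, i, j) if (i < m) x[i + 1, j] - x[i, j] else 0
  num <- 0; den <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    num <- num + (gx(ref, i, j) - gx(out, i, j))^2 +
      (gy(ref, i, j) - gy(out, i, j))^2
    den <- den + gx(ref, i, j)^2 + gy(ref, i, j)^2
  }
  num / den
}

oracle_nv <- function(x) {
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / length(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  s / length(x)
}
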