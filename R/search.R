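# Desk-scale hyperparameter search over the tuning spaces used for the
# network. The sampler is a seeded random search; when every dimension is
# finite and the full grid fits inside the budget the grid is enumerated
# first, so small discrete spaces are searched exhaustively.

space_dim <- function(x) {
  if (is.list(x) && !is.null(x$type)) return(x)
  list(type = "choice", values = x)
}

#' Define a hyperparameter search space
#'
#' Each dimension is either a finite choice set (any vector), or a
#' continuous interval declared with `uniform(lo, hi)` /
#' `log_uniform(lo, hi)`. The defaults are the fine-tuning space: dropout
#' uniform in `[0.4, 0.5]`, encoder channels in `{64, 96, 112}`, middle in
#' `{96, 112, 128}`, decoder in `{64, 96, 112}`, refinement blocks in
#' `{3, 4, 5}`, learning rate log-uniform in `[1e-5, 1e-4]`, batch size in
#' `{4, 6, 8}`.
#'
#' @param dropout,enc_channels,mid_channels,dec_channels,dncnn_blocks,learning_rate,batch_size
#'   the dimensions (see above).
#' @return An object of class `search_space` (named list of dimensions).
#' @export
search_space <- function(dropout = uniform(0.4, 0.5),
                         enc_channels = c(64, 96, 112),
                         mid_channels = c(96, 112, 128),
                         dec_channels = c(64, 96, 112),
                         dncnn_blocks = c(3, 4, 5),
                         learning_rate = log_uniform(1e-5, 1e-4),
                         batch_size = c(4, 6, 8)) {
  dims <- list(dropout = dropout, enc_channels = enc_channels,
               mid_channels = mid_channels, dec_channels = dec_channels,
               dncnn_blocks = dncnn_blocks, learning_rate = learning_rate,
               batch_size = batch_size)
  structure(lapply(dims, space_dim), class = "search_space")
}

#' @rdname search_space
#' @param lo,hi interval bounds.
#' @export
uniform <- function(lo, hi) list(type = "uniform", lo = lo, hi = hi)

#' @rdname search_space
#' @export
log_uniform <- function(lo, hi) {
  stopifnot(lo > 0, hi > lo)
  list(type = "loguniform", lo = lo, hi = hi)
}

sample_dim <- function(dm) {
  switch(dm$type,
         choice = dm$values[[sample.int(length(dm$values), 1L)]],
         uniform = stats::runif(1, dm$lo, dm$hi),
         loguniform = exp(stats::runif(1, log(dm$lo), log(dm$hi))),
         stop("unknown dimension type"))
}

space_is_finite <- function(space) {
  all(vapply(space, function(d) d$type == "choice", TRUE))
}

space_grid <- function(space) {
  grid <- expand.grid(lapply(space, `[[`, "values"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

#' Random search over a hyperparameter space
#'
#' Draws `budget` configurations from `space` (enumerating the full grid
#' first when the space is finite and no larger than the budget), evaluates
#' `objective` on each, and returns the configuration with the smallest
#' objective value together with a replayable trial log.
#'
#' @param space a [search_space()] (or any named list of dimensions).
#' @param budget number of evaluations, >= 1.
#' @param objective function taking a named list of hyperparameter values
#'   and returning a single numeric score to minimize (e.g. a validation
#'   MSE).
#' @param seed integer seed making the trial sequence reproducible.
#' @return List with `best` (named list of values), `best_objective`, and
#'   `trials` (data.frame with one row per evaluation, its objective, and
#'   the running best).
#' @export
hyperparameter_search <- function(space, budget, objective, seed = 1) {
  if (length(space) == 0L) stop("`space` is empty", call. = FALSE)
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  space <- lapply(space, space_dim)

  configs <- withr::with_seed(seed, {
    out <- list()
    if (space_is_finite(space)) {
      grid <- space_grid(space)
      if (length(grid) <= budget) out <- grid
    }
    while (length(out) < budget) {
      out[[length(out) + 1L]] <- lapply(space, sample_dim)
    }
    out
  })

  scores <- vapply(configs, function(cf) as.numeric(objective(cf)), 0)
  trials <- cbind(do.call(rbind, lapply(configs, as.data.frame)),
                  objective = scores, best_so_far = cummin(scores))
  best_i <- which.min(scores)
  list(best = configs[[best_i]], best_objective = scores[best_i],
       trials = trials)
}
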