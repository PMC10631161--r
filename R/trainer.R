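# Dice-loss training: Adam with weight decay 1e-5, batch size 2, learning
# rate decaying from 2e-4 (epoch 0) to 4e-7 (epoch 999) over 1000 epochs,
# random 32-slice slabs as network inputs, seed 1000, case-level 80/20
# split. All RNG streams derive from the configured seed.

#' Training configuration
#'
#' @param epochs Training epochs (default 1000).
#' @param batch_size Slabs per optimization step (default 2).
#' @param lr_initial,lr_final Learning-rate endpoints at epoch 0 and
#'   `epochs - 1` (defaults 2e-4 and 4e-7).
#' @param weight_decay L2 coupling added to the Adam gradient (1e-5).
#' @param slab_depth Consecutive slices per input slab (32, divisible by 16).
#' @param seed Master seed (1000); split, slab sampling, dropout and - by
#'   convention - weight initialization all derive from it.
#' @param train_fraction Case-level training share (0.8).
#' @param lr_schedule `"loglinear"` (default), `"linear"` or `"cosine"`
#'   interpolation between the endpoints.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, batch_size = 2L, lr_initial = 2e-4,
                         lr_final = 4e-7, weight_decay = 1e-5,
                         slab_depth = 32L, seed = 1000L, train_fraction = 0.8,
                         lr_schedule = c("loglinear", "linear", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  if (lr_final <= 0 || lr_final > lr_initial) stop("need 0 < lr_final <= lr_initial")
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0, 1)")
  if (slab_depth %% 16L != 0L) stop("slab_depth must be divisible by 16")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_final = lr_final,
                 weight_decay = weight_decay, slab_depth = as.integer(slab_depth),
                 seed = as.integer(seed), train_fraction = train_fraction,
                 lr_schedule = lr_schedule),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum p + sum g + eps)` with `eps = 1e-5`: the
#' soft complement of the Dice score, robust to the extreme
#' foreground/background imbalance of small tumors (the motivation for
#' choosing Dice over cross-entropy here).
#'
#' @param pred Probability array in [0, 1].
#' @param target Binary array of the same shape (or [ct_mask()]).
#' @param eps Smoothing constant.
#' @return Loss in [0, 1].
#' @export
dice_loss <- function(pred, target, eps = 1e-5) {
  if (inherits(target, "ct_mask")) target <- target$data
  if (inherits(pred, "ct_volume")) pred <- pred$data
  if (!identical(dim(pred), dim(target))) {
    stop("prediction and target shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ", paste(dim(target), collapse = "x"))
  }
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# d loss / d pred of the soft Dice loss.
dice_loss_grad <- function(pred, target, eps = 1e-5) {
  denom <- sum(pred) + sum(target) + eps
  num <- 2 * sum(pred * target) + eps
  (num / denom^2) - (2 * target) / denom
}

#' Learning rate at an epoch
#'
#' Interpolates between the printed endpoints `lr(0) = 2e-4` and
#' `lr(epochs - 1) = 4e-7`. The default is log-linear
#' (`lr_initial * (lr_final / lr_initial)^(e / (epochs - 1))`), the natural
#' way to traverse three orders of magnitude smoothly; linear and cosine
#' schedules are available.
#'
#' @param e Epoch index, `0 <= e <= epochs - 1`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(e, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(e < 0) || any(e > cfg$epochs - 1)) {
    stop("epoch out of range [0, ", cfg$epochs - 1, "]")
  }
  if (cfg$epochs == 1L) return(rep(cfg$lr_initial, length(e)))
  t <- e / (cfg$epochs - 1)
  lr <- switch(cfg$lr_schedule,
    loglinear = cfg$lr_initial * (cfg$lr_final / cfg$lr_initial)^t,
    linear = cfg$lr_initial + t * (cfg$lr_final - cfg$lr_initial),
    cosine = cfg$lr_final + (cfg$lr_initial - cfg$lr_final) * (1 + cos(pi * t)) / 2)
  # the printed endpoints are exact by contract
  lr[e == 0] <- cfg$lr_initial
  lr[e == cfg$epochs - 1] <- cfg$lr_final
  lr
}

#' Sample a slab of consecutive slices
#'
#' Draws a random contiguous block of `slab_depth` axial slices from a
#' case. The start index is uniform over the valid positions; volumes
#' shorter than the slab are zero-padded symmetrically (mask padded with
#' background), the extra slice going below when the padding is odd.
#'
#' @param case List with `image` ([ct_volume()]) and `mask` ([ct_mask()])
#'   on the same grid (e.g. a preprocessed phantom case).
#' @param slab_depth Slices per slab.
#' @return List with `image` and `mask` 3D arrays of depth `slab_depth`,
#'   and `start` (1-based start slice in the source volume, `NA` when
#'   padded).
#' @export
sample_slab <- function(case, slab_depth = 32L) {
  img <- if (inherits(case$image, "ct_volume")) case$image$data else case$image
  msk <- if (inherits(case$mask, "ct_mask")) case$mask$data else case$mask
  stopifnot(identical(dim(img), dim(msk)), slab_depth >= 1)
  d <- dim(img)[3]
  if (d >= slab_depth) {
    start <- sample.int(d - slab_depth + 1L, 1L)
    zi <- start:(start + slab_depth - 1L)
    return(list(image = img[, , zi, drop = FALSE], mask = msk[, , zi, drop = FALSE],
                start = start))
  }
  pad <- slab_depth - d
  lo <- pad %/% 2L
  out_i <- array(0, c(dim(img)[1:2], slab_depth))
  out_m <- array(0, c(dim(img)[1:2], slab_depth))
  out_i[, , (lo + 1L):(lo + d)] <- img
  out_m[, , (lo + 1L):(lo + d)] <- msk
  list(image = out_i, mask = out_m, start = NA_integer_)
}

#' Case-level train/test split
#'
#' Shuffles cases with a seeded RNG and splits at
#' `round(n * train_fraction)` (clamped so both sides are non-empty).
#' Splitting at case level guarantees no slab of a test case is ever seen
#' in training.
#'
#' @param cases List of cases (length >= 2).
#' @param train_fraction Training share (default 0.8).
#' @param seed Split seed.
#' @return List with `train` and `test` sublists and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
split_cases <- function(cases, train_fraction = 0.8, seed = 1000L) {
  n <- length(cases)
  if (n < 2) stop("need at least 2 cases to split")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- max(1L, min(n - 1L, as.integer(round(n * train_fraction))))
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1L):n])
  list(train = cases[train_idx], test = cases[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0) {
    grads <- param_map2(grads, params, function(g, p) g + weight_decay * p)
  }
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- param_map(state$m, function(m) m / bc1)
  vhat <- param_map(state$v, function(v) v / bc2)
  upd <- param_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}

#' Train a segmentation model
#'
#' Dice-loss training with Adam: per epoch one randomly positioned slab per
#' training case, grouped into batches of `batch_size` (gradients
#' averaged), learning rate from [lr_at_epoch()], L2 weight decay inside
#' the Adam update. Deterministic for a fixed configuration and data in
#' single-threaded execution.
#'
#' @param model A `dst_net` whose configured (W, H) match the case grids
#'   and whose configured D equals `cfg$slab_depth`.
#' @param cases Non-empty list of preprocessed cases (`image` normalized
#'   [ct_volume()], `mask` [ct_mask()] on the same grid).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch loss every `verbose` epochs (0 = silent).
#' @return List with the trained `model` and `history` (data frame: epoch,
#'   lr, mean loss).
#' @export
train <- function(model, cases, cfg, verbose = 0L) {
  stopifnot(inherits(model, "dst_net"), inherits(cfg, "train_config"))
  if (length(cases) == 0) stop("empty training set")
  for (cs in cases) {
    img <- if (inherits(cs$image, "ct_volume")) cs$image else stop("cases must carry ct_volume images")
    if (img$domain != "normalized") stop("cases must be preprocessed (normalized) before training")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed + 1L)

  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))
  n <- length(cases)

  for (e in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(e, cfg)
    order <- sample.int(n)
    losses <- numeric(0)
    b0 <- 1L
    while (b0 <= n) {
      b1 <- min(b0 + cfg$batch_size - 1L, n)
      batch_grads <- NULL
      for (ci in order[b0:b1]) {
        slab <- sample_slab(cases[[ci]], cfg$slab_depth)
        model$params <- params
        fwd <- net_forward_cache(model, slab$image, training = TRUE)
        prob <- plogis_arr(fwd$logits)
        losses <- c(losses, dice_loss(prob, slab$mask))
        gp <- dice_loss_grad(prob, slab$mask)
        glogits <- gp * prob * (1 - prob)
        grads <- net_backward(model, fwd$cache, glogits)
        batch_grads <- if (is.null(batch_grads)) grads else
          param_map2(batch_grads, grads, `+`)
      }
      k <- b1 - b0 + 1L
      if (k > 1L) batch_grads <- param_map(batch_grads, function(g) g / k)
      upd <- adam_step(params, batch_grads, state, lr, cfg$weight_decay)
      params <- upd$params
      state <- upd$state
      b0 <- b1 + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = e, lr = lr, loss = mean(losses)))
    if (verbose > 0 && (e %% verbose == 0L || e == cfg$epochs - 1L)) {
      message(sprintf("epoch %4d  lr %.3e  mean dice loss %.4f", e, lr, mean(losses)))
    }
  }
  model$params <- params
  list(model = model, history = history)
}
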