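# Training stack: HU normalization and pairing, Adam wrapped in Lookahead,
# the seeded training loop with best-validation checkpointing, and
# slice-wise volume inference.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment/stability constants.
#' @param lookahead_k slow-weight sync period (steps).
#' @param lookahead_alpha slow-weight interpolation factor in (0, 1].
#' @param batch_size slices per optimizer step.
#' @param n_steps optimizer steps.
#' @param val_every validation period in steps (default: 10 validations
#'   over the run).
#' @param hu_range (lo, hi) HU window mapped to [-1, 1].
#' @param seed master seed (initialization and data order).
#' @param log_path optional CSV path for per-step loss logging.
#' @return an object of class \code{sct_train_config}.
#' @export
train_config <- function(learning_rate = 0.001, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         lookahead_k = 5L, lookahead_alpha = 0.5,
                         batch_size = 4L, n_steps = 2000L, val_every = NULL,
                         hu_range = c(-1000, 1000), seed = 1L,
                         log_path = NULL) {
  stopifnot(lookahead_alpha > 0, lookahead_alpha <= 1, lookahead_k >= 1L,
            hu_range[1] < hu_range[2], batch_size >= 1L, n_steps >= 1L,
            learning_rate > 0)
  if (is.null(val_every)) val_every <- max(1L, as.integer(n_steps %/% 10L))
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 lookahead_k = as.integer(lookahead_k),
                 lookahead_alpha = lookahead_alpha,
                 batch_size = as.integer(batch_size),
                 n_steps = as.integer(n_steps),
                 val_every = as.integer(val_every),
                 hu_range = as.numeric(hu_range), seed = as.integer(seed),
                 log_path = log_path),
            class = "sct_train_config")
}

#' Normalize an HU image to [-1, 1]
#'
#' Background pixels (outside the body mask, when given) are set to 0 HU
#' before mapping, matching the zeroed-background pairing convention; values
#' are clipped to \code{hu_range} and mapped affinely so that
#' \code{hu_range[1]} -> -1 and \code{hu_range[2]} -> +1.
#'
#' @param x numeric matrix in HU (or an [image_slice()]).
#' @param hu_range (lo, hi) clip window.
#' @param body optional logical mask; overrides the slice's own mask.
#' @return numeric matrix on [-1, 1].
#' @export
normalize_hu <- function(x, hu_range = c(-1000, 1000), body = NULL) {
  if (inherits(x, "image_slice")) {
    if (is.null(body)) body <- x$body
    x <- x$values
  }
  if (hu_range[1] >= hu_range[2]) stop("degenerate hu_range", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite HU values", call. = FALSE)
  if (!is.null(body)) x[!body] <- 0
  x <- pmin(pmax(x, hu_range[1]), hu_range[2])
  2 * (x - hu_range[1]) / (hu_range[2] - hu_range[1]) - 1
}

#' Invert [normalize_hu()]
#'
#' Exact inverse of the affine map on the clipped range:
#' \code{denormalize_hu(normalize_hu(x))} equals \code{x} clipped to
#' \code{hu_range}.
#'
#' @param y numeric matrix on [-1, 1].
#' @param hu_range (lo, hi) window used for normalization.
#' @return numeric matrix in HU.
#' @export
denormalize_hu <- function(y, hu_range = c(-1000, 1000)) {
  if (hu_range[1] >= hu_range[2]) stop("degenerate hu_range", call. = FALSE)
  (y + 1) / 2 * (hu_range[2] - hu_range[1]) + hu_range[1]
}

#' Automatic body mask from a CBCT slice
#'
#' Threshold above -300 HU, keep the largest connected component, fill
#' holes. Used when no body mask accompanies a volume.
#'
#' @param hu numeric matrix in HU.
#' @return logical matrix.
#' @export
auto_body_mask <- function(hu) {
  m <- hu > -300
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  EBImage::fillHull(keep * 1) > 0
}

## ---- optimizers --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

#' One Lookahead synchronization step
#'
#' The inner (fast) optimizer updates \code{fast} every step; every k-th
#' step the slow weights move toward the fast weights,
#' slow <- slow + alpha * (fast - slow), and the fast weights are reset to
#' the slow weights. With alpha = 1 the slow weights track the inner
#' optimizer sampled at sync points; with alpha = 0 they never move.
#'
#' @param fast,slow named lists of parameter arrays (matched shapes).
#' @param step_index current optimizer step (1-based).
#' @param k sync period.
#' @param alpha interpolation factor in [0, 1].
#' @return list with updated \code{fast} and \code{slow}.
#' @export
lookahead_step <- function(fast, slow, step_index, k = 5L, alpha = 0.5) {
  if (step_index %% k == 0L) {
    for (nm in names(slow)) {
      slow[[nm]] <- slow[[nm]] + alpha * (fast[[nm]] - slow[[nm]])
      fast[[nm]] <- slow[[nm]]
    }
  }
  list(fast = fast, slow = slow)
}

## ---- training loop -----------------------------------------------------------

# shared preprocessing for training, validation and inference
preprocess_pair <- function(pair, hu_range) {
  body <- if (!is.null(pair$masks)) as_mask_matrix(pair$masks$body) else
    pair$ct$body
  list(x = normalize_hu(pair$cbct$values, hu_range, body),
       y = normalize_hu(pair$ct$values, hu_range, body),
       body = body)
}

# loss + parameter gradients for one normalized pair
step_gradients <- function(x, y, cfg, params, loss_cfg) {
  tape_start(8192L)
  on.exit(tape_stop(), add = TRUE)
  P <- lapply(params, tn_leaf)
  xin <- tn(array(x, dim = c(nrow(x), ncol(x), 1L)))
  pred <- forward_tape(xin, cfg, P)
  yn <- tn(array(y, dim = dim(pred$value)))
  ch <- charbonnier_tape(pred, yn, loss_cfg$epsilon, loss_cfg$charbonnier_form)
  ms <- ms_ssim_tape(pred, yn, loss_cfg)
  loss <- t_add(t_scale(ch, loss_cfg$mix[1]),
                t_scale(t_shift(t_scale(ms, -1), 1), loss_cfg$mix[2]))
  grads_by_id <- tape_backward(loss)
  grads <- lapply(P, function(p) grads_by_id[[p$id]])
  list(loss = loss$value, charbonnier = ch$value, ms_ssim = ms$value,
       grads = grads)
}

#' Train the CBCT-to-sCT network
#'
#' Minimizes the composite Charbonnier + (1 - MS-SSIM) objective over
#' CBCT -> CT pairs with Adam wrapped in Lookahead. Fully seeded: parameter
#' initialization, batch order and everything downstream reproduce exactly
#' from \code{train_cfg$seed}. Validation (when given) uses the identical
#' preprocessing and loss code path as training; the returned checkpoint
#' carries the slow weights with the best validation loss.
#'
#' @param pairs training pairs: a list of \code{list(ct, cbct, masks)} as
#'   produced by [generate_anatomy()]/[degrade_to_cbct()] or
#'   [load_dataset()], or a manifest data.frame/path (then \code{data_dir}
#'   locates the files and the manifest's split column is honoured).
#' @param net_cfg a [network_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param val_pairs optional validation pairs (same formats).
#' @param data_dir dataset directory when \code{pairs} is a manifest.
#' @return an \code{sct_checkpoint}: network config + parameters (slow
#'   weights), optimizer state, configs, step count and loss history.
#' @export
train <- function(pairs, net_cfg = network_config(),
                  loss_cfg = loss_config(), train_cfg = train_config(),
                  val_pairs = NULL, data_dir = NULL) {
  if (is.character(pairs) || is.data.frame(pairs)) {
    manifest <- pairs
    pairs <- load_dataset(manifest, data_dir, split = "train")
    if (is.null(val_pairs))
      val_pairs <- load_dataset(manifest, data_dir, split = "val")
    if (length(val_pairs) == 0L) val_pairs <- NULL
  }
  if (length(pairs) == 0L) stop("empty training split", call. = FALSE)
  prep <- lapply(pairs, preprocess_pair, hu_range = train_cfg$hu_range)
  vprep <- if (!is.null(val_pairs))
    lapply(val_pairs, preprocess_pair, hu_range = train_cfg$hu_range)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  slow <- init_network_params(net_cfg, seed = train_cfg$seed)
  fast <- slow
  state <- adam_init(fast)
  set.seed(train_cfg$seed + 1L)

  n <- length(prep)
  history <- data.frame(step = integer(0), charbonnier = numeric(0),
                        ms_ssim = numeric(0), composite = numeric(0))
  val_history <- data.frame(step = integer(0), composite = numeric(0))
  best_val <- Inf
  best_params <- slow

  val_loss <- function(params) {
    mean(vapply(vprep, function(pp) {
      pred <- forward_net(pp$x, net_cfg, params)
      composite_loss(pred, pp$y, loss_cfg)
    }, numeric(1)))
  }

  for (step in seq_len(train_cfg$n_steps)) {
    idx <- if (n <= train_cfg$batch_size) seq_len(n) else
      sample.int(n, train_cfg$batch_size)
    gacc <- NULL
    lsum <- chsum <- mssum <- 0
    for (i in idx) {
      r <- step_gradients(prep[[i]]$x, prep[[i]]$y, net_cfg, fast, loss_cfg)
      if (!is.finite(r$loss))
        stop(sprintf("non-finite loss at step %d (sample %d)", step, i),
             call. = FALSE)
      lsum <- lsum + r$loss
      chsum <- chsum + r$charbonnier
      mssum <- mssum + r$ms_ssim
      gacc <- if (is.null(gacc)) r$grads else
        mapply(function(a, b) a + b, gacc, r$grads, SIMPLIFY = FALSE)
    }
    nb <- length(idx)
    gacc <- lapply(gacc, function(g) g / nb)
    upd <- adam_update(fast, gacc, state, train_cfg)
    fast <- upd$params
    state <- upd$state
    la <- lookahead_step(fast, slow, step, train_cfg$lookahead_k,
                         train_cfg$lookahead_alpha)
    fast <- la$fast
    slow <- la$slow
    history[nrow(history) + 1L, ] <- list(step, chsum / nb, mssum / nb,
                                          lsum / nb)
    if (!is.null(vprep) && step %% train_cfg$val_every == 0L) {
      vl <- val_loss(slow)
      val_history[nrow(val_history) + 1L, ] <- list(step, vl)
      if (vl < best_val) {
        best_val <- vl
        best_params <- slow
      }
    }
  }
  if (is.null(vprep)) {
    best_params <- slow
    best_val <- NA_real_
  }
  if (!is.null(train_cfg$log_path))
    utils::write.csv(history, train_cfg$log_path, row.names = FALSE)
  structure(list(version = 1L, net_cfg = net_cfg, params = best_params,
                 opt_state = state, train_cfg = train_cfg,
                 loss_cfg = loss_cfg, step = train_cfg$n_steps,
                 history = history, val_history = val_history,
                 best_val = best_val),
            class = "sct_checkpoint")
}

#' Save / load a checkpoint
#'
#' Single-file, versioned container of network config, parameters,
#' optimizer state and training history. A save/load round trip reproduces
#' [synthesize()] outputs bitwise.
#'
#' @param ck an \code{sct_checkpoint}.
#' @param path file path.
#' @return \code{load_checkpoint} returns the checkpoint.
#' @export
save_checkpoint <- function(ck, path) {
  stopifnot(inherits(ck, "sct_checkpoint"))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "sct_checkpoint") || is.null(ck$version))
    stop("not a valid checkpoint file: ", path, call. = FALSE)
  ck
}

#' Synthesize CT from a CBCT volume
#'
#' Slice-wise inference: each axial slice is normalized, pushed through the
#' network, denormalized back to HU, and re-zeroed outside the body mask
#' (supplied, or estimated from the CBCT by [auto_body_mask()]). The output
#' grid (shape and spacing) is identical to the input's. Deterministic:
#' repeated calls with the same checkpoint give identical volumes.
#'
#' @param volume 3D HU array, (H, W) matrix, or [image_slice()].
#' @param checkpoint an \code{sct_checkpoint} (or a path to one).
#' @param body optional logical mask, same shape as \code{volume}.
#' @param spacing voxel spacing; if missing, unit spacing is assumed with a
#'   warning.
#' @return synthetic-CT array of the input's shape, with a
#'   \code{spacing} attribute.
#' @export
synthesize <- function(volume, checkpoint, body = NULL, spacing = NULL) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  stopifnot(inherits(checkpoint, "sct_checkpoint"))
  if (inherits(volume, "image_slice")) {
    if (is.null(body)) body <- volume$body
    if (is.null(spacing)) spacing <- volume$spacing
    volume <- volume$values
  }
  was2d <- is.matrix(volume)
  if (was2d) volume <- array(volume, c(dim(volume), 1L))
  if (!is.null(body) && is.matrix(body)) body <- array(body, dim(volume))
  if (is.null(spacing)) {
    warning("no spacing metadata; assuming 1 mm isotropic", call. = FALSE)
    spacing <- rep(1, 3)
  }
  hu_range <- checkpoint$train_cfg$hu_range
  out <- array(0, dim(volume))
  for (s in seq_len(dim(volume)[3])) {
    sl <- volume[, , s]
    msk <- if (!is.null(body)) body[, , s] > 0 else auto_body_mask(sl)
    xn <- normalize_hu(sl, hu_range, msk)
    yn <- forward_net(xn, checkpoint$net_cfg, checkpoint$params)
    hu <- denormalize_hu(yn, hu_range)
    hu[!msk] <- 0
    out[, , s] <- hu
  }
  if (was2d) out <- out[, , 1L]
  attr(out, "spacing") <- as.numeric(spacing)
  out
}
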