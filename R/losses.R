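# Composite training objective: Charbonnier loss (a smooth L1 surrogate that
# calibrates CT numbers) mixed 9:1 with multi-scale structural similarity
# (which restores structural detail).

#' Loss configuration
#'
#' @param epsilon Charbonnier constant (on the normalized intensity scale).
#' @param C1,C2,C3 SSIM luminance/contrast/structure constants. The value 1
#'   is large for intensities normalized to [-1, 1], which makes the SSIM
#'   term forgiving; it is kept configurable.
#' @param n_scales number of dyadic scales in MS-SSIM.
#' @param scale_weights exponent per scale (alpha_M = beta_j = gamma_j); the
#'   default truncates the standard 5-scale vector (0.0448, 0.2856, 0.3001,
#'   0.2363, 0.1333) to n_scales and renormalizes to sum 1.
#' @param mix weights (w_charbonnier, w_msssim); must sum to 1. MS-SSIM
#'   enters the objective as w_msssim * (1 - MS-SSIM).
#' @param ssim_window side of the local-statistics window (pixels).
#' @param ssim_sigma Gaussian sigma of the local-statistics window.
#' @param charbonnier_form "mean": per-pixel mean of sqrt((y-x)^2 + eps^2)
#'   (the eps -> 0 limit is MAE); "norm": sqrt(sum((y-x)^2) + eps^2).
#' @return an object of class \code{sct_loss_config}.
#' @export
loss_config <- function(epsilon = 1e-3, C1 = 1, C2 = 1, C3 = 1,
                        n_scales = 3L, scale_weights = NULL,
                        mix = c(0.9, 0.1), ssim_window = 11L,
                        ssim_sigma = 1.5,
                        charbonnier_form = c("mean", "norm")) {
  charbonnier_form <- match.arg(charbonnier_form)
  stopifnot(epsilon > 0, n_scales >= 1L, ssim_window >= 3L,
            length(mix) == 2L, abs(sum(mix) - 1) < 1e-12)
  if (is.null(scale_weights)) {
    w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
    if (n_scales > 5L) stop("default scale weights cover up to 5 scales",
                            call. = FALSE)
    scale_weights <- w5[seq_len(n_scales)]
    scale_weights <- scale_weights / sum(scale_weights)
  }
  stopifnot(length(scale_weights) == n_scales,
            abs(sum(scale_weights) - 1) < 1e-8)
  structure(list(epsilon = epsilon, C1 = C1, C2 = C2, C3 = C3,
                 n_scales = as.integer(n_scales),
                 scale_weights = scale_weights, mix = mix,
                 ssim_window = as.integer(ssim_window),
                 ssim_sigma = ssim_sigma,
                 charbonnier_form = charbonnier_form),
            class = "sct_loss_config")
}

gauss_kernel1d <- function(win, sigma) {
  half <- (win - 1L) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

# symmetric reflect pad of a map node by p pixels on every side
t_pad_reflect_sym <- function(x, p) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (p >= H || p >= W)
    stop("window larger than the image", call. = FALSE)
  ri <- c(seq(p + 1L, 2L), seq_len(H), seq(H - 1L, H - p))
  rj <- c(seq(p + 1L, 2L), seq_len(W), seq(W - 1L, W - p))
  Hp <- H + 2L * p; Wp <- W + 2L * p
  base <- rep(ri, times = Wp) + (rep(rj, each = Hp) - 1L) * H
  idx <- as.vector(outer(base, (seq_len(C) - 1L) * H * W, "+"))
  t_gather(x, idx, c(Hp, Wp, C), mode = "accum")
}

# Gaussian blur of a map node (separable, reflect boundary)
t_gauss_blur <- function(x, win, sigma) {
  p <- (win - 1L) %/% 2L
  g <- gauss_kernel1d(win, sigma)
  xp <- t_pad_reflect_sym(x, p)
  h <- t_dwconv_fixed(xp, matrix(g, ncol = 1L), pad = 0L)   # rows
  t_dwconv_fixed(h, matrix(g, nrow = 1L), pad = 0L)         # cols
}

as_node_map <- function(x) {
  if (is_tn(x)) return(x)
  tn(as_map3(x))
}

check_same_shape <- function(a, b) {
  if (!identical(dim_of(a), dim_of(b)))
    stop("images must share shape", call. = FALSE)
}

#' Charbonnier loss
#'
#' Smooth surrogate for the L1 error, sqrt((y - x)^2 + epsilon^2), reduced
#' over pixels. With the default per-pixel mean the epsilon -> 0 limit is
#' the mean absolute error, and the loss is always >= epsilon with equality
#' exactly at pred = target.
#'
#' @param pred,target numeric arrays of identical shape.
#' @param epsilon smoothing constant.
#' @param form "mean" or "norm"; see [loss_config()].
#' @return scalar loss.
#' @export
charbonnier <- function(pred, target, epsilon = 1e-3,
                        form = c("mean", "norm")) {
  form <- match.arg(form)
  check_same_shape(pred, target)
  charbonnier_tape(tn(pred), tn(target), epsilon, form)$value
}

charbonnier_tape <- function(p, t, epsilon, form = "mean") {
  r2 <- t_square(t_sub(p, t))
  if (form == "mean") {
    t_mean(t_sqrt(t_shift(r2, epsilon^2)))
  } else {
    t_sqrt(t_shift(t_sum(r2), epsilon^2))
  }
}

#' Local SSIM comparison maps
#'
#' Luminance, contrast and structure maps from local Gaussian-window
#' statistics: L = (2 ux uy + C1) / (ux^2 + uy^2 + C1),
#' C = (2 sx sy + C2) / (sx^2 + sy^2 + C2),
#' S = (sxy + C3) / (sx sy + C3).
#'
#' @param x,y numeric matrices of identical shape on the normalized scale.
#' @param cfg a [loss_config()].
#' @return list of matrices L, C, S.
#' @export
ssim_components <- function(x, y, cfg = loss_config()) {
  check_same_shape(x, y)
  r <- ssim_maps_tape(as_node_map(x), as_node_map(y), cfg)
  lapply(r, function(n) n$value[, , 1L])
}

ssim_maps_tape <- function(x, y, cfg) {
  # one blur of the stacked statistics [x, y, x^2, y^2, xy]
  s5 <- t_concat_c(t_concat_c(x, y),
                   t_concat_c(t_square(x),
                              t_concat_c(t_square(y), t_mul(x, y))))
  b5 <- t_gauss_blur(s5, cfg$ssim_window, cfg$ssim_sigma)
  d <- dim(b5$value)
  ch <- function(i) {
    n <- d[1] * d[2]
    t_gather(b5, (i - 1L) * n + seq_len(n), c(d[1], d[2], 1L),
             mode = "unique")
  }
  ux <- ch(1L); uy <- ch(2L)
  ux2 <- t_square(ux); uy2 <- t_square(uy)
  uxy <- t_mul(ux, uy)
  varx <- t_clamp_min(t_sub(ch(3L), ux2), 0)
  vary <- t_clamp_min(t_sub(ch(4L), uy2), 0)
  cov <- t_sub(ch(5L), uxy)
  sxsy <- t_sqrt(t_shift(t_mul(varx, vary), 1e-24))
  L <- t_div(t_shift(t_scale(uxy, 2), cfg$C1),
             t_shift(t_add(ux2, uy2), cfg$C1))
  Cm <- t_div(t_shift(t_scale(sxsy, 2), cfg$C2),
              t_shift(t_add(varx, vary), cfg$C2))
  S <- t_div(t_shift(cov, cfg$C3), t_shift(sxsy, cfg$C3))
  list(L = L, C = Cm, S = S)
}

#' Multi-scale structural similarity
#'
#' Product over dyadic scales of mean contrast and structure terms, with the
#' luminance term entering only at the coarsest scale:
#' MS-SSIM = L_M^alpha_M * prod_j C_j^beta_j S_j^gamma_j. Scales are
#' connected by 2x average-pool downsampling. Value in (0, 1], equal to 1
#' for identical inputs.
#'
#' @param x,y numeric matrices of identical shape.
#' @param cfg a [loss_config()].
#' @return scalar in (0, 1].
#' @export
ms_ssim <- function(x, y, cfg = loss_config()) {
  check_same_shape(x, y)
  ms_ssim_tape(as_node_map(x), as_node_map(y), cfg)$value
}

ms_ssim_tape <- function(x, y, cfg) {
  M <- cfg$n_scales
  d <- dim(x$value)
  if (min(d[1], d[2]) / 2^(M - 1) < cfg$ssim_window)
    stop("too many MS-SSIM scales for this image size", call. = FALSE)
  w <- cfg$scale_weights
  total <- NULL
  for (j in seq_len(M)) {
    comp <- ssim_maps_tape(x, y, cfg)
    cs <- t_mul(t_pow_const(t_clamp_min(t_mean(comp$C), 1e-8), w[j]),
                t_pow_const(t_clamp_min(t_mean(comp$S), 1e-8), w[j]))
    total <- if (is.null(total)) cs else t_mul(total, cs)
    if (j == M) {
      Lm <- t_pow_const(t_clamp_min(t_mean(comp$L), 1e-8), w[M])
      total <- t_mul(total, Lm)
    } else {
      x <- t_avgpool2(x)
      y <- t_avgpool2(y)
    }
  }
  total
}

#' Composite training objective
#'
#' mix[1] * Charbonnier + mix[2] * (1 - MS-SSIM); with the defaults,
#' 0.9 * Charbonnier + 0.1 * (1 - MS-SSIM). Differentiable everywhere,
#' including at pred = target where it attains its floor
#' mix[1] * epsilon.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
composite_loss <- function(pred, target, cfg = loss_config()) {
  check_same_shape(pred, target)
  composite_tape(as_node_map(pred), as_node_map(target), cfg)$value
}

composite_tape <- function(p, t, cfg) {
  ch <- charbonnier_tape(p, t, cfg$epsilon, cfg$charbonnier_form)
  if (cfg$mix[2] == 0) return(t_scale(ch, cfg$mix[1]))
  ms <- ms_ssim_tape(p, t, cfg)
  t_add(t_scale(ch, cfg$mix[1]),
        t_scale(t_shift(t_scale(ms, -1), 1), cfg$mix[2]))
}

#' Gradient of the composite loss with respect to the prediction
#'
#' Exposes the training gradient for diagnostics; finite everywhere,
#' including at the loss minimum pred = target.
#'
#' @inheritParams composite_loss
#' @return numeric matrix shaped like \code{pred}.
#' @export
loss_gradient <- function(pred, target, cfg = loss_config()) {
  check_same_shape(pred, target)
  tape_start()
  on.exit(tape_stop(), add = TRUE)
  p <- tn_leaf(as_map3(pred))
  loss <- composite_tape(p, tn(as_map3(target)), cfg)
  g <- tape_backward(loss)[[p$id]]
  if (is.matrix(pred)) g[, , 1L] else g
}
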