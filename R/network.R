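# The CBCT-to-sCT network: a U-shaped hierarchical encoder-decoder whose
# stages are pairs of transformer blocks (window attention, then shifted-
# window attention) with locally enhanced feed-forward layers, convolutional
# input/output projections, strided-convolution downsampling, transposed-
# convolution upsampling and concatenation skip connections.

#' Network configuration
#'
#' @param base_channels channels after the input projection (C0).
#' @param window attention window side length M, in tokens.
#' @param heads number of attention heads per resolution level (length
#'   n_stages + 1; the last entry is the bottleneck). Channels at every
#'   level must be divisible by the head count there.
#' @param channel_mult channel multiplier per level relative to C0.
#' @param blocks_per_stage transformer blocks per level; even-numbered
#'   blocks use the shifted window partition (shift = floor(M/2)).
#' @param n_stages number of encoder (and decoder) levels.
#' @param leff_expansion hidden-width ratio of the locally enhanced
#'   feed-forward layer.
#' @param leaky_slope negative slope of the LeakyReLU after the input
#'   projection.
#' @param attn_scale "rsqrt_d" scales attention logits by 1/sqrt(d)
#'   (d = C/k per head); "inv_d" uses 1/d.
#' @param global_residual add the input image to the network output, so
#'   the network learns an artifact correction rather than a full
#'   re-synthesis (default TRUE; edges of the input are then preserved
#'   exactly at initialization). Set FALSE for pure synthesis.
#' @return an object of class \code{sct_net_config}.
#' @export
network_config <- function(base_channels = 32L, window = 8L,
                           heads = c(1L, 2L, 4L, 8L, 16L),
                           channel_mult = c(1L, 2L, 4L, 8L, 16L),
                           blocks_per_stage = 2L, n_stages = 4L,
                           leff_expansion = 4L, leaky_slope = 0.01,
                           attn_scale = c("rsqrt_d", "inv_d"),
                           global_residual = TRUE) {
  attn_scale <- match.arg(attn_scale)
  stopifnot(n_stages >= 1L, blocks_per_stage >= 1L, window >= 1L,
            length(heads) == n_stages + 1L,
            length(channel_mult) == n_stages + 1L,
            all(channel_mult > 0), base_channels >= 1L)
  ch <- base_channels * channel_mult
  if (any(ch %% heads != 0))
    stop("channels must be divisible by the head count at every level",
         call. = FALSE)
  structure(list(base_channels = as.integer(base_channels),
                 window = as.integer(window),
                 heads = as.integer(heads),
                 channel_mult = as.integer(channel_mult),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 n_stages = as.integer(n_stages),
                 leff_expansion = as.integer(leff_expansion),
                 leaky_slope = leaky_slope,
                 attn_scale = attn_scale,
                 global_residual = isTRUE(global_residual)),
            class = "sct_net_config")
}

net_channels <- function(cfg) cfg$base_channels * cfg$channel_mult

# shape inventory of one transformer block at C channels, k heads
block_shapes <- function(C, k, M, e) {
  eC <- e * C
  list(ln1.g = C, ln1.b = C,
       qkv.w = c(C, 3L * C), qkv.b = 3L * C,
       proj.w = c(C, C), proj.b = C,
       relpos = c((2L * M - 1L)^2, k),
       ln2.g = C, ln2.b = C,
       leff1.w = c(C, eC), leff1.b = eC,
       leffdw.w = c(3L, 3L, eC), leffdw.b = eC,
       leff2.w = c(eC, C), leff2.b = C)
}

# full parameter shape inventory, named flat list
param_shapes <- function(cfg) {
  ch <- net_channels(cfg)
  ns <- cfg$n_stages
  M <- cfg$window
  e <- cfg$leff_expansion
  out <- list(in_proj.w = c(3L, 3L, 1L, ch[1]), in_proj.b = ch[1])
  add_blocks <- function(out, prefix, C, k) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      bs <- block_shapes(C, k, M, e)
      names(bs) <- paste0(prefix, ".blk", b, ".", names(bs))
      out <- c(out, bs)
    }
    out
  }
  for (s in seq_len(ns)) {
    out <- add_blocks(out, paste0("enc", s), ch[s], cfg$heads[s])
    out <- c(out, stats::setNames(
      list(c(4L, 4L, ch[s], ch[s + 1]), ch[s + 1]),
      paste0("down", s, c(".w", ".b"))))
  }
  out <- add_blocks(out, "bott", ch[ns + 1], cfg$heads[ns + 1])
  for (s in rev(seq_len(ns))) {
    out <- c(out, stats::setNames(
      list(c(2L, 2L, ch[s + 1], ch[s]), ch[s]),
      paste0("up", s, c(".w", ".b"))))
    out <- c(out, stats::setNames(
      list(c(2L * ch[s], ch[s]), ch[s]),
      paste0("fuse", s, c(".w", ".b"))))
    out <- add_blocks(out, paste0("dec", s), ch[s], cfg$heads[s])
  }
  c(out, list(out_proj.w = c(3L, 3L, ch[1], 1L), out_proj.b = 1L))
}

#' Count learnable parameters of a network configuration
#'
#' Total number of learnable scalars the configuration instantiates;
#' matches \code{sum(lengths(init_network_params(cfg)))} exactly.
#'
#' @param cfg a [network_config()].
#' @return integer scalar.
#' @export
count_parameters <- function(cfg) {
  sum(vapply(param_shapes(cfg), prod, numeric(1)))
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

#' Initialize network parameters
#'
#' Linear and attention weights are truncated-normal (sd 0.02, the Swin
#' convention); convolution weights use He scaling; normalization gains are
#' 1; all biases 0. Deterministic given the seed.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed.
#' @return named list of numeric arrays.
#' @export
init_network_params <- function(cfg, seed = 1L) {
  shapes <- param_shapes(cfg)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    n <- prod(d)
    leaf <- sub(".*\\.", "", nm)
    v <- if (leaf %in% c("b", "ln1.b", "ln2.b") || grepl("\\.b$", nm)) {
      numeric(n)
    } else if (grepl("ln[12]\\.g$", nm)) {
      rep(1, n)
    } else if (grepl("(in_proj|out_proj|down[0-9]+|up[0-9]+)\\.w$", nm)) {
      fan_in <- prod(d[-length(d)])
      stats::rnorm(n, 0, sqrt(2 / fan_in))
    } else if (grepl("leffdw\\.w$", nm)) {
      stats::rnorm(n, 0, sqrt(2 / 9))
    } else {
      trunc_normal(n)
    }
    if (length(d) > 1L) dim(v) <- d
    out[[nm]] <- v
  }
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## ---- cached index maps -------------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- build()
    .idx_cache[[key]] <- v
  }
  v
}

row_gather_idx <- function(rows, N, C) {
  as.vector(outer(rows, (seq_len(C) - 1L) * N, "+"))
}

idx_img2tok <- function(H, W, C) {
  cached(sprintf("i2t_%d_%d_%d", H, W, C),
         function() img_token_idx(H, W, C))
}

idx_tok2img <- function(H, W, C) {
  cached(sprintf("t2i_%d_%d_%d", H, W, C), function() {
    fwd <- img_token_idx(H, W, C)
    inv <- integer(length(fwd))
    inv[fwd] <- seq_along(fwd)
    inv
  })
}

idx_windows <- function(H, W, M, s, C) {
  cached(sprintf("win_%d_%d_%d_%d_%d", H, W, M, s, C), function() {
    rows <- window_row_idx(H, W, M, s)
    inv <- integer(length(rows))
    inv[rows] <- seq_along(rows)
    list(fwd = row_gather_idx(rows, H * W, C),
         bwd = row_gather_idx(inv, H * W, C))
  })
}

cached_mask <- function(H, W, M, s) {
  cached(sprintf("mask_%d_%d_%d_%d", H, W, M, s),
         function() build_attention_mask(H, W, M, s))
}

cached_bias_idx <- function(M, k) {
  cached(sprintf("bidx_%d_%d", M, k), function() {
    ridx <- as.vector(relpos_index(M))
    R <- (2L * M - 1L)^2
    as.vector(outer(ridx, (seq_len(k) - 1L) * R, "+"))
  })
}

## ---- forward pass ------------------------------------------------------------

# token node (H*W, C) -> token node, one transformer block
tf_block <- function(t0, P, prefix, H, W, M, shift, k, scale_mode) {
  C <- ncol(t0$value)
  N <- H * W
  m <- M * M
  nw <- (H %/% M) * (W %/% M)
  dh <- C %/% k
  scale <- if (scale_mode == "rsqrt_d") 1 / sqrt(dh) else 1 / dh
  p <- function(nm) P[[paste0(prefix, ".", nm)]]

  a <- t_layernorm(t0, p("ln1.g"), p("ln1.b"))
  wi <- idx_windows(H, W, M, shift, C)
  aw <- t_gather(a, wi$fwd, c(N, C))
  qkv <- t_linear(aw, p("qkv.w"), p("qkv.b"))
  bias <- t_gather(p("relpos"), cached_bias_idx(M, k), c(m, m, k),
                   mode = "accum")
  mask <- if (shift > 0L) cached_mask(H, W, M, shift) else NULL
  o <- t_attention_core(qkv, bias, mask, nw, m, k, scale)
  o <- t_linear(o, p("proj.w"), p("proj.b"))
  o <- t_gather(o, wi$bwd, c(N, C))
  x1 <- t_add(t0, o)

  b <- t_layernorm(x1, p("ln2.g"), p("ln2.b"))
  h1 <- t_linear_gelu(b, p("leff1.w"), p("leff1.b"))
  eC <- ncol(h1$value)
  hmap <- t_gather(h1, idx_tok2img(H, W, eC), c(H, W, eC))
  hdw <- t_gelu(t_dwconv(hmap, p("leffdw.w"), p("leffdw.b"), pad = 1L))
  ht <- t_gather(hdw, idx_img2tok(H, W, eC), c(N, eC))
  h2 <- t_linear_gelu(ht, p("leff2.w"), p("leff2.b"))
  t_add(x1, h2)
}

stage_blocks <- function(x, P, prefix, cfg, level) {
  M <- cfg$window
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  t <- t_gather(x, idx_img2tok(H, W, C), c(H * W, C))
  for (b in seq_len(cfg$blocks_per_stage)) {
    shift <- if (b %% 2L == 0L) M %/% 2L else 0L
    t <- tf_block(t, P, paste0(prefix, ".blk", b), H, W, M, shift,
                  cfg$heads[level], cfg$attn_scale)
  }
  t_gather(t, idx_tok2img(H, W, C), c(H, W, C))
}

# reflect-pad a map node on the bottom/right to (Hp, Wp); iterates when the
# target exceeds one reflection span
t_pad_reflect <- function(x, Hp, Wp) {
  repeat {
    d <- dim(x$value)
    if (d[1] >= Hp && d[2] >= Wp) return(x)
    x <- t_pad_reflect_once(x, min(Hp, 2L * d[1] - 1L),
                            min(Wp, 2L * d[2] - 1L))
  }
}

t_pad_reflect_once <- function(x, Hp, Wp) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (Hp == H && Wp == W) return(x)
  ri <- c(seq_len(H), seq(H - 1L, by = -1L, length.out = Hp - H))
  rj <- c(seq_len(W), seq(W - 1L, by = -1L, length.out = Wp - W))
  grid_i <- rep(ri, times = Wp)
  grid_j <- rep(rj, each = Hp)
  base <- grid_i + (grid_j - 1L) * H
  idx <- as.vector(outer(base, (seq_len(C) - 1L) * H * W, "+"))
  t_gather(x, idx, c(Hp, Wp, C), mode = "accum")
}

t_crop <- function(x, H0, W0) {
  d <- dim(x$value)
  if (d[1] == H0 && d[2] == W0) return(x)
  base <- rep(seq_len(H0), times = W0) +
    (rep(seq_len(W0), each = H0) - 1L) * d[1]
  idx <- as.vector(outer(base, (seq_len(d[3]) - 1L) * d[1] * d[2], "+"))
  t_gather(x, idx, c(H0, W0, d[3]), mode = "unique")
}

# forward pass on the tape; x: node (H, W, 1); P: named list of nodes
forward_tape <- function(x, cfg, P) {
  d0 <- dim(x$value)
  unit <- cfg$window * 2L^cfg$n_stages
  Hp <- as.integer(ceiling(d0[1] / unit) * unit)
  Wp <- as.integer(ceiling(d0[2] / unit) * unit)
  xin <- t_pad_reflect(x, Hp, Wp)
  h <- t_leaky_relu(t_conv2d(xin, P$in_proj.w, P$in_proj.b, 1L, 1L),
                    cfg$leaky_slope)
  skips <- vector("list", cfg$n_stages)
  for (s in seq_len(cfg$n_stages)) {
    h <- stage_blocks(h, P, paste0("enc", s), cfg, s)
    skips[[s]] <- h
    h <- t_conv2d(h, P[[paste0("down", s, ".w")]],
                  P[[paste0("down", s, ".b")]], 2L, 1L)
  }
  h <- stage_blocks(h, P, "bott", cfg, cfg$n_stages + 1L)
  for (s in rev(seq_len(cfg$n_stages))) {
    h <- t_convt2(h, P[[paste0("up", s, ".w")]], P[[paste0("up", s, ".b")]])
    h <- t_concat_c(h, skips[[s]])
    dd <- dim(h$value)
    tt <- t_gather(h, idx_img2tok(dd[1], dd[2], dd[3]),
                   c(dd[1] * dd[2], dd[3]))
    tt <- t_linear(tt, P[[paste0("fuse", s, ".w")]],
                   P[[paste0("fuse", s, ".b")]])
    Cs <- ncol(tt$value)
    h <- t_gather(tt, idx_tok2img(dd[1], dd[2], Cs), c(dd[1], dd[2], Cs))
    h <- stage_blocks(h, P, paste0("dec", s), cfg, s)
  }
  y <- t_conv2d(h, P$out_proj.w, P$out_proj.b, 1L, 1L)
  if (cfg$global_residual) y <- t_add(y, xin)
  t_crop(y, d0[1], d0[2])
}

#' Run the network forward on a single normalized slice
#'
#' Reflect-pads the input so every resolution level tiles into whole
#' attention windows, runs the hierarchical encoder-decoder, and crops the
#' output back to the input extent. Deterministic given (image, params).
#'
#' @param image (H, W) numeric matrix on the normalized intensity scale.
#' @param cfg a [network_config()].
#' @param params parameters from [init_network_params()] or a checkpoint.
#' @return (H, W) numeric matrix.
#' @export
forward_net <- function(image, cfg, params) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("non-finite network input", call. = FALSE)
  if (any(!vapply(params, function(p) all(is.finite(p)), logical(1))))
    stop("non-finite network parameters", call. = FALSE)
  x <- tn(array(image, dim = c(nrow(image), ncol(image), 1L)))
  P <- lapply(params, tn)
  y <- forward_tape(x, cfg, P)
  y$value[, , 1L]
}

#' Locally enhanced feed-forward layer
#'
#' Token MLP with an interposed 3x3 depth-wise convolution on the
#' re-gridded tokens: linear expansion, GELU, reshape to a 2D map, 3x3
#' depth-wise convolution (same padding), GELU, flatten, linear shrink,
#' GELU. Output shape equals input shape.
#'
#' @param tokens (H*W) x C token matrix.
#' @param H,W spatial extent the tokens grid to.
#' @param params list with w1 (C x eC), b1, w_dw (3, 3, eC), b_dw,
#'   w2 (eC x C), b2.
#' @return (H*W) x C token matrix.
#' @export
leff <- function(tokens, H, W, params) {
  if (nrow(tokens) != H * W)
    stop("token count does not match H*W", call. = FALSE)
  h1 <- t_gelu(t_linear(tn(tokens), tn(params$w1), tn(params$b1)))
  eC <- ncol(h1$value)
  hmap <- tokens_to_img(h1$value, H, W)
  hdw <- t_gelu(t_dwconv(tn(hmap), tn(params$w_dw), tn(params$b_dw),
                         pad = 1L))
  ht <- img_to_tokens(hdw$value)
  t_gelu(t_linear(tn(ht), tn(params$w2), tn(params$b2)))$value
}
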