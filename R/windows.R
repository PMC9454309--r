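# Window partitioning, cyclic shifts, relative position bias and the
# window-based multi-head self-attention core.
#
# Feature maps are (H, W, C) arrays. Tokens are row-major over spatial
# positions: token n corresponds to pixel (i, j) with n = (i-1)*W + j.

as_map3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(nrow(x), ncol(x), 1L)) else x
}

# linear indices that map an (H, W, C) array to an (H*W, C) token matrix
img_token_idx <- function(H, W, C) {
  n <- seq_len(H * W)
  i <- ((n - 1L) %/% W) + 1L
  j <- ((n - 1L) %% W) + 1L
  base <- i + (j - 1L) * H                      # linear index in (H, W)
  as.vector(outer(base, (seq_len(C) - 1L) * H * W, "+"))
}

#' Flatten a feature map to a token matrix
#'
#' Tokens are ordered row-major over spatial positions, so token
#' \code{n = (i-1)*W + j} holds the channel vector of pixel \code{(i, j)}.
#'
#' @param x an (H, W, C) array or an (H, W) matrix.
#' @return an (H*W) x C matrix.
#' @export
img_to_tokens <- function(x) {
  x <- as_map3(x)
  d <- dim(x)
  matrix(x[img_token_idx(d[1], d[2], d[3])], nrow = d[1] * d[2], ncol = d[3])
}

#' Reshape a token matrix back to a feature map
#'
#' Exact inverse of [img_to_tokens()].
#'
#' @param t an (H*W) x C token matrix.
#' @param H,W spatial extent of the target map.
#' @return an (H, W, C) array.
#' @export
tokens_to_img <- function(t, H, W) {
  if (nrow(t) != H * W) stop("token count does not match H*W", call. = FALSE)
  C <- ncol(t)
  out <- array(0, dim = c(H, W, C))
  out[img_token_idx(H, W, C)] <- t
  out
}

#' Cyclically shift a feature map
#'
#' The element at position (i, j) moves to ((i - s) mod H, (j - s) mod W);
#' shifting by \code{-s} restores the input. \code{s = 0} is the identity.
#'
#' @param x (H, W, C) array or (H, W) matrix.
#' @param s integer shift (may be negative).
#' @return array of the same shape.
#' @export
cyclic_shift <- function(x, s) {
  m <- is.matrix(x)
  x <- as_map3(x)
  d <- dim(x)
  ri <- ((seq_len(d[1]) - 1L + s) %% d[1]) + 1L
  rj <- ((seq_len(d[2]) - 1L + s) %% d[2]) + 1L
  out <- x[ri, rj, , drop = FALSE]
  if (m) out[, , 1L] else out
}

# row order that maps the token matrix of the (optionally shifted) map to
# window-major token rows: row (w-1)*M^2 + p  <-  token index of window w,
# in-window position p, both row-major. s > 0 applies the cyclic shift.
window_row_idx <- function(H, W, M, s = 0L) {
  nwj <- W %/% M
  a <- rep(seq_len(H), each = W)      # shifted-map row of each ordered slot
  b <- rep(seq_len(W), times = H)
  wi <- (a - 1L) %/% M
  wj <- (b - 1L) %/% M
  w <- wi * nwj + wj                  # 0-based window id
  p <- ((a - 1L) %% M) * M + ((b - 1L) %% M)   # 0-based in-window position
  # source token in the UNSHIFTED map
  si <- ((a - 1L + s) %% H) + 1L
  sj <- ((b - 1L + s) %% W) + 1L
  src <- (si - 1L) * W + sj
  ord <- integer(H * W)
  ord[w * (M * M) + p + 1L] <- src
  ord
}

#' Split a feature map into non-overlapping windows
#'
#' Windows are ordered row-major over the window grid; within each window
#' tokens are row-major. Requires H and W divisible by M.
#'
#' @param x (H, W, C) array or (H, W) matrix.
#' @param M window side length in tokens.
#' @return an (M^2, C, n_windows) array of flattened window features.
#' @export
partition_windows <- function(x, M) {
  x <- as_map3(x)
  d <- dim(x)
  if (d[1] %% M != 0 || d[2] %% M != 0)
    stop("H and W must be divisible by the window size M", call. = FALSE)
  if (M > d[1] || M > d[2])
    stop("window size exceeds the feature map", call. = FALSE)
  t <- img_to_tokens(x)
  rows <- window_row_idx(d[1], d[2], M, 0L)
  stack <- t[rows, , drop = FALSE]          # (nw*m, C), window-major rows
  m <- M * M
  nw <- (d[1] / M) * (d[2] / M)
  aperm(array(t(stack), dim = c(d[3], m, nw)), c(2, 1, 3))
}

#' Merge a window stack back into a feature map
#'
#' Exact inverse of [partition_windows()].
#'
#' @param stack (M^2, C, n_windows) array.
#' @param H,W spatial extent of the target map.
#' @return an (H, W, C) array.
#' @export
merge_windows <- function(stack, H, W) {
  d <- dim(stack)
  m <- d[1]
  M <- as.integer(round(sqrt(m)))
  if (M * M != m || (H / M) * (W / M) != d[3])
    stop("window stack does not tile an H x W map", call. = FALSE)
  flat <- matrix(aperm(stack, c(2, 1, 3)), nrow = d[2])   # C x (m*nw)
  rows <- window_row_idx(H, W, M, 0L)
  t <- matrix(0, nrow = H * W, ncol = d[2])
  t[rows, ] <- t(flat)
  tokens_to_img(t, H, W)
}

#' Relative-position index map for an M x M window
#'
#' Maps every ordered token pair (p, q) to a row of the (2M-1)^2 learned
#' bias table according to their 2D offset; depends only on M.
#'
#' @param M window side length.
#' @return an M^2 x M^2 integer matrix with values in 1..(2M-1)^2.
#' @export
relpos_index <- function(M) {
  p <- seq_len(M * M) - 1L
  ri <- p %/% M
  ci <- p %% M
  di <- outer(ri, ri, "-") + (M - 1L)     # 0 .. 2M-2
  dj <- outer(ci, ci, "-") + (M - 1L)
  di * (2L * M - 1L) + dj + 1L
}

#' Additive attention mask for shifted windows
#'
#' After a cyclic shift by \code{s}, windows near the map edge contain
#' content that was not spatially adjacent before the shift. Token pairs
#' originating from different pre-shift regions receive a large negative
#' additive logit so softmax attention cannot mix wrapped-around content;
#' same-region pairs receive 0.
#'
#' @param H,W map extent; must be divisible by M.
#' @param M window side length.
#' @param s shift offset, 0 < s < M.
#' @param neg value used for forbidden pairs.
#' @return an (M^2, M^2, n_windows) array of additive logits.
#' @export
build_attention_mask <- function(H, W, M, s, neg = -1e9) {
  if (s <= 0) stop("mask is only defined for a positive shift", call. = FALSE)
  if (s >= M) stop("shift must be smaller than the window size", call. = FALSE)
  band <- function(n) {
    id <- integer(n)
    id[seq_len(n - M)] <- 0L
    if (n - M + 1L <= n - s) id[seq(n - M + 1L, n - s)] <- 1L
    id[seq(n - s + 1L, n)] <- 2L
    id
  }
  rid <- band(H)
  cid <- band(W)
  region <- outer(rid, cid, function(a, b) 3L * a + b)    # shifted-map coords
  win <- partition_windows(region, M)[, 1L, , drop = FALSE]
  nw <- dim(win)[3]
  m <- M * M
  mask <- array(0, dim = c(m, m, nw))
  for (w in seq_len(nw)) {
    ids <- win[, 1L, w]
    mask[, , w] <- ifelse(outer(ids, ids, "!="), neg, 0)
  }
  mask
}

## ---- fused multi-head window attention (tape op) ----------------------------

# qkv: node, (nw*m, 3C) window-major rows; bias: node, (m, m, k);
# mask: (m, m, nw) array or NULL. Returns node (nw*m, C).
# Forward/adjoint are fused C++ (cpp_attn_fwd caches the softmax weights).
t_attention_core <- function(qkv, bias, mask, nw, m, k, scale) {
  has_mask <- !is.null(mask)
  mk <- if (has_mask) mask else array(0, dim = c(1L, 1L, 1L))
  r <- cpp_attn_fwd(qkv$value, bias$value, mk, has_mask, nw, m, k, scale)
  tape_record(r$out, c(qkv$id, bias$id), function(g, cache) {
    b <- cpp_attn_bwd(cache$qkv, cache$A, g, cache$nw, cache$m, cache$k,
                      cache$scale)
    list(b$dqkv, b$dbias)
  }, cache = list(qkv = qkv$value, A = r$A, nw = nw, m = m, k = k,
                  scale = scale))
}

#' Window-based multi-head self-attention on a window stack
#'
#' Computes, per window and head, softmax(Q K' * scale + B + mask) V with
#' learned linear Q/K/V maps and output mixing, the learned relative
#' position bias B shared across windows.
#'
#' @param windows (M^2, C, n_windows) array from [partition_windows()].
#' @param params list with w_qkv (C x 3C), b_qkv (3C), w_out (C x C),
#'   b_out (C).
#' @param bias_table (2M-1)^2 x k matrix of learned bias values.
#' @param k number of heads; C must be divisible by k.
#' @param mask optional (M^2, M^2, n_windows) additive mask.
#' @param scale attention scale; default 1/sqrt(d) with d = C/k.
#' @return an (M^2, C, n_windows) array.
#' @export
window_attention <- function(windows, params, bias_table, k, mask = NULL,
                             scale = NULL) {
  d3 <- dim(windows)
  m <- d3[1]; C <- d3[2]; nw <- d3[3]
  if (C %% k != 0) stop("C must be divisible by the head count", call. = FALSE)
  if (any(!is.finite(windows))) stop("non-finite attention input", call. = FALSE)
  M <- as.integer(round(sqrt(m)))
  dh <- C %/% k
  if (is.null(scale)) scale <- 1 / sqrt(dh)
  x <- tn(matrix(aperm(windows, c(1, 3, 2)), nrow = m * nw, ncol = C))
  qkv <- t_linear(x, tn(params$w_qkv), tn(params$b_qkv))
  ridx <- relpos_index(M)
  bias <- array(0, dim = c(m, m, k))
  for (h in seq_len(k)) bias[, , h] <- bias_table[ridx, h]
  o <- t_attention_core(qkv, tn(bias), mask, nw, m, k, scale)
  o <- t_linear(o, tn(params$w_out), tn(params$b_out))
  aperm(array(o$value, dim = c(m, nw, C)), c(1, 3, 2))
}

#' Shifted-window multi-head self-attention on a feature map
#'
#' The full attention path of one transformer block (without normalization
#' or the residual): cyclic shift by \code{shift}, window partition, masked
#' window attention with relative position bias, window merge, inverse
#' shift. With \code{shift = 0} this is plain window attention.
#'
#' @param x (H, W, C) array or (H, W) matrix; H, W divisible by M.
#' @param params list with w_qkv, b_qkv, w_out, b_out (see
#'   [window_attention()]).
#' @param bias_table (2M-1)^2 x k learned bias table.
#' @param k number of heads.
#' @param M window side length.
#' @param shift shift offset in tokens, 0 <= shift < M.
#' @param scale attention scale; default 1/sqrt(C/k).
#' @return an (H, W, C) array.
#' @export
shifted_window_attention <- function(x, params, bias_table, k, M, shift = 0L,
                                     scale = NULL) {
  x <- as_map3(x)
  d <- dim(x)
  xs <- if (shift > 0L) cyclic_shift(x, shift) else x
  win <- partition_windows(xs, M)
  mask <- if (shift > 0L) build_attention_mask(d[1], d[2], M, shift) else NULL
  out <- window_attention(win, params, bias_table, k, mask, scale)
  y <- merge_windows(out, d[1], d[2])
  if (shift > 0L) cyclic_shift(y, -shift) else y
}
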