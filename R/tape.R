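# Minimal reverse-mode autodiff tape.
#
# Forward passes build a linear tape of nodes; backward() walks it in reverse
# creation order. A "tensor" is a plain list(value, id): id 0 marks a constant
# (no gradient path), id > 0 indexes the tape. When the tape is off every op
# just computes values, so inference costs no bookkeeping.

.tape <- new.env(parent = emptyenv())
.tape$on <- FALSE
.tape$last <- NULL   # nodes form a linked list (newest first)
.tape$n <- 0L

tape_start <- function(capacity = NULL) {
  .tape$on <- TRUE
  .tape$last <- NULL
  .tape$n <- 0L
  invisible(NULL)
}

tape_stop <- function() {
  .tape$on <- FALSE
  .tape$last <- NULL
  .tape$n <- 0L
  invisible(NULL)
}

tape_is_on <- function() .tape$on

#' @noRd
tn <- function(value) list(value = value, id = 0L)

is_tn <- function(x) is.list(x) && !is.null(x$id)

# Record a node. parents: integer ids (0 allowed, skipped in backward).
# backward: function(g, cache) -> list of grads, one per parent (NULL ok).
tape_record <- function(value, parents, backward, cache = NULL) {
  if (!.tape$on || (length(parents) > 0L && all(parents == 0L)))
    return(tn(value))
  n <- .tape$n + 1L
  .tape$last <- list(id = n, prev = .tape$last, parents = parents,
                     backward = backward, cache = cache)
  .tape$n <- n
  list(value = value, id = n)
}

# Leaf node for a learnable parameter.
tn_leaf <- function(value) {
  if (!.tape$on) return(tn(value))
  tape_record(value, parents = integer(0), backward = NULL)
}

# Backpropagate from a scalar node; returns list of gradients indexed by
# node id (NULL where no gradient reached).
tape_backward <- function(node) {
  stopifnot(node$id > 0L, length(node$value) == 1L)
  grads <- vector("list", .tape$n)
  grads[[node$id]] <- array(1, dim = dim_of(node$value))
  rec <- .tape$last
  while (!is.null(rec)) {
    i <- rec$id
    g <- grads[[i]]
    if (!is.null(g) && !is.null(rec$backward)) {
      pg <- rec$backward(g, rec$cache)
      ps <- rec$parents
      for (j in seq_along(ps)) {
        pid <- ps[j]
        if (pid == 0L || is.null(pg[[j]])) next
        grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else
          grads[[pid]] + pg[[j]]
      }
      grads[[i]] <- NULL   # free as we go
    }
    rec <- rec$prev
  }
  grads
}

dim_of <- function(v) if (is.null(dim(v))) length(v) else dim(v)

with_dim <- function(v, d) { dim(v) <- d; v }

# reduce a gradient to the shape of an operand (scalar broadcast support)
reduce_to <- function(g, value) {
  if (length(value) == 1L && length(g) > 1L) return(sum(g))
  g
}

## ---- elementwise arithmetic -------------------------------------------------

t_add <- function(a, b) {
  v <- a$value + b$value
  tape_record(v, c(a$id, b$id), function(g, cache) {
    list(reduce_to(g, cache$a), reduce_to(g, cache$b))
  }, cache = list(a = a$value, b = b$value))
}

t_sub <- function(a, b) {
  v <- a$value - b$value
  tape_record(v, c(a$id, b$id), function(g, cache) {
    list(reduce_to(g, cache$a), reduce_to(-g, cache$b))
  }, cache = list(a = a$value, b = b$value))
}

t_mul <- function(a, b) {
  v <- a$value * b$value
  tape_record(v, c(a$id, b$id), function(g, cache) {
    list(reduce_to(g * cache$b, cache$a), reduce_to(g * cache$a, cache$b))
  }, cache = list(a = a$value, b = b$value))
}

t_div <- function(a, b) {
  v <- a$value / b$value
  tape_record(v, c(a$id, b$id), function(g, cache) {
    list(reduce_to(g / cache$b, cache$a),
         reduce_to(-g * cache$a / cache$b^2, cache$b))
  }, cache = list(a = a$value, b = b$value))
}

t_scale <- function(a, k) {
  tape_record(a$value * k, a$id, function(g, cache) list(g * cache$k),
              cache = list(k = k))
}

t_shift <- function(a, k) {
  tape_record(a$value + k, a$id, function(g, cache) list(g), cache = NULL)
}

t_square <- function(a) {
  tape_record(a$value^2, a$id, function(g, cache) list(2 * cache$a * g),
              cache = list(a = a$value))
}

t_sqrt <- function(a) {
  v <- sqrt(a$value)
  tape_record(v, a$id, function(g, cache) list(g / (2 * cache$v)),
              cache = list(v = v))
}

# x^p for constant p (x > 0 where p is fractional)
t_pow_const <- function(a, p) {
  v <- a$value^p
  tape_record(v, a$id, function(g, cache) {
    list(g * cache$p * cache$a^(cache$p - 1))
  }, cache = list(a = a$value, p = p))
}

t_clamp_min <- function(a, lo) {
  v <- pmax(a$value, lo)
  if (!is.null(dim(a$value))) dim(v) <- dim(a$value)
  tape_record(v, a$id, function(g, cache) list(g * cache$pass),
              cache = list(pass = (a$value > lo) * 1))
}

t_mean <- function(a) {
  n <- length(a$value)
  tape_record(mean(a$value), a$id, function(g, cache) {
    list(array(as.numeric(g) / cache$n, dim = cache$d))
  }, cache = list(n = n, d = dim_of(a$value)))
}

t_sum <- function(a) {
  tape_record(sum(a$value), a$id, function(g, cache) {
    list(array(as.numeric(g), dim = cache$d))
  }, cache = list(d = dim_of(a$value)))
}

## ---- activations ------------------------------------------------------------

# exact GELU: x * Phi(x); Phi is cached for the adjoint
t_gelu <- function(a) {
  x <- a$value
  r <- cpp_gelu_fwd2(x)
  v <- r$y
  dim(v) <- dim_of(x)
  tape_record(v, a$id, function(g, cache) {
    gx <- cpp_gelu_bwd2(cache$x, cache$phi, g)
    dim(gx) <- dim_of(g)
    list(gx)
  }, cache = list(x = x, phi = r$phi))
}

t_leaky_relu <- function(a, slope = 0.01) {
  x <- a$value
  v <- ifelse(x >= 0, x, slope * x)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  tape_record(v, a$id, function(g, cache) {
    list(g * ifelse(cache$x >= 0, 1, cache$slope))
  }, cache = list(x = x, slope = slope))
}

## ---- shape / indexing -------------------------------------------------------

t_reshape <- function(a, d) {
  v <- a$value
  dim(v) <- d
  tape_record(v, a$id, function(g, cache) {
    dim(g) <- cache$d0
    list(g)
  }, cache = list(d0 = dim_of(a$value)))
}

# gather by linear index. mode: "bijective" (permutation), "unique"
# (injective subset, e.g. crop), "accum" (duplicates allowed, e.g. reflect pad)
t_gather <- function(a, idx, out_dim, mode = "bijective", inv = NULL) {
  idx <- as.integer(idx)
  v <- a$value[idx]
  dim(v) <- out_dim
  n_in <- length(a$value)
  d_in <- dim_of(a$value)
  bw <- switch(mode,
    bijective = function(g, cache) {
      gv <- as.vector(g)[cache$inv]
      dim(gv) <- cache$d_in
      list(gv)
    },
    unique = function(g, cache) {
      z <- numeric(cache$n_in)
      z[cache$idx] <- as.vector(g)
      dim(z) <- cache$d_in
      list(z)
    },
    accum = function(g, cache) {
      z <- cpp_scatter_add(cache$idx, as.vector(g), cache$n_in)
      dim(z) <- cache$d_in
      list(z)
    })
  if (mode == "bijective" && is.null(inv)) {
    inv <- integer(n_in)
    inv[idx] <- seq_along(idx)
  }
  tape_record(v, a$id, bw,
              cache = list(idx = idx, inv = inv, n_in = n_in, d_in = d_in))
}

# concatenate two (H, W, C) maps along channels
t_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  tape_record(v, c(a$id, b$id), function(g, cache) {
    na <- prod(cache$da)
    ga <- with_dim(as.vector(g)[seq_len(na)], cache$da)
    gb <- with_dim(as.vector(g)[-seq_len(na)], cache$db)
    list(ga, gb)
  }, cache = list(da = da, db = db))
}

## ---- dense / norm layers ----------------------------------------------------

# fused y = GELU(x %*% w + b): one tape node, shared caches
t_linear_gelu <- function(x, w, b) {
  pre <- x$value %*% w$value
  pre <- pre + rep(b$value, each = nrow(pre))
  r <- cpp_gelu_fwd2(pre)
  v <- r$y
  dim(v) <- dim(pre)
  tape_record(v, c(x$id, w$id, b$id), function(g, cache) {
    dpre <- cpp_gelu_bwd2(cache$pre, cache$phi, g)
    dim(dpre) <- dim_of(g)
    list(dpre %*% t(cache$w), crossprod(cache$x, dpre), colSums(dpre))
  }, cache = list(x = x$value, w = w$value, pre = pre, phi = r$phi))
}

# x: (N, C) matrix node; w: (C, D); b: (D)
t_linear <- function(x, w, b) {
  v <- x$value %*% w$value
  v <- v + rep(b$value, each = nrow(v))
  tape_record(v, c(x$id, w$id, b$id), function(g, cache) {
    list(g %*% t(cache$w), crossprod(cache$x, g), colSums(g))
  }, cache = list(x = x$value, w = w$value))
}

# layer normalization over channels for each token row; x (N, C)
t_layernorm <- function(x, gam, bet, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  v2 <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v2 + eps)
  xhat <- xc * istd
  n <- nrow(xv)
  v <- xhat * rep(gam$value, each = n) + rep(bet$value, each = n)
  tape_record(v, c(x$id, gam$id, bet$id), function(g, cache) {
    xhat <- cache$xhat
    dxhat <- g * rep(cache$gam, each = nrow(g))
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- cache$istd * (dxhat - m1 - xhat * m2)
    list(dx, colSums(g * xhat), colSums(g))
  }, cache = list(xhat = xhat, istd = istd, gam = gam$value))
}

## ---- convolutions (Rcpp kernels) -------------------------------------------

# x: (H, W, Cin); w: (kh, kw, Cin, Cout); b: (Cout)
t_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  dw <- dim(w$value)
  v <- cpp_conv2d_fwd(x$value, w$value, as.vector(b$value),
                      dw[1], dw[2], dw[4], stride, pad)
  tape_record(v, c(x$id, w$id, b$id), function(g, cache) {
    r <- cpp_conv2d_bwd(cache$x, cache$w, g, cache$kh, cache$kw,
                        cache$stride, cache$pad)
    list(r$dx, with_dim(r$dw, cache$dw), r$db)
  }, cache = list(x = x$value, w = w$value, kh = dw[1], kw = dw[2],
                  stride = stride, pad = pad, dw = dw))
}

# 2x2 stride-2 transposed convolution; w: (2, 2, Cin, Cout)
t_convt2 <- function(x, w, b) {
  dw <- dim(w$value)
  v <- cpp_convt2_fwd(x$value, as.vector(w$value), as.vector(b$value), dw[4])
  tape_record(v, c(x$id, w$id, b$id), function(g, cache) {
    r <- cpp_convt2_bwd(cache$x, cache$w, g)
    list(r$dx, with_dim(r$dw, cache$dw), r$db)
  }, cache = list(x = x$value, w = as.vector(w$value), dw = dw))
}

# depth-wise convolution with learned per-channel kernels; w: (kh, kw, C)
t_dwconv <- function(x, w, b, pad = 1L) {
  dw <- dim(w$value)
  v <- cpp_dwconv_fwd(x$value, w$value, as.vector(b$value),
                      dw[1], dw[2], pad, pad)
  tape_record(v, c(x$id, w$id, b$id), function(g, cache) {
    r <- cpp_dwconv_bwd(cache$x, cache$w, g, cache$kh, cache$kw,
                        cache$pad, cache$pad)
    list(r$dx, with_dim(r$dw, cache$dw), r$db)
  }, cache = list(x = x$value, w = w$value, kh = dw[1], kw = dw[2],
                  pad = pad, dw = dw))
}

# depth-wise convolution with a FIXED kernel shared by all channels
# (no weight gradient) -- used for Gaussian filtering in the SSIM stack
t_dwconv_fixed <- function(x, kern, pad = 0L) {
  C <- dim(x$value)[3]
  kh <- nrow(kern); kw <- ncol(kern)
  wv <- rep(as.vector(kern), times = C)
  bv <- numeric(C)
  v <- cpp_dwconv_fwd(x$value, wv, bv, kh, kw, pad, pad)
  tape_record(v, x$id, function(g, cache) {
    r <- cpp_dwconv_bwd(cache$x, cache$w, g, cache$kh, cache$kw,
                        cache$pad, cache$pad)
    list(r$dx)
  }, cache = list(x = x$value, w = wv, kh = kh, kw = kw, pad = pad))
}

# 2x2 average pooling on (H, W, C)
t_avgpool2 <- function(x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  oi <- seq(1L, H - 1L, by = 2L); oj <- seq(1L, W - 1L, by = 2L)
  v <- (x$value[oi, oj, , drop = FALSE] + x$value[oi + 1L, oj, , drop = FALSE] +
        x$value[oi, oj + 1L, , drop = FALSE] +
        x$value[oi + 1L, oj + 1L, , drop = FALSE]) / 4
  tape_record(v, x$id, function(g, cache) {
    d <- cache$d
    dx <- array(0, dim = d)
    oi <- cache$oi; oj <- cache$oj
    g4 <- g / 4
    dx[oi, oj, ] <- g4
    dx[oi + 1L, oj, ] <- g4
    dx[oi, oj + 1L, ] <- g4
    dx[oi + 1L, oj + 1L, ] <- g4
    list(dx)
  }, cache = list(d = d, oi = oi, oj = oj))
}
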