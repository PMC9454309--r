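# Token/window plumbing and the attention core.

test_that("token flattening is row-major and exactly invertible", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)   # [[a,b],[c,d]]
  expect_equal(img_to_tokens(m)[, 1], c(1, 2, 3, 4))
  set.seed(5)
  x <- array(rnorm(8 * 4 * 4), c(8, 4, 4))         # C preserved: see dims
  t <- img_to_tokens(x)
  expect_equal(dim(t), c(32L, 4L))
  expect_identical(tokens_to_img(t, 8, 4), x)
  x2 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))        # 8-channel 4x4 -> 16x8
  expect_equal(dim(img_to_tokens(x2)), c(16L, 8L))
  expect_error(tokens_to_img(t, 5, 4), "token count")
})

test_that("window partition follows the row-major window grid and inverts", {
  m <- matrix(seq_len(16), 4, 4, byrow = TRUE)
  pw <- partition_windows(m, 2)
  # first window holds entries (1,1),(1,2),(2,1),(2,2)
  expect_equal(pw[, 1, 1], c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
  expect_equal(dim(pw)[3], 4L)
  set.seed(6)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_identical(merge_windows(partition_windows(x, 4), 8, 8), x)
  # M = H = W: single window equals the token matrix
  one <- partition_windows(x, 8)
  expect_equal(dim(one)[3], 1L)
  expect_equal(one[, , 1], img_to_tokens(x))
  expect_error(partition_windows(x, 3), "divisible")
})

test_that("cyclic shift moves (i,j) to ((i-s) mod H, (j-s) mod W)", {
  m <- matrix(seq_len(16), 4, 4)
  expect_identical(cyclic_shift(m, 0), m)
  s <- cyclic_shift(m, 2)
  expect_equal(s[1, 1], m[3, 3])
  set.seed(7)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  expect_identical(cyclic_shift(cyclic_shift(x, 2), -2), x)
})

test_that("relative position index depends only on the 2D token offset", {
  for (M in c(2L, 4L)) {
    idx <- relpos_index(M)
    expect_true(all(idx >= 1 & idx <= (2 * M - 1)^2))
    pos <- expand.grid(ci = 0:(M - 1), ri = 0:(M - 1))[, c("ri", "ci")]
    for (p in seq_len(M * M)) for (q in seq_len(M * M)) {
      off <- c(pos$ri[p] - pos$ri[q], pos$ci[p] - pos$ci[q])
      same <- which(outer(pos$ri, pos$ri, "-") == off[1] &
                      outer(pos$ci, pos$ci, "-") == off[2])
      expect_true(all(idx[same] == idx[p + (q - 1) * M * M]))
    }
  }
})

test_that("shifted-window mask matches a source-coordinate oracle", {
  for (sz in list(c(4L, 4L, 2L, 1L), c(8L, 8L, 4L, 2L), c(8L, 12L, 4L, 1L))) {
    H <- sz[1]; W <- sz[2]; M <- sz[3]; s <- sz[4]
    mask <- build_attention_mask(H, W, M, s)
    # oracle: label each shifted-map slot by its source pixel; a pair is
    # forbidden iff source offsets disagree with positional offsets
    si <- ((seq_len(H) - 1 + s) %% H) + 1
    sj <- ((seq_len(W) - 1 + s) %% W) + 1
    nwj <- W %/% M
    for (w in seq_len(dim(mask)[3])) {
      wi <- (w - 1) %/% nwj
      wj <- (w - 1) %% nwj
      rows <- wi * M + seq_len(M)
      cols <- wj * M + seq_len(M)
      pos <- expand.grid(b = cols, a = rows)[, c("a", "b")]
      for (p in seq_len(M * M)) for (q in seq_len(M * M)) {
        bad <- (si[pos$a[p]] - si[pos$a[q]]) != (pos$a[p] - pos$a[q]) ||
          (sj[pos$b[p]] - sj[pos$b[q]]) != (pos$b[p] - pos$b[q])
        expect_identical(mask[p, q, w] < 0, bad)
      }
    }
    # a token always attends at least to itself
    expect_true(all(apply(mask == 0, c(1, 3), any)))
  }
  expect_error(build_attention_mask(8, 8, 4, 4), "smaller")
  expect_error(build_attention_mask(8, 8, 4, 0), "positive")
})

test_that("single-token windows reduce attention to the value path", {
  C <- 3L
  params <- random_attention_params(C, 11)
  x <- array(rnorm(2 * 2 * C), c(2, 2, C))
  win <- partition_windows(x, 1)
  out <- window_attention(win, params, matrix(0.7, 1, 1), k = 1L)
  # softmax over one key = 1: output = (V) %*% w_out + b_out, B irrelevant
  v <- img_to_tokens(x) %*% params$w_qkv[, 2 * C + seq_len(C)] +
    matrix(params$b_qkv[2 * C + seq_len(C)], 4, C, byrow = TRUE)
  expected <- v %*% params$w_out + matrix(params$b_out, 4, C, byrow = TRUE)
  expect_equal(merge_windows(out, 2, 2), tokens_to_img(expected, 2, 2),
               tolerance = 1e-12)
})

test_that("identical keys with zero bias give uniform attention weights", {
  C <- 2L; M <- 2L
  params <- random_attention_params(C, 12)
  params$w_qkv[, C + seq_len(C)] <- 0        # K identical (= bias b_qkv)
  set.seed(13)
  x <- array(rnorm(M * M * C), c(M, M, C))
  win <- partition_windows(x, M)
  out <- window_attention(win, params, matrix(0, (2 * M - 1)^2, 1), k = 1L)
  # each output token = mean of V rows, then output-mixed
  t <- img_to_tokens(x)
  v <- t %*% params$w_qkv[, 2 * C + seq_len(C)] +
    matrix(params$b_qkv[2 * C + seq_len(C)], 4, C, byrow = TRUE)
  mv <- matrix(colMeans(v), 4, C, byrow = TRUE)
  expected <- mv %*% params$w_out + matrix(params$b_out, 4, C, byrow = TRUE)
  expect_equal(out[, , 1], expected, tolerance = 1e-12)
})

test_that("window and shifted-window attention match the loop oracle", {
  H <- W <- 8L; M <- 4L; C <- 4L
  for (k in c(1L, 2L)) for (shift in c(0L, 2L)) {
    params <- random_attention_params(C, 20 + k + shift)
    set.seed(30 + k + shift)
    bias <- matrix(rnorm((2 * M - 1)^2 * k) * 0.5, (2 * M - 1)^2, k)
    x <- array(rnorm(H * W * C) * 0.7, c(H, W, C))
    got <- shifted_window_attention(x, params, bias, k, M, shift)
    want <- oracle_attention(x, params, bias, k, M, shift)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("unshifted window attention is equivariant to translation by M", {
  H <- W <- 8L; M <- 4L; C <- 4L; k <- 2L
  params <- random_attention_params(C, 41)
  set.seed(42)
  bias <- matrix(rnorm((2 * M - 1)^2 * k) * 0.5, (2 * M - 1)^2, k)
  x <- array(rnorm(H * W * C), c(H, W, C))
  y <- shifted_window_attention(x, params, bias, k, M, 0L)
  ys <- shifted_window_attention(cyclic_shift(x, M), params, bias, k, M, 0L)
  expect_equal(cyclic_shift(ys, -M), y, tolerance = 1e-12)
})

test_that("attention softmax rows are a valid distribution", {
  # recompute weights through the fused core and check rows sum to 1
  nw <- 4L; m <- 16L; k <- 2L; C <- 4L
  set.seed(50)
  qkv <- matrix(rnorm(nw * m * 3 * C), nw * m, 3 * C)
  bias <- array(rnorm(m * m * k), c(m, m, k))
  r <- sctwin:::cpp_attn_fwd(qkv, bias, array(0, c(1, 1, 1)), FALSE,
                             nw, m, k, 0.5)
  A <- r$A
  expect_true(all(A >= 0))
  expect_true(all(abs(apply(A, 3, rowSums) - 1) < 1e-6))
})
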