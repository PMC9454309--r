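# Architecture-level contracts: shapes, determinism, parameter accounting,
# degenerate paths and the LeFF layer.

test_that("forward pass preserves shape and is deterministic", {
  cfg <- tiny_net()
  p <- init_network_params(cfg, seed = 3)
  set.seed(4)
  x <- matrix(rnorm(64 * 64) * 0.2, 64, 64)
  y1 <- forward_net(x, cfg, p)
  expect_equal(dim(y1), c(64L, 64L))
  expect_identical(forward_net(x, cfg, p), y1)
  # non-divisible input is reflect-padded and cropped back
  x2 <- matrix(rnorm(70 * 90) * 0.2, 70, 90)
  expect_equal(dim(forward_net(x2, cfg, p)), c(70L, 90L))
  expect_error(forward_net(matrix(c(NA, 1, 2, 3), 2, 2), cfg, p),
               "non-finite")
})

test_that("parameter count matches an independent closed-form inventory", {
  closed_form <- function(C0, M, heads, e) {
    blk <- function(C, k) {
      2 * C + (3 * C^2 + 3 * C) + (C^2 + C) + (2 * M - 1)^2 * k + 2 * C +
        (e * C^2 + e * C) + (9 * e * C + e * C) + (e * C^2 + C)
    }
    ch <- C0 * c(1, 2, 4, 8, 16)
    total <- 9 * ch[1] + ch[1]                       # input projection
    for (s in 1:4) {
      total <- total + 2 * blk(ch[s], heads[s]) +
        16 * ch[s] * ch[s + 1] + ch[s + 1]           # downsampling conv
    }
    total <- total + 2 * blk(ch[5], heads[5])        # bottleneck
    for (s in 4:1) {
      total <- total + 4 * ch[s + 1] * ch[s] + ch[s] +  # up-conv
        2 * ch[s] * ch[s] + ch[s] +                     # skip fusion
        2 * blk(ch[s], heads[s])
    }
    total + 9 * ch[1] + 1                            # output projection
  }
  cases <- list(list(8L, 4L, c(1L, 2L, 4L, 8L, 8L), 2L),
                list(4L, 4L, c(1L, 1L, 2L, 4L, 8L), 4L),
                list(6L, 8L, c(1L, 2L, 3L, 6L, 12L), 3L))
  for (cs in cases) {
    cfg <- network_config(base_channels = cs[[1]], window = cs[[2]],
                          heads = cs[[3]], leff_expansion = cs[[4]])
    want <- closed_form(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_identical(count_parameters(cfg), want)
    expect_identical(sum(vapply(init_network_params(cfg, 1), length,
                                integer(1))), as.integer(want))
  }
  # the bias table contributes (2M-1)^2 * k per attention layer
  base <- network_config(base_channels = 8L, window = 4L,
                         heads = c(1L, 1L, 1L, 1L, 1L))
  wide <- network_config(base_channels = 8L, window = 8L,
                         heads = c(1L, 1L, 1L, 1L, 1L))
  n_attn <- 2L * (2L * 4L + 1L)      # 2 blocks per level, enc+dec+bottleneck
  expect_identical(count_parameters(wide) - count_parameters(base),
                   n_attn * (15^2 - 7^2))
  # doubling C0 more than doubles the count (quadratic weight matrices)
  expect_gt(count_parameters(network_config(base_channels = 16L, window = 4L)),
            2 * count_parameters(network_config(base_channels = 8L,
                                                window = 4L)))
})

test_that("zeroed residual-branch outputs make transformer blocks identity", {
  cfg <- tiny_net()
  p <- init_network_params(cfg, seed = 5)
  for (nm in grep("(proj\\.w|proj\\.b|leff2\\.w|leff2\\.b)$", names(p),
                  value = TRUE)) {
    if (grepl("(in_proj|out_proj)", nm)) next
    p[[nm]] <- p[[nm]] * 0
  }
  # one block in isolation is the identity on tokens
  set.seed(6)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  t0 <- img_to_tokens(x)
  got <- sctwin:::tf_block(sctwin:::tn(t0), lapply(p, sctwin:::tn),
                           "enc1.blk1", 8L, 8L, 4L, 0L, 1L, "rsqrt_d")
  expect_equal(got$value, t0, tolerance = 1e-12)
  # GELU(0) = 0 also silences the LeFF shrink bias path; the whole
  # encoder-decoder still runs and keeps its shape
  xin <- matrix(rnorm(64 * 64) * 0.2, 64, 64)
  expect_equal(dim(forward_net(xin, cfg, p)), c(64L, 64L))
})

test_that("LeFF is a pointwise GELU stack when spatial mixing is disabled", {
  C <- 2L
  w_dw <- array(0, c(3, 3, C))
  w_dw[2, 2, ] <- 1                      # centre-tap identity kernel
  params <- list(w1 = diag(C), b1 = numeric(C),
                 w_dw = w_dw, b_dw = numeric(C),
                 w2 = diag(C), b2 = numeric(C))
  x <- matrix(c(0.5, -0.3, 1.2, 0.1, -1, 2, 0.7, -0.2), 4, C)
  got <- leff(x, 2, 2, params)
  gelu <- function(v) v * pnorm(v)
  expect_equal(got, gelu(gelu(gelu(x))), tolerance = 1e-12)
  expect_equal(dim(got), dim(x))
})

test_that("a changed pixel only propagates within the LeFF 3x3 support", {
  C <- 2L
  set.seed(8)
  params <- list(w1 = matrix(rnorm(C * C), C, C), b1 = rnorm(C),
                 w_dw = array(rnorm(9 * C), c(3, 3, C)), b_dw = rnorm(C),
                 w2 = matrix(rnorm(C * C), C, C), b2 = rnorm(C))
  H <- W <- 8L
  x <- matrix(rnorm(H * W * C), H * W, C)
  x2 <- x
  pix <- c(4L, 5L)                       # (i, j) of perturbed token
  n0 <- (pix[1] - 1L) * W + pix[2]
  x2[n0, ] <- x2[n0, ] + 1
  dif <- rowSums(abs(leff(x2, H, W, params) - leff(x, H, W, params)))
  moved <- which(dif > 1e-12)
  ij <- cbind(((moved - 1L) %/% W) + 1L, ((moved - 1L) %% W) + 1L)
  expect_true(all(abs(ij[, 1] - pix[1]) <= 1 & abs(ij[, 2] - pix[2]) <= 1))
  expect_true(n0 %in% moved)
})

test_that("every parameter group receives gradient through the loss", {
  cfg <- tiny_net()
  p <- init_network_params(cfg, seed = 9)
  set.seed(10)
  x <- matrix(rnorm(64 * 64) * 0.2, 64, 64)
  y <- matrix(rnorm(64 * 64) * 0.2, 64, 64)
  r <- sctwin:::step_gradients(x, y, cfg, p, loss_config())
  nz <- vapply(r$grads, function(g) !is.null(g) && any(g != 0), logical(1))
  expect_identical(sum(nz), length(p))
})
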