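# Independent oracles and small fixtures, all generated in code.

# brute-force (shifted-)window multi-head attention: explicit loops over
# windows and token pairs; masking decided from source-coordinate
# consistency, relative-position rows computed inline from 2D offsets.
oracle_attention <- function(x, params, bias_table, k, M, shift = 0,
                             scale = NULL) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  dh <- C / k
  if (is.null(scale)) scale <- 1 / sqrt(dh)
  si <- ((seq_len(H) - 1 + shift) %% H) + 1
  sj <- ((seq_len(W) - 1 + shift) %% W) + 1
  xs <- x[si, sj, , drop = FALSE]          # shifted map
  out_s <- array(0, dim = d)
  for (wi in seq_len(H / M)) for (wj in seq_len(W / M)) {
    rows <- (wi - 1) * M + seq_len(M)
    cols <- (wj - 1) * M + seq_len(M)
    pos <- expand.grid(b = cols, a = rows)[, c("a", "b")]  # row-major
    m <- M * M
    feats <- t(vapply(seq_len(m),
                      function(p) xs[pos$a[p], pos$b[p], ], numeric(C)))
    qkv <- feats %*% params$w_qkv + matrix(params$b_qkv, m, 3 * C,
                                           byrow = TRUE)
    outw <- matrix(0, m, C)
    for (h in seq_len(k)) {
      hc <- (h - 1) * dh + seq_len(dh)
      A <- matrix(0, m, m)
      for (p in seq_len(m)) {
        logits <- numeric(m)
        for (q in seq_len(m)) {
          dot <- sum(qkv[p, hc] * qkv[q, C + hc]) * scale
          di <- ((pos$a[p] - 1) %% M) - ((pos$a[q] - 1) %% M)
          dj <- ((pos$b[p] - 1) %% M) - ((pos$b[q] - 1) %% M)
          brow <- (di + M - 1) * (2 * M - 1) + (dj + M - 1) + 1
          logits[q] <- dot + bias_table[brow, h]
          # forbid pairs whose pre-shift content was not spatially adjacent
          if ((si[pos$a[p]] - si[pos$a[q]]) != (pos$a[p] - pos$a[q]) ||
              (sj[pos$b[p]] - sj[pos$b[q]]) != (pos$b[p] - pos$b[q]))
            logits[q] <- logits[q] - 1e9
        }
        e <- exp(logits - max(logits))
        A[p, ] <- e / sum(e)
      }
      for (p in seq_len(m))
        outw[p, hc] <- colSums(A[p, ] * qkv[, 2 * C + hc, drop = FALSE])
    }
    outw <- outw %*% params$w_out + matrix(params$b_out, m, C, byrow = TRUE)
    for (p in seq_len(m)) out_s[pos$a[p], pos$b[p], ] <- outw[p, ]
  }
  ii <- ((seq_len(H) - 1 - shift) %% H) + 1
  jj <- ((seq_len(W) - 1 - shift) %% W) + 1
  out_s[ii, jj, , drop = FALSE]            # inverse shift
}

random_attention_params <- function(C, seed) {
  set.seed(seed)
  list(w_qkv = matrix(rnorm(C * 3 * C) * 0.4, C, 3 * C),
       b_qkv = rnorm(3 * C) * 0.1,
       w_out = matrix(rnorm(C * C) * 0.4, C, C),
       b_out = rnorm(C) * 0.1)
}

# exhaustive gamma search over the full sub-voxel candidate grid,
# vectorized per offset with its own trilinear interpolation
oracle_gamma <- function(ref, test, cfg) {
  v <- ref$values
  tv <- test$values
  sp <- ref$spacing
  dm <- dim(v)
  R <- cfg$search_radius * cfg$dta
  s <- seq(-R, R, by = cfg$step * cfg$dta)
  off <- as.matrix(expand.grid(s, s, s))
  off <- off[rowSums(off^2) <= R^2 + 1e-12, , drop = FALSE]
  Dc <- cfg$dose_criterion / 100 * ref$prescription
  thr <- cfg$low_dose_threshold * ref$prescription
  gi <- slice.index(v, 1); gj <- slice.index(v, 2); gk <- slice.index(v, 3)
  lin <- function(i, j, k) i + (j - 1) * dm[1] + (k - 1) * dm[1] * dm[2]
  best <- array(Inf, dm)
  for (o in seq_len(nrow(off))) {
    x <- gi + off[o, 1] / sp[1]
    y <- gj + off[o, 2] / sp[2]
    z <- gk + off[o, 3] / sp[3]
    ok <- x >= 1 & x <= dm[1] & y >= 1 & y <= dm[2] & z >= 1 & z <= dm[3]
    x0 <- pmax(pmin(floor(x), dm[1] - 1), 1); fx <- x - x0
    y0 <- pmax(pmin(floor(y), dm[2] - 1), 1); fy <- y - y0
    z0 <- pmax(pmin(floor(z), dm[3] - 1), 1); fz <- z - z0
    if (dm[3] == 1) { z0 <- z * 0 + 1; fz <- z * 0 }
    dt <- tv[lin(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
      tv[lin(x0 + 1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
      tv[lin(x0, y0 + 1, z0)] * (1 - fx) * fy * (1 - fz) +
      tv[lin(x0 + 1, y0 + 1, z0)] * fx * fy * (1 - fz) +
      tv[lin(x0, y0, pmin(z0 + 1, dm[3]))] * (1 - fx) * (1 - fy) * fz +
      tv[lin(x0 + 1, y0, pmin(z0 + 1, dm[3]))] * fx * (1 - fy) * fz +
      tv[lin(x0, y0 + 1, pmin(z0 + 1, dm[3]))] * (1 - fx) * fy * fz +
      tv[lin(x0 + 1, y0 + 1, pmin(z0 + 1, dm[3]))] * fx * fy * fz
    g2 <- ((dt - v) / Dc)^2 +
      sum(off[o, ]^2) / cfg$dta^2
    g2[!ok] <- Inf
    best <- pmin(best, g2)
  }
  gam <- sqrt(best)
  gam[v < thr] <- NA
  gam
}

# one small phantom pair
make_test_pair <- function(seed = 1L, size = 64L,
                           params = artifact_params(seed = seed + 500L)) {
  cfg <- phantom_config(image_size = size, seed = seed)
  anat <- generate_anatomy(cfg)
  cbct <- degrade_to_cbct(anat$ct, anat$masks, params)
  list(ct = anat$ct, cbct = cbct, masks = anat$masks)
}

tiny_net <- function(...) {
  network_config(base_channels = 2L, window = 4L,
                 heads = c(1L, 1L, 1L, 1L, 1L), leff_expansion = 2L, ...)
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

tape_grad_check <- function(f_tape, x0, tol = 1e-5) {
  tape_start <- sctwin:::tape_start
  tn_leaf <- sctwin:::tn_leaf
  tape_backward <- sctwin:::tape_backward
  tape_stop <- sctwin:::tape_stop
  tape_start()
  leaf <- tn_leaf(x0)
  loss <- f_tape(leaf)
  g <- tape_backward(loss)[[leaf$id]]
  tape_stop()
  gn <- num_grad(function(x) f_tape(sctwin:::tn(x))$value, x0)
  max(abs(g - gn)) / max(1e-8, max(abs(gn)))
}
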