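# HU metrics, histograms, contour agreement and the gamma engine.

test_that("MAE/RMSE/PSNR reproduce their closed-form examples", {
  z4 <- rep(0, 4); o4 <- rep(1, 4)
  expect_identical(mae(o4, z4), 1)
  expect_identical(rmse(o4, z4), 1)
  expect_equal(psnr(o4, z4, max_p = 1), 0)
  expect_identical(mae(z4, z4), 0)
  expect_identical(psnr(z4, z4), Inf)
  y <- c(0, 2); yh <- c(1, 1)
  expect_identical(mae(yh, y), 1)
  expect_identical(rmse(yh, y), 1)
  expect_equal(psnr(yh, y, max_p = 255), 10 * log10(65025), tolerance = 1e-12)
  expect_equal(round(psnr(yh, y, max_p = 255), 2), 48.13)
  # cross-check the two code paths on random data
  set.seed(1)
  a <- matrix(rnorm(100, 0, 40), 10); b <- matrix(rnorm(100, 0, 40), 10)
  expect_equal(psnr(a, b, max_p = 2000),
               10 * log10(2000^2 / rmse(a, b)^2), tolerance = 1e-12)
  msk <- matrix(FALSE, 10, 10)
  expect_error(mae(a, b, msk), "empty")
  expect_error(mae(a, b[1:5, ]), "share grids")
})

test_that("HU histogram conserves counts and clamps to the end bins", {
  img <- matrix(40, 8, 8)
  edges <- c(-100, 0, 50, 100)
  h <- hu_histogram(img, bin_edges = edges)
  expect_identical(h, c(0L, 64L, 0L))
  set.seed(2)
  r <- matrix(rnorm(200, 0, 500), 10, 20)
  expect_identical(sum(hu_histogram(r, bin_edges = edges)), 200L)
  two <- matrix(c(rep(-1000, 32), rep(3000, 32)), 8, 8)  # beyond both edges
  expect_identical(hu_histogram(two, bin_edges = edges), c(32L, 0L, 32L))
  expect_error(hu_histogram(img, bin_edges = 5), ">= 2")
})

test_that("ROI statistics use the population sd and honour zeroing", {
  img <- matrix(40, 6, 6)
  roi <- matrix(FALSE, 6, 6); roi[2:3, 2:3] <- TRUE
  expect_equal(roi_stats(img, roi), c(mean = 40, sd = 0))
  img2 <- img; img2[roi] <- c(0, 2, 0, 2)
  expect_equal(roi_stats(img2, roi), c(mean = 1, sd = 1))
  # ROI outside the body of a preprocessed slice reads 0
  a <- generate_anatomy(phantom_config(image_size = 32L, seed = 3L))
  out <- !a$masks$body$mask
  expect_equal(unname(roi_stats(a$ct$values, out)["mean"]), 0)
  expect_error(roi_stats(img, matrix(FALSE, 6, 6)), "empty")
})

test_that("DSC counts overlap and defines empty-vs-empty as 1", {
  m <- matrix(FALSE, 8, 8)
  a <- m; a[2:5, 2:5] <- TRUE
  expect_identical(dsc(a, a), 1)
  b <- m; b[6:8, 6:8] <- TRUE
  expect_identical(dsc(a, b), 0)
  c4 <- m; c4[2:5, 2] <- TRUE       # |A| = 4 within a
  c2 <- m; c2[2:3, 2] <- TRUE       # |B| = 2, overlap 2
  expect_equal(dsc(c4, c2), 2 * 2 / 6)
  expect_identical(dsc(m, m), 1)
  expect_equal(dsc(a, b), dsc(b, a))
  # dilate-by-1 of a 10x10 square: 2*100 / (100 + 144)
  sq <- matrix(FALSE, 16, 16); sq[4:13, 4:13] <- TRUE
  dil <- matrix(FALSE, 16, 16); dil[3:14, 3:14] <- TRUE
  expect_equal(dsc(sq, dil), 200 / 244, tolerance = 1e-12)
})

test_that("MDA matches an all-pairs oracle and scales with spacing", {
  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  off <- matrix(FALSE, 20, 20); off[6:15, 5:14] <- TRUE   # 1 px down
  expect_identical(mda(sq, sq), 0)
  # independent oracle: explicit double loop over boundary pixels
  boundary <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    keep <- apply(idx, 1, function(p) {
      nb <- c(p[1] - 1, p[2], p[1] + 1, p[2], p[1], p[2] - 1, p[1], p[2] + 1)
      nb <- matrix(nb, ncol = 2, byrow = TRUE)
      any(nb[, 1] < 1 | nb[, 1] > nrow(m) | nb[, 2] < 1 | nb[, 2] > ncol(m)) ||
        !all(m[nb])
    })
    idx[keep, , drop = FALSE]
  }
  dmin <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)), numeric(1))
  }
  pa <- boundary(sq); pb <- boundary(off)
  want <- (mean(dmin(pa, pb)) + mean(dmin(pb, pa))) / 2
  expect_equal(mda(sq, off), want, tolerance = 1e-12)
  # doubling spacing doubles the distance; symmetry
  expect_equal(mda(contour_mask(sq, 2), contour_mask(off, 2)), 2 * want,
               tolerance = 1e-12)
  expect_equal(mda(off, sq), mda(sq, off))
  # monotone under growing offset
  off2 <- matrix(FALSE, 20, 20); off2[7:16, 5:14] <- TRUE
  off3 <- matrix(FALSE, 20, 20); off3[8:17, 5:14] <- TRUE
  expect_true(mda(sq, off) < mda(sq, off2) &&
                mda(sq, off2) < mda(sq, off3))
  expect_error(mda(sq, matrix(FALSE, 20, 20)), "empty")
})

test_that("gamma engine reproduces uniform-field closed forms", {
  u <- dose_grid(array(60, c(8, 8, 4)), c(1, 1, 1), prescription = 60)
  cfg <- gamma_config(dose_criterion = 1, dta = 1)
  same <- gamma_index(u, u, cfg)
  expect_true(all(same$gamma[!is.na(same$gamma)] == 0))
  expect_identical(same$pass_rate, 100)
  # +1% everywhere: no spatial remedy on a uniform field, gamma = 1 (passes)
  up1 <- dose_grid(array(60 * 1.01, c(8, 8, 4)), c(1, 1, 1), 60)
  g1 <- gamma_index(u, up1, cfg)
  expect_equal(max(abs(g1$gamma - 1), na.rm = TRUE), 0, tolerance = 1e-9)
  expect_identical(g1$pass_rate, 100)
  # +3%: gamma = 3, nothing passes
  up3 <- dose_grid(array(60 * 1.03, c(8, 8, 4)), c(1, 1, 1), 60)
  g3 <- gamma_index(u, up3, cfg)
  expect_equal(max(abs(g3$gamma - 3), na.rm = TRUE), 0, tolerance = 1e-9)
  expect_identical(g3$pass_rate, 0)
  # voxels below 10% of prescription are excluded
  lo <- u; lo$values[1, 1, 1] <- 1
  glo <- gamma_index(lo, lo, cfg)
  expect_true(is.na(glo$gamma[1, 1, 1]))
  expect_identical(glo$n_evaluated, length(u$values) - 1L)
  expect_error(gamma_index(u, dose_grid(array(60, c(4, 4, 4)), c(1, 1, 1), 60),
                           cfg), "share")
})

test_that("optimized gamma search equals the exhaustive oracle", {
  dp <- make_dose_pair(c(16L, 16L, 16L), spacing_mm = c(2, 2, 2),
                       prescription = 60, perturbation = 0.012)
  cfg <- gamma_config(dose_criterion = 1, dta = 1, search_radius = 1.5,
                      step = 0.2)
  got <- gamma_index(dp$ref, dp$test, cfg)$gamma
  want <- oracle_gamma(dp$ref, dp$test, cfg)
  expect_identical(is.na(got), is.na(want))
  expect_lt(max(abs(got - want), na.rm = TRUE), 1e-6)
})

test_that("gamma pass rate is monotone in perturbation and criteria", {
  rates <- vapply(c(0.01, 0.03, 0.06), function(pert) {
    dp <- make_dose_pair(c(12L, 12L, 8L), prescription = 60,
                         perturbation = pert)
    gamma_index(dp$ref, dp$test,
                gamma_config(2, 2, search_radius = 1.5, step = 0.25))$pass_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  dp <- make_dose_pair(c(12L, 12L, 8L), prescription = 60,
                       perturbation = 0.04)
  grid <- expand.grid(dose = c(1, 2, 4), dta = c(1, 2, 4))
  # keep the candidate spacing fixed in mm so coarser dta grids stay
  # supersets and the comparison is a pure criteria effect
  rate <- function(dose, dta)
    gamma_index(dp$ref, dp$test,
                gamma_config(dose, dta, search_radius = 1.5,
                             step = 0.5 / dta))$pass_rate
  rates <- matrix(mapply(rate, grid$dose, grid$dta), 3, 3)
  expect_true(all(apply(rates, 2, diff) >= 0))   # looser dose criterion
  expect_true(all(apply(rates, 1, diff) >= 0))   # looser dta criterion
})

test_that("evaluation report aggregates per-case metrics deterministically", {
  pair <- make_test_pair(seed = 30L, size = 32L)
  case1 <- list(ct = pair$ct, cbct = pair$cbct, sct = pair$ct,
                masks = pair$masks,
                masks_pred = list(bladder = perturb_mask(pair$masks$bladder,
                                                         1, seed = 5)))
  rep1 <- evaluation_report(list(case1))
  s <- rep1$summary
  expect_identical(unique(s$sd), 0)          # single case: sd 0
  expect_identical(s$mean[s$metric == "mae_sct"], 0)   # sct == ct here
  expect_gt(s$mean[s$metric == "mae_cbct"], 0)
  expect_true("dsc_bladder" %in% s$metric)
  td <- file.path(tempdir(), "rep")
  write_report(rep1, td)
  b1 <- readBin(file.path(td, "summary.json"), "raw", 1e6)
  write_report(rep1, td)
  expect_identical(readBin(file.path(td, "summary.json"), "raw", 1e6), b1)
  expect_error(evaluation_report(list()), "at least one")
})
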