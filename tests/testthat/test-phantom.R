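# Phantom generator: anatomy, degradation model, mask perturbation, dose
# pairs and dataset writing.

test_that("anatomy is zero outside the body, seeded, with disjoint organs", {
  cfg <- phantom_config(image_size = 64L, seed = 7L)
  a <- generate_anatomy(cfg)
  body <- a$masks$body$mask
  expect_true(all(a$ct$values[!body] == 0))
  expect_true(any(a$ct$values[body] != 0))
  b <- generate_anatomy(cfg)
  expect_identical(a$ct$values, b$ct$values)
  # organ disjointness and containment
  expect_false(any(a$masks$bladder$mask & a$masks$rectum$mask))
  expect_false(any(a$masks$bladder$mask & a$masks$bone$mask))
  expect_false(any(a$masks$rectum$mask & a$masks$bone$mask))
  for (org in c("bladder", "rectum", "bone"))
    expect_true(all(body[a$masks[[org]]$mask]))
  # geometry outside the body is a configuration error
  bad <- phantom_config(image_size = 64L,
                        geometry = list(bladder = c(cx = 0.05, cy = 0.05,
                                                    rx = 0.1, ry = 0.1)))
  expect_error(generate_anatomy(bad), "outside the body")
  expect_error(phantom_config(image_size = 40L), "divisible")
  expect_error(phantom_config(hu = c(air = -2000, soft = 40, bladder = 10,
                                     gas = -800, bone = 700)), "within")
})

test_that("degradation is the identity at zero amplitudes and adds the
          stated artifacts inside the body only", {
  a <- generate_anatomy(phantom_config(image_size = 64L, seed = 8L))
  zero <- artifact_params(cupping = 0, streak_count = 0, streak_amplitude = 0,
                          beam_hardening = 0, noise_sigma = 0,
                          global_shift = 0)
  expect_identical(degrade_to_cbct(a$ct, a$masks, zero)$values, a$ct$values)
  # pure global shift moves the in-body mean by exactly that amount
  sh <- artifact_params(cupping = 0, streak_count = 0, streak_amplitude = 0,
                        beam_hardening = 0, noise_sigma = 0,
                        global_shift = 50)
  d <- degrade_to_cbct(a$ct, a$masks, sh)
  body <- a$masks$body$mask
  expect_equal(mean(d$values[body] - a$ct$values[body]), 50,
               tolerance = 1e-12)
  expect_true(all(d$values[!body] == 0))
  # full model: deterministic per seed, distinct across seeds
  p1 <- artifact_params(seed = 1L)
  d1 <- degrade_to_cbct(a$ct, a$masks, p1)
  expect_identical(degrade_to_cbct(a$ct, a$masks, p1)$values, d1$values)
  d2 <- degrade_to_cbct(a$ct, a$masks, artifact_params(seed = 2L))
  expect_false(identical(d1$values, d2$values))
  expect_true(all(d1$values[!body] == 0))
  expect_error(artifact_params(cupping = -1), ">= 0")
})

test_that("MAE between CBCT and CT grows monotonically with global shift", {
  a <- generate_anatomy(phantom_config(image_size = 64L, seed = 9L))
  body <- a$masks$body$mask
  maes <- vapply(c(10, 25, 60, 120), function(gs) {
    d <- degrade_to_cbct(a$ct, a$masks,
                         artifact_params(cupping = 0, streak_count = 0,
                                         streak_amplitude = 0,
                                         beam_hardening = 0, noise_sigma = 0,
                                         global_shift = gs, seed = 3L))
    mae(d$values, a$ct$values, body)
  }, numeric(1))
  expect_true(all(diff(maes) > 0))
  # and any active amplitude separates CBCT from CT
  d <- degrade_to_cbct(a$ct, a$masks, artifact_params(seed = 3L))
  expect_gt(mae(d$values, a$ct$values, body), 0)
})

test_that("mask perturbation is bounded, seeded and clipped", {
  a <- generate_anatomy(phantom_config(image_size = 64L, seed = 10L))
  bl <- a$masks$bladder
  expect_identical(perturb_mask(bl, 0)$mask, bl$mask)
  p1 <- perturb_mask(bl, 2, seed = 4L, body = a$masks$body)
  expect_identical(perturb_mask(bl, 2, seed = 4L, body = a$masks$body)$mask,
                   p1$mask)
  expect_true(all(a$masks$body$mask[p1$mask]))
  expect_false(identical(p1$mask, bl$mask))
  # bounded by the magnitude: inside the 2-pixel erosion nothing changes
  expect_error(perturb_mask(contour_mask(matrix(FALSE, 4, 4)), 1), "empty")
})

test_that("dose pairs peak at the prescription and scale linearly", {
  dp <- make_dose_pair(c(16L, 16L, 8L), spacing_mm = c(2, 2, 3),
                       prescription = 60, perturbation = 0)
  expect_identical(dp$ref$values, dp$test$values)
  expect_equal(max(dp$ref$values), 60)
  dp1 <- make_dose_pair(c(16L, 16L, 8L), prescription = 60,
                        perturbation = 0.01)
  rel <- (dp1$test$values - dp1$ref$values) / 60
  expect_equal(max(rel), 0.01, tolerance = 1e-12)    # 1% at the peak
  expect_equal(dp1$test$values, dp1$ref$values * 1.01, tolerance = 1e-12)
  expect_error(make_dose_pair(c(8, 8, 8), prescription = 0), "positive")
  expect_error(make_dose_pair(c(8, 8, 8), perturbation = -0.1), ">= 0")
})

test_that("dataset writing is reproducible with a valid manifest", {
  td1 <- file.path(tempdir(), "ds1"); td2 <- file.path(tempdir(), "ds2")
  unlink(c(td1, td2), recursive = TRUE)
  cfg <- phantom_config(image_size = 32L, seed = 20L)
  ap <- artifact_params(seed = 21L)
  m1 <- generate_dataset(10L, cfg, ap, td1,
                         split = c(train = 0.8, val = 0.1, test = 0.1))
  expect_identical(nrow(m1), 10L)
  expect_identical(as.integer(table(m1$split)[c("train", "val", "test")]),
                   c(8L, 1L, 1L))
  generate_dataset(10L, cfg, ap, td2,
                   split = c(train = 0.8, val = 0.1, test = 0.1))
  expect_identical(readBin(file.path(td1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(td2, "manifest.csv"), "raw", 1e6))
  # written pairs satisfy the pairing contract
  pairs <- load_dataset(file.path(td1, "manifest.csv"))
  expect_length(pairs, 10L)
  for (p in pairs[c(1, 10)]) {
    expect_identical(dim(p$ct$values), dim(p$cbct$values))
    body <- p$masks$body$mask
    expect_true(all(abs(p$ct$values[!body]) < 1e-4))   # float32 storage
    expect_true(all(abs(p$cbct$values[!body]) < 1e-4))
    expect_false(any(p$masks$bladder$mask & p$masks$rectum$mask))
  }
})
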