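# Seeded digital pelvis phantom: an analytic 2D cartoon (elliptical body, two
# circular femoral-head bones, elliptical bladder, rectum disk with a gas
# pocket) plus a CBCT degradation model (cupping, photon-starvation streaks,
# a beam-hardening band between the bones, noise, global HU shift), mask
# perturbation for contour-metric testing, and analytic dose-grid pairs for
# gamma analysis. Everything downstream of data loading is testable on these
# phantoms without any external data.

#' A single 2D HU image with grid spacing and body mask
#'
#' @param values (H, W) numeric matrix in Hounsfield units.
#' @param spacing pixel spacing in mm, length 2 (row, col) or scalar.
#' @param body optional logical (H, W) body mask.
#' @return an object of class \code{image_slice}.
#' @export
image_slice <- function(values, spacing = c(1, 1), body = NULL) {
  stopifnot(is.matrix(values))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (!is.null(body)) stopifnot(identical(dim(body), dim(values)))
  structure(list(values = values, spacing = as.numeric(spacing), body = body),
            class = "image_slice")
}

#' A binary contour mask with grid spacing
#'
#' @param mask logical matrix.
#' @param spacing pixel spacing in mm, length 2 or scalar.
#' @return an object of class \code{contour_mask}.
#' @export
contour_mask <- function(mask, spacing = c(1, 1)) {
  stopifnot(is.matrix(mask))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  structure(list(mask = mask > 0, spacing = as.numeric(spacing)),
            class = "contour_mask")
}

as_mask_matrix <- function(m) {
  if (inherits(m, "contour_mask")) m$mask else m > 0
}

#' A 3D dose grid
#'
#' @param values non-negative 3D array of dose in Gy.
#' @param spacing voxel spacing in mm, length 3.
#' @param prescription prescription dose in Gy.
#' @return an object of class \code{dose_grid}.
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), prescription) {
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, all(values >= 0),
            all(spacing > 0), prescription > 0)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(values = values, spacing = as.numeric(spacing),
                 prescription = prescription), class = "dose_grid")
}

#' Phantom configuration
#'
#' Geometry is given as fractions of the image side; HU assignments per
#' tissue class follow typical pelvis values.
#'
#' @param image_size pixels per (square) side; >= 32 and divisible by 16.
#' @param pixel_spacing pixel size in mm.
#' @param hu named HU per tissue class (air, soft, bladder, gas, bone).
#' @param geometry list with body/bladder/rectum ellipse-circle parameters
#'   and the two bone circles (see defaults).
#' @param texture_sd std dev (HU) of the smooth seeded texture added inside
#'   the body.
#' @param seed integer seed.
#' @return an object of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = 128L, pixel_spacing = 1.0,
                           hu = c(air = -1000, soft = 40, bladder = 10,
                                  gas = -800, bone = 700),
                           geometry = NULL, texture_sd = 5, seed = 1L) {
  if (image_size < 32L || image_size %% 16L != 0L)
    stop("image_size must be >= 32 and divisible by 16", call. = FALSE)
  if (any(!is.finite(hu)) || any(hu < -1024) || any(hu > 3000))
    stop("hu values must be finite and within [-1024, 3000]", call. = FALSE)
  g <- list(
    body = c(cx = 0.50, cy = 0.52, rx = 0.42, ry = 0.34),
    bladder = c(cx = 0.50, cy = 0.42, rx = 0.13, ry = 0.10),
    rectum = c(cx = 0.50, cy = 0.68, r = 0.07, gas_r = 0.04),
    bone1 = c(cx = 0.28, cy = 0.58, r = 0.07),
    bone2 = c(cx = 0.72, cy = 0.58, r = 0.07))
  if (!is.null(geometry)) g[names(geometry)] <- geometry
  radii <- c(g$body[c("rx", "ry")], g$bladder[c("rx", "ry")],
             g$rectum[c("r", "gas_r")], g$bone1["r"], g$bone2["r"])
  if (any(radii <= 0)) stop("all radii must be positive", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing, hu = hu, geometry = g,
                 texture_sd = texture_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Artifact parameters of the CBCT degradation model
#'
#' With every amplitude at 0 (and streak_count 0) the degradation is the
#' identity on the body region.
#'
#' @param cupping amplitude (HU) of the radial cupping bias, strongest
#'   (most negative) at the body center.
#' @param streak_count number of photon-starvation streak lines.
#' @param streak_amplitude amplitude (HU) of the streaks (alternating
#'   dark/bright).
#' @param beam_hardening amplitude (HU) of the dark band on the chord
#'   between the two bones.
#' @param noise_sigma std dev (HU) of zero-mean pixel noise.
#' @param global_shift constant HU offset inside the body.
#' @param seed integer seed for streak placement and noise.
#' @return an object of class \code{artifact_params}.
#' @export
artifact_params <- function(cupping = 40, streak_count = 6L,
                            streak_amplitude = 30, beam_hardening = 30,
                            noise_sigma = 10, global_shift = 25, seed = 1L) {
  if (any(c(cupping, streak_amplitude, beam_hardening, noise_sigma) < 0))
    stop("artifact amplitudes must be >= 0", call. = FALSE)
  if (streak_count < 0) stop("streak_count must be >= 0", call. = FALSE)
  structure(list(cupping = cupping, streak_count = as.integer(streak_count),
                 streak_amplitude = streak_amplitude,
                 beam_hardening = beam_hardening, noise_sigma = noise_sigma,
                 global_shift = global_shift, seed = as.integer(seed)),
            class = "artifact_params")
}

# smooth a matrix with a Gaussian kernel (zero-padded borders)
blur_matrix <- function(m, sigma) {
  win <- 2L * ceiling(2 * sigma) + 1L
  g <- gauss_kernel1d(win, sigma)
  x <- array(m, c(dim(m), 1L))
  p <- (win - 1L) %/% 2L
  h <- cpp_dwconv_fwd(x, g, 0, win, 1L, p, 0L)          # down rows
  h2 <- cpp_dwconv_fwd(h, g, 0, 1L, win, 0L, p)         # across cols
  h2[, , 1L]
}

#' Generate a clean CT slice with organ masks
#'
#' Piecewise-constant HU per tissue class plus a small seeded smooth
#' texture; the background outside the body is exactly 0. Deterministic
#' given the config seed.
#'
#' @param config a [phantom_config()].
#' @return list with \code{ct} (an [image_slice()]) and \code{masks}
#'   (named list of [contour_mask()]: body, bladder, rectum, bone).
#' @export
generate_anatomy <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  g <- config$geometry
  # normalized coordinates: rows = y, cols = x
  y <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n)
  x <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)
  ellipse <- function(p) {
    ((x - p["cx"]) / p["rx"])^2 + ((y - p["cy"]) / p["ry"])^2 <= 1
  }
  circle <- function(cx, cy, r) (x - cx)^2 + (y - cy)^2 <= r^2
  body <- ellipse(g$body)
  bladder <- ellipse(g$bladder)
  rectum <- circle(g$rectum["cx"], g$rectum["cy"], g$rectum["r"])
  gas <- circle(g$rectum["cx"], g$rectum["cy"], g$rectum["gas_r"])
  bone <- circle(g$bone1["cx"], g$bone1["cy"], g$bone1["r"]) |
    circle(g$bone2["cx"], g$bone2["cy"], g$bone2["r"])
  organs <- list(bladder = bladder, rectum = rectum, bone = bone)
  for (nm in names(organs)) {
    if (any(organs[[nm]] & !body))
      stop(sprintf("organ '%s' extends outside the body", nm), call. = FALSE)
  }
  if (any(bladder & rectum) || any(bladder & bone) || any(rectum & bone))
    stop("organ masks must be disjoint", call. = FALSE)
  hu <- config$hu
  ct <- matrix(hu["soft"], n, n)
  ct[bladder] <- hu["bladder"]
  ct[bone] <- hu["bone"]
  ct[gas] <- hu["gas"]
  if (config$texture_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(config$seed)
    tex <- blur_matrix(matrix(stats::rnorm(n * n), n, n), 3)
    tex <- tex / stats::sd(tex) * config$texture_sd
    ct <- ct + tex
  }
  ct[!body] <- 0
  sp <- rep(config$pixel_spacing, 2L)
  list(ct = image_slice(ct, sp, body),
       masks = list(body = contour_mask(body, sp),
                    bladder = contour_mask(bladder, sp),
                    rectum = contour_mask(rectum, sp),
                    bone = contour_mask(bone, sp)))
}

# distance (px) from each pixel to the segment (a, b); coords in px
dist_to_segment <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx^2 + vy^2
  t <- ((px - a[1]) * vx + (py - a[2]) * vy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Degrade a clean CT slice into a CBCT-like slice
#'
#' Adds, strictly inside the body: a radial cupping bias (most negative at
#' the body center), seeded straight photon-starvation streaks through the
#' bone regions with a Gaussian cross-profile (sigma 1.5 px, alternating
#' sign), a dark beam-hardening band on the chord between the two bones,
#' zero-mean Gaussian noise, and a constant global HU shift. The background
#' stays exactly 0, and with all amplitudes 0 the output equals the input.
#'
#' @param ct an [image_slice()] from [generate_anatomy()].
#' @param masks the mask set from [generate_anatomy()].
#' @param params an [artifact_params()].
#' @return an [image_slice()] of the degraded CBCT.
#' @export
degrade_to_cbct <- function(ct, masks, params) {
  stopifnot(inherits(ct, "image_slice"), inherits(params, "artifact_params"))
  body <- as_mask_matrix(masks$body)
  bone <- as_mask_matrix(masks$bone)
  if (!identical(dim(body), dim(ct$values)))
    stop("ct and masks must share shape", call. = FALSE)
  if (inherits(masks$body, "contour_mask") &&
      !isTRUE(all.equal(masks$body$spacing, ct$spacing)))
    stop("ct and masks must share spacing", call. = FALSE)
  n1 <- nrow(ct$values); n2 <- ncol(ct$values)
  out <- ct$values
  py <- matrix(rep(seq_len(n1), times = n2), n1, n2)
  px <- matrix(rep(seq_len(n2), each = n1), n1, n2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(params$seed)
  add <- matrix(0, n1, n2)
  if (params$cupping > 0) {
    ctr <- mask_centroid(body)
    d2 <- (py - ctr[1])^2 + (px - ctr[2])^2
    dmax2 <- max(d2[body])
    add <- add - params$cupping * pmax(1 - d2 / dmax2, 0)
  }
  if (params$streak_count > 0 && params$streak_amplitude > 0) {
    inb <- which(bone)
    pts <- sample(inb, params$streak_count, replace = length(inb) <
                    params$streak_count)
    th <- stats::runif(params$streak_count, 0, pi)
    for (s in seq_len(params$streak_count)) {
      i0 <- ((pts[s] - 1L) %% n1) + 1L
      j0 <- ((pts[s] - 1L) %/% n1) + 1L
      d <- abs((px - j0) * sin(th[s]) - (py - i0) * cos(th[s]))
      sgn <- if (s %% 2L == 0L) 1 else -1
      add <- add + sgn * params$streak_amplitude * exp(-d^2 / (2 * 1.5^2))
    }
  }
  if (params$beam_hardening > 0) {
    lab <- EBImage::bwlabel(bone)
    sizes <- tabulate(lab[lab > 0])
    top2 <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
    if (length(top2) == 2L) {
      c1 <- mask_centroid(lab == top2[1])
      c2 <- mask_centroid(lab == top2[2])
      d <- dist_to_segment(px, py, c(c1[2], c1[1]), c(c2[2], c2[1]))
      add <- add - params$beam_hardening * exp(-d^2 / (2 * 3^2))
    }
  }
  if (params$noise_sigma > 0) {
    add <- add + matrix(stats::rnorm(n1 * n2, 0, params$noise_sigma), n1, n2)
  }
  if (params$global_shift != 0) add <- add + params$global_shift
  out[body] <- out[body] + add[body]
  image_slice(out, ct$spacing, body)
}

#' Perturb a binary mask to emulate a predicted contour
#'
#' Morphological dilation/erosion combined with seeded boundary jitter:
#' pixels inside the eroded mask always stay, pixels in the dilation band
#' are kept where a smooth seeded field is positive. The band half-width is
#' \code{ceiling(magnitude)} pixels, so the perturbation is bounded by the
#' magnitude; magnitude 0 is the identity.
#'
#' @param mask a [contour_mask()] or logical matrix (non-empty).
#' @param magnitude perturbation bound in pixels (>= 0).
#' @param seed integer seed.
#' @param body optional clipping mask; the result never leaves it.
#' @return same type as \code{mask}.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L, body = NULL) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  out <- m
  if (magnitude > 0) {
    k <- 2L * as.integer(ceiling(magnitude)) + 1L
    brush <- EBImage::makeBrush(k, shape = "box")
    dil <- EBImage::dilate(m * 1, brush) > 0
    ero <- EBImage::erode(m * 1, brush) > 0
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
    J <- blur_matrix(matrix(stats::rnorm(length(m)), nrow(m), ncol(m)), 2)
    out <- ero | (dil & !ero & (J > 0))
  }
  if (!is.null(body)) out <- out & as_mask_matrix(body)
  if (inherits(mask, "contour_mask")) contour_mask(out, mask$spacing) else out
}

#' Paired reference/evaluated dose grids
#'
#' The reference dose is a smooth 3D Gaussian bell peaking exactly at the
#' prescription (the peak sits on a voxel); the evaluated dose is the
#' reference scaled by (1 + perturbation).
#'
#' @param shape integer length-3 grid shape.
#' @param spacing_mm voxel spacing in mm (length 3 or scalar).
#' @param prescription prescription dose in Gy (> 0).
#' @param perturbation non-negative fractional dose scaling of the
#'   evaluated grid.
#' @param sigma_frac Gaussian sigma as a fraction of the largest grid
#'   extent.
#' @return list with \code{ref} and \code{test} [dose_grid()]s.
#' @export
make_dose_pair <- function(shape, spacing_mm = c(1, 1, 1), prescription = 60,
                           perturbation = 0, sigma_frac = 0.25) {
  if (prescription <= 0) stop("prescription must be positive", call. = FALSE)
  if (perturbation < 0) stop("perturbation must be >= 0", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  peak <- (shape + 1L) %/% 2L
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - peak[a]) * spacing_mm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  sigma <- sigma_frac * max(shape * spacing_mm)
  ref <- prescription * exp(-d2 / (2 * sigma^2))
  list(ref = dose_grid(ref, spacing_mm, prescription),
       test = dose_grid(ref * (1 + perturbation), spacing_mm, prescription))
}

#' Generate and write a paired phantom dataset
#'
#' Writes n CT/CBCT pairs (plus body and organ-label masks) as NIfTI under
#' \code{out_dir} together with a manifest CSV (id, split, seed, paths).
#' Per-sample seeds derive from the config seed, so a re-run reproduces the
#' manifest byte for byte.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param config a [phantom_config()]; its seed is the master seed.
#' @param params an [artifact_params()].
#' @param out_dir output directory (created if needed).
#' @param split named train/val/test fractions summing to 1.
#' @return the manifest as a data.frame (invisibly; also written to
#'   \code{out_dir/manifest.csv}).
#' @export
generate_dataset <- function(n_pairs, config, params, out_dir,
                             split = c(train = 0.8, val = 0.1, test = 0.1)) {
  stopifnot(n_pairs >= 1, abs(sum(split) - 1) < 1e-8)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  n_tr <- floor(split[[1]] * n_pairs)
  n_va <- floor(split[[2]] * n_pairs)
  n_te <- n_pairs - n_tr - n_va
  splits <- rep(c("train", "val", "test"), times = c(n_tr, n_va, n_te))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    seed_i <- (config$seed * 10007L + i) %% 2147483647L
    cfg_i <- config; cfg_i$seed <- seed_i
    par_i <- params; par_i$seed <- (seed_i + 1L) %% 2147483647L
    anat <- generate_anatomy(cfg_i)
    cbct <- degrade_to_cbct(anat$ct, anat$masks, par_i)
    organs <- matrix(0L, nrow(anat$ct$values), ncol(anat$ct$values))
    organs[as_mask_matrix(anat$masks$bladder)] <- 1L
    organs[as_mask_matrix(anat$masks$rectum)] <- 2L
    organs[as_mask_matrix(anat$masks$bone)] <- 3L
    paths <- sprintf("%s_%04d.nii.gz", c("ct", "cbct", "body", "organs"), i)
    write_volume(anat$ct$values, file.path(out_dir, paths[1]),
                 spacing = c(anat$ct$spacing, 1))
    write_volume(cbct$values, file.path(out_dir, paths[2]),
                 spacing = c(cbct$spacing, 1))
    write_volume(as_mask_matrix(anat$masks$body) * 1,
                 file.path(out_dir, paths[3]), spacing = c(anat$ct$spacing, 1))
    write_volume(organs * 1, file.path(out_dir, paths[4]),
                 spacing = c(anat$ct$spacing, 1))
    rows[[i]] <- data.frame(id = i, split = splits[i], seed = seed_i,
                            path_ct = paths[1], path_cbct = paths[2],
                            path_body = paths[3], path_organs = paths[4],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a written phantom dataset back into memory
#'
#' @param manifest manifest data.frame or path to manifest.csv.
#' @param dir dataset directory (defaults to the manifest's directory).
#' @param split optional split filter ("train", "val", "test").
#' @return list of pairs: each has \code{ct}, \code{cbct} ([image_slice()])
#'   and \code{masks} (named [contour_mask()] list).
#' @export
load_dataset <- function(manifest, dir = NULL, split = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(!is.null(dir))
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  lapply(seq_len(nrow(manifest)), function(r) {
    row <- manifest[r, ]
    ctv <- read_volume(file.path(dir, row$path_ct), drop = TRUE)
    cbv <- read_volume(file.path(dir, row$path_cbct), drop = TRUE)
    body <- read_volume(file.path(dir, row$path_body), drop = TRUE)$values > 0
    org <- read_volume(file.path(dir, row$path_organs), drop = TRUE)$values
    sp <- ctv$spacing[1:2]
    list(ct = image_slice(ctv$values, sp, body),
         cbct = image_slice(cbv$values, sp, body),
         masks = list(body = contour_mask(body, sp),
                      bladder = contour_mask(org == 1, sp),
                      rectum = contour_mask(org == 2, sp),
                      bone = contour_mask(org == 3, sp)))
  })
}
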