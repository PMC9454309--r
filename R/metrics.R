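# Evaluation stack: HU-accuracy metrics (MAE, RMSE, PSNR), HU histograms and
# ROI statistics, contour agreement (DSC, MDA), global 3D gamma analysis, and
# report aggregation.

metric_mask <- function(test, ref, mask) {
  if (!identical(dim_of(test), dim_of(ref)))
    stop("images must share grids", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim_of(test))
  mask <- mask > 0
  if (!identical(dim_of(mask), dim_of(test)))
    stop("mask must share the image grid", call. = FALSE)
  if (!any(mask)) stop("empty evaluation mask", call. = FALSE)
  mask
}

#' Mean absolute error over an evaluation mask
#'
#' @param test test image (HU), array of any dimension.
#' @param ref reference image (HU), same shape.
#' @param mask optional logical mask of pixels involved in the calculation;
#'   default: every pixel. For paired body images, pass the union of the two
#'   body masks.
#' @return MAE in HU.
#' @export
mae <- function(test, ref, mask = NULL) {
  m <- metric_mask(test, ref, mask)
  mean(abs(test[m] - ref[m]))
}

#' Root mean square error over an evaluation mask
#'
#' @inheritParams mae
#' @return RMSE in HU.
#' @export
rmse <- function(test, ref, mask = NULL) {
  m <- metric_mask(test, ref, mask)
  sqrt(mean((test[m] - ref[m])^2))
}

#' Peak signal-to-noise ratio over an evaluation mask
#'
#' PSNR = 10 log10(max_p^2 / MSE). A perfect match is reported as +Inf.
#'
#' @inheritParams mae
#' @param max_p possible maximum pixel value; the default 2000 is the width
#'   of the default (-1000, 1000) HU window. Set
#'   \code{max_p = max(abs(ref))} for a per-image convention.
#' @return PSNR in dB.
#' @export
psnr <- function(test, ref, mask = NULL, max_p = 2000) {
  m <- metric_mask(test, ref, mask)
  mse <- mean((test[m] - ref[m])^2)
  if (mse == 0) return(Inf)
  10 * log10(max_p^2 / mse)
}

#' HU histogram over a mask
#'
#' Counts masked pixels per bin; values beyond the outer edges are counted
#' in the first/last bin, so the counts always sum to the mask size.
#'
#' @param image numeric array (HU).
#' @param mask logical mask (default: all pixels).
#' @param bin_edges strictly increasing numeric edges (>= 2).
#' @return integer vector of length \code{length(bin_edges) - 1}.
#' @export
hu_histogram <- function(image, mask = NULL, bin_edges) {
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be >= 2 strictly increasing values", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim_of(image))
  v <- image[mask > 0]
  bins <- findInterval(v, bin_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  tabulate(bins, nbins = length(bin_edges) - 1L)
}

#' Mean and standard deviation of HU inside a region of interest
#'
#' Uses the population standard deviation (divide by n), treating the ROI
#' pixels as the full population of interest.
#'
#' @param image numeric array (HU).
#' @param roi a [contour_mask()] or logical array, non-empty.
#' @return named numeric vector c(mean, sd).
#' @export
roi_stats <- function(image, roi) {
  m <- as_mask_matrix(roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  v <- image[m]
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

#' Dice similarity coefficient
#'
#' 2|A n B| / (|A| + |B|). Two empty masks are defined as perfectly
#' agreeing (DSC 1).
#'
#' @param a,b [contour_mask()]s or logical arrays on the same grid.
#' @return DSC in [0, 1].
#' @export
dsc <- function(a, b) {
  am <- as_mask_matrix(a)
  bm <- as_mask_matrix(b)
  if (!identical(dim_of(am), dim_of(bm)))
    stop("masks must share grids", call. = FALSE)
  sa <- sum(am); sb <- sum(bm)
  if (sa + sb == 0) return(1)
  2 * sum(am & bm) / (sa + sb)
}

# boundary pixels: mask minus its 4-neighbour erosion (array edges count)
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  er <- m
  er[2:H, ] <- er[2:H, ] & m[1:(H - 1), ]
  er[1:(H - 1), ] <- er[1:(H - 1), ] & m[2:H, ]
  er[, 2:W] <- er[, 2:W] & m[, 1:(W - 1)]
  er[, 1:(W - 1)] <- er[, 1:(W - 1)] & m[, 2:W]
  er[1, ] <- FALSE; er[H, ] <- FALSE; er[, 1] <- FALSE; er[, W] <- FALSE
  m & !er
}

boundary_points_mm <- function(m, spacing) {
  idx <- which(mask_boundary(m), arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
}

#' Mean distance to agreement between two contours
#'
#' Symmetric mean surface distance: boundary points are extracted as the
#' mask minus its erosion; each boundary point of A contributes its nearest
#' distance (mm, spacing-aware) to the boundary of B, and the two directed
#' means are averaged.
#'
#' @param a,b non-empty [contour_mask()]s or logical matrices.
#' @param spacing pixel spacing in mm when plain matrices are given.
#' @return MDA in mm.
#' @export
mda <- function(a, b, spacing = c(1, 1)) {
  if (inherits(a, "contour_mask")) spacing <- a$spacing
  am <- as_mask_matrix(a)
  bm <- as_mask_matrix(b)
  if (!identical(dim_of(am), dim_of(bm)))
    stop("masks must share grids", call. = FALSE)
  if (!any(am) || !any(bm)) stop("empty mask", call. = FALSE)
  pa <- boundary_points_mm(am, spacing)
  pb <- boundary_points_mm(bm, spacing)
  directed <- function(p, q) {
    mins <- vapply(seq_len(nrow(p)), function(i) {
      sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
    }, numeric(1))
    mean(mins)
  }
  (directed(pa, pb) + directed(pb, pa)) / 2
}

#' Gamma-analysis configuration
#'
#' @param dose_criterion dose-difference criterion as a percent of the
#'   prescription dose (global normalization).
#' @param dta distance-to-agreement criterion in mm.
#' @param low_dose_threshold voxels below this fraction of the prescription
#'   are excluded from evaluation.
#' @param search_radius candidate search radius in multiples of dta.
#' @param step candidate spacing as a fraction of dta (sub-voxel trilinear
#'   interpolation of the evaluated dose).
#' @return an object of class \code{gamma_config}.
#' @export
gamma_config <- function(dose_criterion = 1, dta = 1,
                         low_dose_threshold = 0.10, search_radius = 3,
                         step = 0.1) {
  stopifnot(dose_criterion > 0, dta > 0, low_dose_threshold > 0,
            search_radius >= 1, step > 0)
  structure(list(dose_criterion = dose_criterion, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 search_radius = search_radius, step = step),
            class = "gamma_config")
}

gamma_offsets <- function(cfg) {
  R <- cfg$search_radius * cfg$dta
  s <- seq(-R, R, by = cfg$step * cfg$dta)
  off <- as.matrix(expand.grid(s, s, s))
  off[off[, 1]^2 + off[, 2]^2 + off[, 3]^2 <= R^2 + 1e-12, , drop = FALSE]
}

#' Global 3D gamma analysis
#'
#' For every reference voxel at or above the low-dose threshold, the gamma
#' index is the minimum over candidate points p within the search radius of
#' sqrt((Dd(p)/Dc)^2 + (r(p)/dta)^2), with Dd the dose difference between
#' the trilinearly interpolated evaluated dose at p and the reference voxel
#' dose, Dc = dose_criterion percent of the prescription (global
#' normalization), and r the distance to p. Gamma <= 1 counts as passing.
#'
#' @param ref,test [dose_grid()]s on the same grid.
#' @param cfg a [gamma_config()].
#' @return list with \code{gamma} (array, NA where not evaluated),
#'   \code{pass_rate} (percent of evaluated voxels with gamma <= 1) and
#'   \code{n_evaluated}.
#' @export
gamma_index <- function(ref, test, cfg = gamma_config()) {
  stopifnot(inherits(ref, "dose_grid"), inherits(test, "dose_grid"))
  if (!identical(dim(ref$values), dim(test$values)) ||
      !isTRUE(all.equal(ref$spacing, test$spacing)))
    stop("dose grids must share shape and spacing", call. = FALSE)
  if (ref$prescription <= 0) stop("prescription must be positive",
                                  call. = FALSE)
  g <- cpp_gamma(ref$values, test$values, ref$spacing, gamma_offsets(cfg),
                 cfg$dose_criterion / 100 * ref$prescription, cfg$dta,
                 cfg$low_dose_threshold * ref$prescription)
  ev <- !is.na(g)
  list(gamma = g,
       pass_rate = 100 * mean(g[ev] <= 1 + 1e-12),
       n_evaluated = sum(ev))
}

#' Per-case and aggregate evaluation report
#'
#' Computes, for each case, the HU metrics of the raw CBCT and the sCT
#' against the reference CT (over the body mask), per-organ contour
#' agreement (DSC/MDA) when predicted masks are present, and the gamma pass
#' rate when dose grids are present; aggregates mean and sample sd (n-1)
#' per metric.
#'
#' @param cases list; each case is a list with \code{ct}, \code{cbct},
#'   optionally \code{sct} (HU matrices or [image_slice()]s), \code{masks}
#'   (named [contour_mask()] list incl. body), optionally
#'   \code{masks_pred}, and optionally \code{dose_ref}/\code{dose_test}.
#' @param gamma_cfg a [gamma_config()] for the dose comparison.
#' @param max_p PSNR peak value.
#' @return list with \code{per_case} and \code{summary} data.frames.
#' @export
evaluation_report <- function(cases, gamma_cfg = gamma_config(),
                              max_p = 2000) {
  if (length(cases) < 1L) stop("need at least one case", call. = FALSE)
  vals <- function(x) if (inherits(x, "image_slice")) x$values else x
  rows <- list()
  add <- function(case_id, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(case = case_id, metric = metric,
                                             value = value,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    ct <- vals(cs$ct)
    body <- as_mask_matrix(cs$masks$body)
    sp <- if (inherits(cs$masks$body, "contour_mask")) cs$masks$body$spacing
          else c(1, 1)
    for (nm in intersect(c("cbct", "sct"), names(cs))) {
      img <- vals(cs[[nm]])
      add(i, paste0("mae_", nm), mae(img, ct, body))
      add(i, paste0("rmse_", nm), rmse(img, ct, body))
      add(i, paste0("psnr_", nm), psnr(img, ct, body, max_p))
    }
    if (!is.null(cs$masks_pred)) {
      for (org in names(cs$masks_pred)) {
        add(i, paste0("dsc_", org), dsc(cs$masks[[org]], cs$masks_pred[[org]]))
        add(i, paste0("mda_", org), mda(cs$masks[[org]], cs$masks_pred[[org]],
                                        spacing = sp))
      }
    }
    if (!is.null(cs$dose_ref) && !is.null(cs$dose_test)) {
      gr <- gamma_index(cs$dose_ref, cs$dose_test, gamma_cfg)
      add(i, "gamma_pass", gr$pass_rate)
    }
  }
  per_case <- do.call(rbind, rows)
  ag <- split(per_case$value, per_case$metric)
  summary <- data.frame(
    metric = names(ag),
    mean = vapply(ag, mean, numeric(1)),
    sd = vapply(ag, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                numeric(1)),
    n = vapply(ag, length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_case = per_case, summary = summary)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report result of [evaluation_report()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "per_case.csv")
  p2 <- file.path(dir, "summary.csv")
  p3 <- file.path(dir, "summary.json")
  utils::write.csv(report$per_case, p1, row.names = FALSE)
  utils::write.csv(report$summary, p2, row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(report$summary$mean), report$summary$metric),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
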