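# NIfTI volume I/O and YAML run configuration.
#
# Axis convention: arrays are (row, column, slice); a 2D slice is stored as a
# single-slice 3D volume and can be read back as 2D on request. Spacing is
# mm per axis in the same order.

#' Read a NIfTI volume
#'
#' @param path .nii or .nii.gz file.
#' @param drop return a 2D matrix when the volume has a single slice.
#' @return list with \code{values} (array) and \code{spacing} (mm per axis).
#' @export
read_volume <- function(path, drop = FALSE) {
  if (!file.exists(path)) stop("no such volume: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read volume ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  values <- as.array(img)
  spacing <- as.numeric(RNifti::pixdim(img))
  d <- dim(values)
  if (length(d) == 2L) d <- c(d, 1L)                 # single-slice volume
  values <- array(as.numeric(values), dim = d)       # strip NIfTI attributes
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3L - length(spacing)))
  if (drop && d[3] == 1L) {
    values <- values[, , 1L]
    spacing <- spacing[1:2]
  }
  list(values = values, spacing = spacing)
}

#' Write a NIfTI volume
#'
#' Round-trips values (within float storage) and spacing with
#' [read_volume()].
#'
#' @param values numeric array; a matrix is stored as a single-slice 3D
#'   volume.
#' @param path output .nii or .nii.gz file.
#' @param spacing mm per axis.
#' @return invisibly, the path.
#' @export
write_volume <- function(values, path, spacing = NULL) {
  if (is.null(spacing)) spacing <- attr(values, "spacing")
  if (is.null(spacing)) spacing <- rep(1, 3)
  attr(values, "spacing") <- NULL
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(spacing) < length(dim(values)))
    spacing <- c(spacing, rep(1, length(dim(values)) - length(spacing)))
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing[seq_along(dim(values))]
  ok <- tryCatch({
    RNifti::writeNifti(img, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("cannot write volume: ", path, call. = FALSE)
  invisible(path)
}

config_sections <- c("phantom", "artifacts", "network", "loss", "train",
                     "gamma", "run")

section_builder <- function(section) {
  switch(section,
         phantom = phantom_config, artifacts = artifact_params,
         network = network_config, loss = loss_config,
         train = train_config, gamma = gamma_config,
         run = function(...) list(...))
}

#' Read a run configuration from YAML
#'
#' The file may contain the sections \code{phantom}, \code{artifacts},
#' \code{network}, \code{loss}, \code{train}, \code{gamma} and \code{run}
#' (free-form paths/counts); unknown sections or fields are rejected.
#' Omitted sections resolve to package defaults. CLI overrides take the
#' form \code{section.field}.
#'
#' @param path YAML file, or NULL for all defaults.
#' @param overrides named list of \code{section.field} overrides.
#' @return named list of resolved configuration objects.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(raw), config_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% config_sections)
      stop("override must be section.field: ", nm, call. = FALSE)
    raw[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  out <- list()
  for (section in config_sections) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    builder <- section_builder(section)
    if (section != "run") {
      known <- names(formals(builder))
      bad <- setdiff(names(args), known)
      if (length(bad))
        stop(sprintf("unknown field(s) in '%s': %s", section,
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
    out[[section]] <- do.call(builder, args)
  }
  out
}

#' Write the fully resolved configuration next to a run's outputs
#'
#' @param cfg resolved config list from [read_run_config()].
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
write_resolved_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) lapply(unclass(x), function(v) {
    if (is.null(v)) NULL else if (is.numeric(v) || is.character(v) ||
                                  is.logical(v)) v else unclass(v)
  }))
  yaml::write_yaml(plain, path)
  invisible(path)
}
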