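#' Phase preparation inputs for real acquisitions
#'
#' Container for the quantities needed to turn raw echo phases into tissue
#' phase: wrapped per-echo phases, spatially unwrapped total and background
#' fields, and the initial (t = 0) phase. Field units must be declared:
#' `"rad_per_s"` or `"hz"` (converted to rad/s internally).
#'
#' @param wrapped_phase 4D (x, y, z, echo) wrapped phase, radians.
#' @param fT_uw 3D unwrapped total field.
#' @param fB_uw 3D unwrapped background field (same unit as `fT_uw`).
#' @param phi0 Initial phase, radians (3D map or scalar).
#' @param echo_times Echo times, seconds.
#' @param field_unit `"rad_per_s"` or `"hz"`.
#' @return Object of class `phase_field_inputs`.
#' @export
phase_field_inputs <- function(wrapped_phase, fT_uw, fB_uw, phi0 = 0,
                               echo_times,
                               field_unit = c("rad_per_s", "hz")) {
  field_unit <- match.arg(field_unit)
  if (length(dim(wrapped_phase)) != 4L) stop("wrapped_phase must be 4D")
  if (dim(wrapped_phase)[4] != length(echo_times))
    stop("echo count mismatch between phase data and echo_times")
  gs <- dim(wrapped_phase)[1:3]
  for (f in list(fT_uw, fB_uw))
    if (!identical(dim(f), gs)) stop("field maps must match the phase grid")
  structure(list(wrapped_phase = wrapped_phase, fT_uw = fT_uw, fB_uw = fB_uw,
                 phi0 = phi0, echo_times = echo_times,
                 field_unit = field_unit),
            class = "phase_field_inputs")
}

#' Tissue phase from wrapped echo phases
#'
#' Unwraps each echo phase against the unwrapped total field,
#' `phase_uw = phase - round((phase - fT t - phi0) / 2pi) * 2pi`, then
#' removes the background-field and initial-phase contributions:
#' `phi' = phase_uw - fB t - phi0`. Adding any multiple of 2 pi to the
#' wrapped input leaves the result unchanged.
#'
#' @param inputs A [phase_field_inputs()].
#' @return 4D (x, y, z, echo) tissue phase, radians.
#' @export
compensate_phase <- function(inputs) {
  stopifnot(inherits(inputs, "phase_field_inputs"))
  conv <- if (inputs$field_unit == "hz") 2 * pi else 1
  fT <- inputs$fT_uw * conv
  fB <- inputs$fB_uw * conv
  out <- inputs$wrapped_phase
  for (j in seq_along(inputs$echo_times)) {
    tj <- inputs$echo_times[j]
    ps <- inputs$wrapped_phase[, , , j]
    uw <- ps - round((ps - fT * tj - inputs$phi0) / (2 * pi)) * 2 * pi
    out[, , , j] <- uw - fB * tj - inputs$phi0
  }
  if (any(!is.finite(out))) stop("non-finite tissue phase")
  out
}

#' Macroscopic-field magnitude compensation
#'
#' `|S'| = |s| / G` element-wise, inverting the macroscopic attenuation of
#' the measured magnitudes.
#'
#' @param magnitudes Magnitude array.
#' @param G Attenuation factor in (0, 1]: scalar or array of matching shape.
#' @return Compensated magnitudes.
#' @export
compensate_magnitude <- function(magnitudes, G) {
  if (any(G <= 0)) stop("G must be positive")
  if (any(G > 1)) stop("G must be <= 1")
  if (length(G) != 1L && !identical(dim(G), dim(magnitudes)))
    stop("G shape does not match magnitudes")
  magnitudes / G
}

# NIfTI helpers ----------------------------------------------------------

write_nii <- function(arr, path, voxel_size) {
  im <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- c(voxel_size, rep(1, nd - 3))[seq_len(nd)]
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

read_nii <- function(path) {
  im <- RNifti::readNifti(path)
  a <- array(as.numeric(im), dim(im))
  attr(a, "pixdim") <- RNifti::pixdim(im)
  a
}

#' Write / read a complex signal stack as NIfTI
#'
#' Complex 4D data are stored as two co-registered 4D NIfTI volumes (echo
#' along the 4th dimension) in one of two dialects -- paired
#' magnitude/phase (`"magphase"`, the clinical-export convention, default)
#' or real/imaginary (`"realimag"`) -- plus a JSON sidecar recording the
#' dialect and acquisition metadata. Both dialects load to identical
#' complex stacks.
#'
#' @param signal A [signal_stack()].
#' @param prefix Output path prefix; files `<prefix>_<part>.nii` and
#'   `<prefix>.json` are produced.
#' @param dialect `"magphase"` or `"realimag"`.
#' @return `write_signal_stack()`: the sidecar path, invisibly;
#'   `read_signal_stack()`: a [signal_stack()].
#' @export
write_signal_stack <- function(signal, prefix,
                               dialect = c("magphase", "realimag")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(signal, "signal_stack"))
  acq <- signal$acq
  parts <- if (dialect == "magphase") {
    list(mag = abs(signal$data), phase = Arg(signal$data))
  } else {
    list(real = Re(signal$data), imag = Im(signal$data))
  }
  for (nm in names(parts))
    write_nii(parts[[nm]], paste0(prefix, "_", nm, ".nii"), acq$voxel_size)
  side <- list(dialect = dialect, echo_times = acq$echo_times, B0 = acq$B0,
               B0_dir = acq$B0_dir, voxel_size = acq$voxel_size,
               grid_shape = dim(signal$data)[1:3])
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_signal_stack
#' @export
read_signal_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nms <- if (side$dialect == "magphase") c("mag", "phase") else
    c("real", "imag")
  a <- read_nii(paste0(prefix, "_", nms[1], ".nii"))
  b <- read_nii(paste0(prefix, "_", nms[2], ".nii"))
  attr(a, "pixdim") <- NULL
  attr(b, "pixdim") <- NULL
  if (!identical(dim(a), dim(b))) stop("inconsistent geometry across parts")
  if (dim(a)[4] != length(side$echo_times))
    stop("echo count mismatch between data and sidecar")
  data <- if (side$dialect == "magphase") {
    a * exp(1i * b)
  } else {
    a + 1i * b
  }
  acq <- acq_params(echo_times = side$echo_times, B0 = side$B0,
                    B0_dir = side$B0_dir, voxel_size = side$voxel_size,
                    grid_shape = dim(a)[1:3])
  signal_stack(data, acq)
}

#' Write / read parameter maps as NIfTI
#'
#' One 3D NIfTI file per parameter map plus the mask, under a common prefix.
#'
#' @param params A [parameter_maps()].
#' @param prefix Output path prefix.
#' @param voxel_size Voxel size, mm.
#' @return `write_parameter_maps()`: invisibly, the written paths;
#'   `read_parameter_maps()`: a [parameter_maps()].
#' @export
write_parameter_maps <- function(params, prefix, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(params, "parameter_maps"))
  paths <- character(0)
  for (nm in c(param_names, "mask")) {
    p <- paste0(prefix, "_", nm, ".nii")
    write_nii(params[[nm]] + 0, p, voxel_size)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_parameter_maps
#' @export
read_parameter_maps <- function(prefix) {
  m <- lapply(c(param_names, "mask"), function(nm) {
    a <- read_nii(paste0(prefix, "_", nm, ".nii"))
    attr(a, "pixdim") <- NULL
    a
  })
  names(m) <- c(param_names, "mask")
  parameter_maps(m$S0, m$R2, m$Y, m$v, m$chi_n, m$mask > 0.5)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @param config Named list of run settings.
#' @return `read_run_config()`: the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

log_stage <- function(stage, ...) {
  info <- paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                collapse = " ")
  message(sprintf("[qsmqbold] %s %s", stage, info))
}
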