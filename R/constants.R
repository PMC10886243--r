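#' Physiological and physical constants of the QSM+qBOLD model
#'
#' Bundle of the fixed constants that parameterize the characteristic
#' dephasing frequency and the blood susceptibility mixture. Defaults are the
#' standard literature values used for OEF mapping at 3T with tissue
#' hematocrit 0.357.
#'
#' @param gamma Gyromagnetic ratio of the proton, rad s^-1 T^-1.
#' @param psi_Hb Hemoglobin volume fraction (dimensionless; 0.0909 at
#'   Hct = 0.357).
#' @param dchi_Hb Susceptibility difference between deoxy- and oxyhemoglobin,
#'   ppb.
#' @param chi_ba Susceptibility of fully oxygenated blood, ppb.
#' @param Hct Tissue hematocrit (dimensionless).
#' @param alpha Ratio of venous to total blood volume (dimensionless).
#' @param Ya Arterial oxygen saturation (fraction).
#' @return An object of class `physio_constants`.
#' @export
#' @examples
#' pc <- physio_constants()
#' pc$alpha
physio_constants <- function(gamma = 267.51e6,
                             psi_Hb = 0.0909,
                             dchi_Hb = 12522,
                             chi_ba = -108.3,
                             Hct = 0.357,
                             alpha = 0.77,
                             Ya = 0.98) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (!(Ya > 0 && Ya <= 1)) stop("Ya must be in (0, 1]")
  if (!(psi_Hb > 0)) stop("psi_Hb must be positive")
  if (!(dchi_Hb > 0)) stop("dchi_Hb must be positive")
  structure(list(gamma = gamma, psi_Hb = psi_Hb, dchi_Hb = dchi_Hb,
                 chi_ba = chi_ba, Hct = Hct, alpha = alpha, Ya = Ya),
            class = "physio_constants")
}

#' Acquisition parameters of a multi-echo gradient-echo protocol
#'
#' Echo times, static field and grid geometry. The default echo set is the
#' 8-echo protocol TE1/dTE/TE8 = 4.5/5/39.5 ms at 3T. `omega0` (the Larmor
#' angular frequency, rad/s) is derived as `gamma * B0`.
#'
#' @param echo_times Echo times in seconds, strictly increasing, positive.
#' @param B0 Main field strength, Tesla.
#' @param B0_dir Unit 3-vector of the main field direction in the voxel frame.
#' @param voxel_size Voxel edge lengths, mm (length-3).
#' @param grid_shape Integer length-3 grid dimensions.
#' @param gamma Gyromagnetic ratio used to derive `omega0`.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(echo_times = seq(4.5e-3, by = 5e-3, length.out = 8),
                       B0 = 3,
                       B0_dir = c(0, 0, 1),
                       voxel_size = c(2, 2, 2),
                       grid_shape = c(48L, 48L, 48L),
                       gamma = 267.51e6) {
  stopifnot(length(echo_times) >= 1L, all(is.finite(echo_times)))
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo_times must be positive and strictly increasing")
  stopifnot(length(B0_dir) == 3L, all(is.finite(B0_dir)))
  nb <- sqrt(sum(B0_dir^2))
  if (abs(nb - 1) > 1e-8) stop("B0_dir must be a unit vector")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0),
            length(grid_shape) == 3L, all(grid_shape >= 2))
  structure(list(echo_times = as.numeric(echo_times), B0 = B0,
                 B0_dir = B0_dir / nb, voxel_size = as.numeric(voxel_size),
                 grid_shape = as.integer(grid_shape),
                 omega0 = gamma * B0),
            class = "acq_params")
}

#' Co-registered parameter maps of the signal model
#'
#' The five voxel-wise unknowns of the model -- `S0` (signal at t = 0), `R2`
#' (transverse relaxation rate, 1/s), `Y` (venous oxygen saturation,
#' fraction), `v` (venous blood volume fraction) and `chi_n` (non-blood
#' neural tissue susceptibility, ppb) -- plus the brain mask, all on one 3D
#' grid. Voxels outside the mask are zero-filled so that the dipole
#' convolution is well posed.
#'
#' @param S0,R2,Y,v,chi_n 3D numeric arrays of identical dimension.
#' @param mask 3D logical (or 0/1) array of the same dimension.
#' @param alpha Venous-to-total blood volume ratio used to validate `v`.
#' @return An object of class `parameter_maps` (a list of the zero-filled
#'   maps and the logical mask).
#' @export
parameter_maps <- function(S0, R2, Y, v, chi_n, mask,
                           alpha = physio_constants()$alpha) {
  dm <- dim(S0)
  if (is.null(dm) || length(dm) != 3L) stop("maps must be 3D arrays")
  for (m in list(R2, Y, v, chi_n, mask))
    if (!identical(dim(m), dm)) stop("all maps must share one grid shape")
  mask <- array(as.logical(mask), dm)
  zf <- function(x) { x[!mask] <- 0; x[] <- as.numeric(x); x }
  S0 <- zf(S0); R2 <- zf(R2); Y <- zf(Y); v <- zf(v); chi_n <- zf(chi_n)
  inm <- which(mask)
  if (length(inm)) {
    if (any(!is.finite(S0[inm])) || any(!is.finite(R2[inm])) ||
        any(!is.finite(Y[inm])) || any(!is.finite(v[inm])) ||
        any(!is.finite(chi_n[inm]))) stop("non-finite values inside mask")
    if (any(Y[inm] < 0 | Y[inm] > 1)) stop("Y must lie in [0, 1]")
    if (any(v[inm] < 0 | v[inm] >= alpha))
      stop("v must lie in [0, alpha)")
    if (any(S0[inm] < 0)) stop("S0 must be non-negative")
    if (any(R2[inm] < 0)) stop("R2 must be non-negative")
  }
  structure(list(S0 = S0, R2 = R2, Y = Y, v = v, chi_n = chi_n, mask = mask),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  dm <- dim(x$S0)
  cat(sprintf("<parameter_maps> grid %dx%dx%d, %d voxels in mask\n",
              dm[1], dm[2], dm[3], sum(x$mask)))
  invisible(x)
}

#' Echo-indexed complex signal stack
#'
#' @param data Complex 4D array, dimensions (x, y, z, echo).
#' @param acq The [acq_params()] the stack was simulated/acquired with.
#' @return Object of class `signal_stack`.
#' @export
signal_stack <- function(data, acq) {
  dm <- dim(data)
  if (is.null(dm) || length(dm) != 4L) stop("data must be a 4D array")
  if (!inherits(acq, "acq_params")) stop("acq must be acq_params")
  if (dm[4] != length(acq$echo_times))
    stop("echo dimension must equal length(echo_times)")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("signal values must be finite")
  structure(list(data = data, acq = acq), class = "signal_stack")
}

#' @export
print.signal_stack <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<signal_stack> grid %dx%dx%d, %d echoes\n",
              dm[1], dm[2], dm[3], dm[4]))
  invisible(x)
}

# Validate a macroscopic-field attenuation factor G against a signal grid.
# G may be NULL (taken as 1 everywhere), a scalar, or a 4D (x,y,z,echo) array.
check_G <- function(G, grid_shape, n_echo) {
  if (is.null(G)) return(NULL)
  if (length(G) == 1L) {
    if (!is.finite(G) || G <= 0 || G > 1) stop("G must lie in (0, 1]")
    return(as.numeric(G))
  }
  dm <- dim(G)
  if (is.null(dm) || length(dm) != 4L ||
      !all(dm == c(grid_shape, n_echo)))
    stop("G must be scalar or a 4D (x, y, z, echo) array matching the grid")
  if (any(G <= 0 | G > 1)) stop("G must lie in (0, 1]")
  G
}
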