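#' k-space dipole kernel
#'
#' The unit magnetic dipole response in the Fourier domain,
#' `D(k) = 1/3 - (k . b)^2 / |k|^2`, on the discrete FFT frequency grid of a
#' given 3D volume, with the singular DC term set to 0 (which makes a
#' spatially uniform susceptibility produce zero field). `b` is the unit
#' main-field direction. Values lie in `[-2/3, 1/3]`.
#'
#' @param grid_shape Integer length-3 grid dimensions (each >= 2).
#' @param voxel_size Voxel size in mm (length-3, positive); enters through
#'   the physical spatial frequencies.
#' @param B0_dir Unit 3-vector main-field direction.
#' @return Real 3D array of kernel values (unshifted FFT layout).
#' @export
dipole_kernel <- function(grid_shape, voxel_size = c(1, 1, 1),
                          B0_dir = c(0, 0, 1)) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2))
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  nb <- sqrt(sum(B0_dir^2))
  if (!isTRUE(all.equal(nb, 1, tolerance = 1e-6)))
    stop("B0_dir must be a unit vector")
  b <- B0_dir / nb
  fftfreq <- function(n, d) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * d)
    k
  }
  kx <- fftfreq(grid_shape[1], voxel_size[1])
  ky <- fftfreq(grid_shape[2], voxel_size[2])
  kz <- fftfreq(grid_shape[3], voxel_size[3])
  KX <- array(kx, grid_shape)
  KY <- array(rep(ky, each = grid_shape[1]), grid_shape)
  KZ <- array(rep(kz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b[1] + KY * b[2] + KZ * b[3]
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Tissue field induced by a susceptibility distribution
#'
#' Circular (periodic) dipole convolution `d * chi` computed in k-space as
#' `IFFT(D . FFT(chi))`. Input and output are in ppb; conversion to radians
#' happens only in the phase term of the signal model. Because `D(0) = 0` a
#' uniform susceptibility yields an identically zero field. Sources should be
#' kept away from the volume boundary (the phantom generator leaves a >= 25%
#' zero margin) to suppress wrap-around.
#'
#' @param chi Real 3D array of susceptibility values, ppb, zero outside the
#'   object.
#' @param kernel Kernel from [dipole_kernel()] on the same grid.
#' @return Real 3D field map, ppb.
#' @export
field_from_chi <- function(chi, kernel) {
  if (!identical(dim(chi), dim(kernel)))
    stop("chi and kernel grids do not match")
  Re(stats::fft(stats::fft(chi) * kernel, inverse = TRUE)) / length(chi)
}

#' Forward complex signal model
#'
#' Simulates the echo-indexed complex mGRE signal
#'
#'   S_j = F_qBOLD(S0, R2, Y, v, chi_n, t_j) * exp(i omega0 t_j (d * chi)),
#'
#' where `chi = chi_qsm(Y, v, chi_n)` and `d *` is the dipole convolution.
#' The magnitude equals the qBOLD model and the phase grows linearly with
#' echo time at every voxel.
#'
#' @inheritParams f_qbold
#' @return A [signal_stack()].
#' @export
simulate_signal <- function(params, acq, consts = physio_constants(),
                            G = NULL) {
  fw <- model_forward(params, acq, consts, G)
  signal_stack(fw$signal, acq)
}

# Shared forward evaluation returning all intermediates needed by gradients.
model_forward <- function(params, acq, consts, G = NULL) {
  dm <- dim(params$S0)
  te <- acq$echo_times
  ne <- length(te)
  G <- check_G(G, dm, ne)
  dw <- delta_omega(params$Y, params$chi_n, consts, acq$B0)
  chi <- chi_qsm(params$Y, params$v, params$chi_n, consts)
  chi[!params$mask] <- 0
  D <- dipole_kernel(dm, acq$voxel_size, acq$B0_dir)
  field <- field_from_chi(chi, D)
  x <- array(0, c(dm, ne)); fsx <- x; E <- x; phi <- x
  signal <- array(0i, c(dm, ne)); A <- x
  for (j in seq_len(ne)) {
    xj <- dw * te[j]
    fj <- fs(xj)
    Ej <- exp(-params$R2 * te[j]) * exp(-params$v * fj)
    if (!is.null(G))
      Ej <- Ej * (if (length(G) == 1L) G else G[, , , j])
    Aj <- params$S0 * Ej
    pj <- acq$omega0 * te[j] * field * 1e-9
    x[, , , j] <- xj; fsx[, , , j] <- fj; E[, , , j] <- Ej
    A[, , , j] <- Aj; phi[, , , j] <- pj
    signal[, , , j] <- Aj * exp(1i * pj)
  }
  list(signal = signal, A = A, E = E, phi = phi, x = x, fsx = fsx,
       field = field, chi = chi, kernel = D, dw = dw)
}

# Vector-Jacobian product of the forward model.
#
# Given a complex cotangent R (4D, echo-indexed) such that a scalar loss
# satisfies dL = sum_j Re(Conj(R_j) dS_j), returns the real gradients of L
# with respect to the five parameter maps. The dipole convolution is
# self-adjoint in k-space (real, even kernel), so the field pathway is pulled
# back with the same convolution.
model_gradient <- function(fw, params, acq, consts, R) {
  te <- acq$echo_times
  ne <- length(te)
  a_ <- consts$alpha
  Cdw <- (1 / 3) * consts$gamma * acq$B0 * 1e-9  # d(delta_omega)/d(ppb term)
  pdc <- consts$psi_Hb * consts$dchi_Hb
  gS0 <- 0; gR2 <- 0; gY <- 0; gv <- 0; gchi_n <- 0
  bsum <- 0
  for (j in seq_len(ne)) {
    Rj <- R[, , , j]
    eip <- exp(1i * fw$phi[, , , j])
    aj <- Re(Conj(Rj) * eip)
    bj <- -Im(Conj(Rj) * fw$signal[, , , j])
    Aj <- fw$A[, , , j]
    fsd <- fs_deriv(fw$x[, , , j])
    gS0 <- gS0 + aj * fw$E[, , , j]
    gR2 <- gR2 - aj * te[j] * Aj
    gv  <- gv  - aj * fw$fsx[, , , j] * Aj
    gY  <- gY  + aj * params$v * fsd * (Cdw * pdc * te[j]) * Aj
    gchi_n <- gchi_n + aj * params$v * fsd * (Cdw * te[j]) * Aj
    bsum <- bsum + bj * (acq$omega0 * te[j] * 1e-9)
  }
  gchi <- field_from_chi(bsum, fw$kernel)  # adjoint of the convolution
  blood <- consts$chi_ba / a_ + pdc * (-params$Y + 1 - (1 - a_) * consts$Ya) / a_
  gv <- gv + gchi * (blood - params$chi_n / a_)
  gY <- gY + gchi * (-params$v * pdc / a_)
  gchi_n <- gchi_n + gchi * (1 - params$v / a_)
  msk <- !params$mask
  for (nm in c("gS0", "gR2", "gY", "gv", "gchi_n")) {
    g <- get(nm); g[msk] <- 0; assign(nm, g)
  }
  list(S0 = gS0, R2 = gR2, Y = gY, v = gv, chi_n = gchi_n)
}
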