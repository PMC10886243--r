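#' Characteristic dephasing frequency of deoxygenated blood
#'
#' Angular frequency offset between deoxygenated venous blood and the
#' surrounding tissue in the static dephasing regime,
#'
#'   delta_omega = (1/3) gamma B0 (psi_Hb dchi_Hb (1 - Y) + chi_ba - chi_n),
#'
#' with susceptibilities in ppb (the 1e-9 conversion is applied here, and
#' only here, on the magnitude pathway).
#'
#' @param Y Venous oxygen saturation (fraction), scalar or array.
#' @param chi_n Non-blood tissue susceptibility, ppb, scalar or array.
#' @param consts [physio_constants()].
#' @param B0 Field strength, Tesla.
#' @return Angular frequency in rad/s, same shape as the broadcast inputs.
#'   May be negative when `chi_n` exceeds the blood term.
#' @export
#' @examples
#' delta_omega(0.98, 0, physio_constants(), 3)   # ~ -22.9 rad/s
delta_omega <- function(Y, chi_n, consts = physio_constants(), B0 = 3) {
  if (any(!is.finite(Y)) || any(!is.finite(chi_n)))
    stop("delta_omega inputs must be finite")
  if (any(Y < 0 | Y > 1)) stop("Y must lie in [0, 1]")
  (1 / 3) * consts$gamma * B0 * 1e-9 *
    (consts$psi_Hb * consts$dchi_Hb * (1 - Y) + consts$chi_ba - chi_n)
}

#' Mesoscopic (blood-network) magnitude attenuation
#'
#' `F_BOLD(Y, v, chi_n, t) = exp(-v * fs(delta_omega * t))`: the decay of the
#' mGRE magnitude caused by the field of deoxygenated blood in randomly
#' oriented vessels occupying a volume fraction `v`.
#'
#' @param Y,chi_n,consts,B0 As in [delta_omega()].
#' @param v Venous blood volume fraction, in `[0, 1)`.
#' @param t Time (echo time), seconds, `>= 0`.
#' @return Attenuation in (0, 1]; 1 when `v = 0` or `t = 0`.
#' @export
f_bold <- function(Y, v, chi_n, t, consts = physio_constants(), B0 = 3) {
  if (any(v < 0)) stop("v must be non-negative")
  if (any(t < 0)) stop("t must be non-negative")
  dw <- delta_omega(Y, chi_n, consts, B0)
  exp(-v * fs(dw * t))
}

#' qBOLD magnitude model
#'
#' Per-echo magnitude `S0 * exp(-R2 * t) * F_BOLD * G(t)` evaluated on the
#' full parameter maps. `R2` is interpreted as a rate in 1/s (no 2*pi).
#'
#' @param params [parameter_maps()].
#' @param acq [acq_params()].
#' @param consts [physio_constants()].
#' @param G Macroscopic-field attenuation: `NULL` (1 everywhere), a scalar in
#'   (0, 1], or a 4D (x, y, z, echo) array.
#' @param echo Optional single echo index; if `NULL` all echoes are returned
#'   as a 4D array.
#' @return Magnitude map (3D for one echo, 4D for all echoes).
#' @export
f_qbold <- function(params, acq, consts = physio_constants(), G = NULL,
                    echo = NULL) {
  stopifnot(inherits(params, "parameter_maps"), inherits(acq, "acq_params"))
  dm <- dim(params$S0)
  te <- acq$echo_times
  G <- check_G(G, dm, length(te))
  js <- if (is.null(echo)) seq_along(te) else {
    if (echo < 1 || echo > length(te)) stop("echo index out of range")
    as.integer(echo)
  }
  dw <- delta_omega(params$Y, params$chi_n, consts, acq$B0)
  out <- array(0, c(dm, length(js)))
  for (k in seq_along(js)) {
    j <- js[k]
    m <- params$S0 * exp(-params$R2 * te[j]) * exp(-params$v * fs(dw * te[j]))
    if (!is.null(G))
      m <- m * (if (length(G) == 1L) G else G[, , , j])
    out[, , , k] <- m
  }
  if (!is.null(echo)) array(out, dm) else out
}

#' Voxel-wise susceptibility of the blood/tissue mixture
#'
#' Susceptibility (ppb) of a voxel containing venous blood of volume fraction
#' `v` and saturation `Y` inside non-blood tissue of susceptibility `chi_n`:
#'
#'   chi = v * [chi_ba/alpha + psi_Hb dchi_Hb (-Y + 1 - (1-alpha) Ya)/alpha]
#'         + (1 - v/alpha) * chi_n
#'
#' `chi_qsm_mixture()` is an independent cross-check built from the explicit
#' volume-weighted three-compartment mixture (venous blood `v`, arterial
#' blood `v(1-alpha)/alpha`, tissue `1 - v/alpha`); the two forms differ in
#' the saturation weighting (see the methods vignette) and the first is the
#' model used throughout the package.
#'
#' @param Y Venous saturation (fraction).
#' @param v Venous blood volume fraction, in `[0, alpha)`.
#' @param chi_n Tissue susceptibility, ppb.
#' @param consts [physio_constants()].
#' @return Susceptibility in ppb, linear in `v` and in `chi_n` separately.
#' @export
chi_qsm <- function(Y, v, chi_n, consts = physio_constants()) {
  a <- consts$alpha
  if (any(v < 0 | v >= a)) stop("v must lie in [0, alpha)")
  blood <- consts$chi_ba / a +
    consts$psi_Hb * consts$dchi_Hb * (-Y + 1 - (1 - a) * consts$Ya) / a
  v * blood + (1 - v / a) * chi_n
}

#' @rdname chi_qsm
#' @export
chi_qsm_mixture <- function(Y, v, chi_n, consts = physio_constants()) {
  a <- consts$alpha
  if (any(v < 0 | v >= a)) stop("v must lie in [0, alpha)")
  chi_v <- consts$chi_ba + consts$psi_Hb * consts$dchi_Hb * (1 - Y)
  chi_a <- consts$chi_ba + consts$psi_Hb * consts$dchi_Hb * (1 - consts$Ya)
  v * chi_v + v * (1 - a) / a * chi_a + (1 - v / a) * chi_n
}

#' Oxygen extraction fraction from venous saturation
#'
#' `OEF = 1 - Y / Ya`. Values `Y > Ya` are permitted (negative OEF) but a
#' warning is raised, since they are unphysiological.
#'
#' @param Y Venous saturation (fraction), scalar or array.
#' @param Ya Arterial saturation (fraction), nonzero.
#' @return OEF as a fraction, same shape as `Y`.
#' @export
#' @examples
#' oef_from_Y(0.67)  # ~ 0.3163
oef_from_Y <- function(Y, Ya = physio_constants()$Ya) {
  if (length(Ya) != 1L || !is.finite(Ya) || Ya == 0)
    stop("Ya must be a nonzero scalar")
  if (any(Y > Ya)) warning("Y exceeds Ya at some voxels; OEF is negative there")
  1 - Y / Ya
}
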