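#' Configuration of the synthetic stroke-brain phantom
#'
#' Defines the geometry, per-parameter statistics and lesion of the phantom
#' generator. The default `tissue_stats` are the whole-cohort statistics
#' (mean, SD, min, max) of stroke-patient parameter maps that the training
#' data emulate: S0 (1.10, 0.04, 1.04, 2.12), R2 (19.6, 7.1, 7.3, 161.1 1/s),
#' Y (0.67, 0.10, 0.31, 0.98), v (0.023, 0.012, 0.003, 0.072) and chi_n
#' (-11.6, 37.5, -957.2, 159.7 ppb).
#'
#' @param grid_shape Integer length-3 grid.
#' @param voxel_size Voxel size, mm.
#' @param seed Integer seed; the clean phantom depends only on this seed.
#' @param lesion List with `center` (mm, relative to volume center; `NULL`
#'   places it mid-hemisphere), `radii` (mm, `NULL` scales to the brain),
#'   `Y_scale` and `v_scale` multipliers applied inside the lesion.
#' @param tissue_stats Named list of `c(mean, sd, min, max)` per parameter.
#' @param smoothness Spatial correlation length (Gaussian kernel SD), mm.
#' @param brain_axes_frac Brain ellipsoid semi-axes as fractions of the grid
#'   extent; defaults keep a >= 25% zero margin for the periodic dipole
#'   convolution.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           voxel_size = c(2, 2, 2),
                           seed = 1L,
                           lesion = list(center = NULL, radii = NULL,
                                         Y_scale = 0.6, v_scale = 0.5),
                           tissue_stats = list(
                             S0    = c(1.10, 0.04, 1.04, 2.12),
                             R2    = c(19.6, 7.1, 7.3, 161.1),
                             Y     = c(0.67, 0.10, 0.31, 0.98),
                             v     = c(0.023, 0.012, 0.003, 0.072),
                             chi_n = c(-11.6, 37.5, -957.2, 159.7)),
                           smoothness = 6,
                           brain_axes_frac = c(0.36, 0.34, 0.30)) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(voxel_size) == 3L, all(voxel_size > 0),
            smoothness > 0)
  for (nm in c("S0", "R2", "Y", "v", "chi_n")) {
    s <- tissue_stats[[nm]]
    if (is.null(s) || length(s) != 4L)
      stop("tissue_stats must give c(mean, sd, min, max) for ", nm)
    if (!(s[3] <= s[1] && s[1] <= s[4]))
      stop("tissue_stats for ", nm, " must satisfy min <= mean <= max")
    if (s[2] <= 0) stop("tissue_stats sd must be positive for ", nm)
  }
  les <- utils::modifyList(list(center = NULL, radii = NULL,
                                Y_scale = 0.6, v_scale = 0.5), lesion)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 seed = as.integer(seed), lesion = les,
                 tissue_stats = tissue_stats, smoothness = smoothness,
                 brain_axes_frac = brain_axes_frac),
            class = "phantom_config")
}

# Evaluate code with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Ellipsoid indicator on the voxel grid. center in voxel units (may be
# fractional), semi in voxel units per axis.
ellipsoid_mask <- function(grid_shape, center, semi) {
  ix <- seq_len(grid_shape[1]); iy <- seq_len(grid_shape[2])
  iz <- seq_len(grid_shape[3])
  X <- array(ix, grid_shape)
  Y <- array(rep(iy, each = grid_shape[1]), grid_shape)
  Z <- array(rep(iz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

# Smooth standardized Gaussian random field: white noise convolved with a
# periodic Gaussian kernel (SD sigma_mm), then standardized to mean 0 / SD 1
# over the mask voxels.
smooth_grf <- function(grid_shape, voxel_size, sigma_mm, mask) {
  w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  g1 <- function(n, d) {
    x <- (0:(n - 1)); x <- pmin(x, n - x) * d
    k <- exp(-x^2 / (2 * sigma_mm^2)); k / sum(k)
  }
  kx <- g1(grid_shape[1], voxel_size[1])
  ky <- g1(grid_shape[2], voxel_size[2])
  kz <- g1(grid_shape[3], voxel_size[3])
  K <- outer(outer(kx, ky), kz)
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) /
    length(w)
  mv <- sm[mask]
  (sm - mean(mv)) / stats::sd(mv)
}

# Affine-transform a standardized field so that, after hard clipping to
# [lo, hi] and any lesion scaling, the masked sample mean/SD match the
# targets (the cohort statistics describe whole brains, lesions included).
# Iterative re-centering compensates the truncation bias.
calibrate_clipped <- function(g, mask, target, lesion = NULL, scale = 1,
                              n_iter = 60L, tol = 1e-4) {
  tmean <- target[1]; tsd <- target[2]; lo <- target[3]; hi <- target[4]
  mu <- tmean; sig <- tsd
  gm <- g[mask]
  les <- if (is.null(lesion) || scale == 1) NULL else lesion[mask]
  realize <- function() {
    x <- pmin(pmax(mu + sig * gm, lo), hi)
    if (!is.null(les)) x[les] <- pmin(pmax(x[les] * scale, lo), hi)
    x
  }
  for (it in seq_len(n_iter)) {
    x <- realize()
    m <- mean(x); s <- stats::sd(x)
    if (abs(m - tmean) < tol * max(abs(tmean), 1e-12) &&
        abs(s - tsd) < tol * tsd) break
    mu <- mu + (tmean - m)
    if (s > 0) sig <- sig * min(max(tsd / s, 0.5), 2)
  }
  out <- array(0, dim(g))
  out[mask] <- realize()
  out
}

#' Generate a synthetic stroke-brain phantom
#'
#' Builds an ellipsoidal brain with spatially smooth, clipped Gaussian
#' random fields for the five model parameters whose masked sample mean/SD
#' reproduce `tissue_stats`, carves an ellipsoidal lesion in which `Y` and
#' `v` are scaled down (the low-oxygenation, low-blood-volume phenotype of
#' subacute ischemic lesions), and mirrors the lesion across the
#' mid-sagittal plane to define the contralateral reference mask. The clean
#' phantom is a deterministic function of `config` (including its seed).
#'
#' @param config [phantom_config()].
#' @return List with `params` ([parameter_maps()]), `lesion_mask`,
#'   `contralateral_mask` (logical 3D arrays) and the `config`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(grid_shape = c(24, 24, 24)))
#' mean(ph$params$Y[ph$params$mask])
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape; vs <- config$voxel_size
  center <- (gs + 1) / 2
  semi <- config$brain_axes_frac * gs
  brain <- ellipsoid_mask(gs, center, semi)

  les <- config$lesion
  semi_mm <- semi * vs
  ctr_mm <- if (is.null(les$center)) c(0.45 * semi_mm[1], 0, 0) else les$center
  rad_mm <- if (is.null(les$radii)) 0.32 * semi_mm else les$radii
  lcenter <- center + ctr_mm / vs
  lsemi <- rad_mm / vs
  lesion <- ellipsoid_mask(gs, lcenter, lsemi)
  if (any(lesion & !brain)) stop("lesion does not fit inside the brain")
  if (!any(lesion)) stop("lesion mask is empty")
  contra <- lesion[gs[1]:1, , , drop = FALSE]  # mirror across mid-sagittal

  scales <- list(S0 = 1, R2 = 1, Y = les$Y_scale, v = les$v_scale,
                 chi_n = 1)
  maps <- with_seed(config$seed, {
    setNames(lapply(names(config$tissue_stats), function(nm) {
      g <- smooth_grf(gs, vs, config$smoothness, brain)
      calibrate_clipped(g, brain, config$tissue_stats[[nm]],
                        lesion = lesion, scale = scales[[nm]])
    }), names(config$tissue_stats))
  })

  params <- parameter_maps(maps$S0, maps$R2, maps$Y, maps$v, maps$chi_n,
                           brain)
  list(params = params, lesion_mask = lesion, contralateral_mask = contra,
       config = config)
}

#' Noise specification
#'
#' @param snr_db Signal-to-noise ratio at the first echo, dB (amplitude
#'   convention: `snr_db = 20 log10(signal / sigma)` with signal the masked
#'   mean first-echo magnitude).
#' @param model `"complex_gaussian"` (noise on real and imaginary channels)
#'   or `"magnitude_plus_qsm_gaussian"` (the magnitude + susceptibility
#'   baseline).
#' @param seed Integer noise seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = 20,
                       model = c("complex_gaussian",
                                 "magnitude_plus_qsm_gaussian"),
                       seed = 1L) {
  stopifnot(is.finite(snr_db))
  model <- match.arg(model)
  structure(list(snr_db = snr_db, model = model, seed = as.integer(seed)),
            class = "noise_spec")
}

# Noise SD from the amplitude-dB convention.
noise_sigma <- function(signal_level, snr_db) signal_level * 10^(-snr_db / 20)

#' Add complex Gaussian noise to a signal stack
#'
#' Independent zero-mean Gaussian noise of standard deviation
#' `sigma = mean(|S1| over mask) * 10^(-snr_db/20)` is added to the real and
#' imaginary parts of every echo. This is the realistic measurement noise of
#' complex mGRE data; the magnitude of the noisy signal is Rice-distributed.
#'
#' @param signal A [signal_stack()].
#' @param spec A [noise_spec()] with `model = "complex_gaussian"`.
#' @param mask Logical 3D array defining the voxels over which the first-echo
#'   signal level is measured; defaults to voxels with nonzero first-echo
#'   magnitude.
#' @return A noisy [signal_stack()]; attribute `"sigma"` records the noise SD.
#' @export
add_complex_noise <- function(signal, spec, mask = NULL) {
  stopifnot(inherits(signal, "signal_stack"), inherits(spec, "noise_spec"))
  if (spec$model != "complex_gaussian")
    stop("spec$model must be 'complex_gaussian'")
  m1 <- abs(signal$data[, , , 1])
  if (is.null(mask)) mask <- m1 > 0
  if (!any(mask)) stop("mask is empty")
  sigma <- noise_sigma(mean(m1[mask]), spec$snr_db)
  n <- length(signal$data)
  noisy <- with_seed(spec$seed, {
    signal$data + complex(real = stats::rnorm(n, 0, sigma),
                          imaginary = stats::rnorm(n, 0, sigma))
  })
  out <- signal_stack(noisy, signal$acq)
  attr(out, "sigma") <- sigma
  out
}

#' Add Gaussian noise to magnitudes and susceptibility (baseline noise model)
#'
#' The baseline noise model of magnitude-domain processing: Gaussian noise
#' with the same first-echo SNR convention is added to each echo magnitude
#' (noisy magnitudes may go negative -- an intentional property of this
#' model, in contrast to Rician magnitude noise), and Gaussian noise of SD
#' `sigma_chi` (ppb) is added to the susceptibility map.
#'
#' @param magnitudes 4D (x, y, z, echo) magnitude array.
#' @param chi_map 3D susceptibility map, ppb.
#' @param spec [noise_spec()] with `model = "magnitude_plus_qsm_gaussian"`.
#' @param mask As in [add_complex_noise()].
#' @param sigma_chi Susceptibility noise SD, ppb.
#' @return List with `magnitudes`, `chi` and the noise SDs `sigma`,
#'   `sigma_chi`.
#' @export
add_magnitude_qsm_noise <- function(magnitudes, chi_map, spec, mask = NULL,
                                    sigma_chi = 10) {
  stopifnot(inherits(spec, "noise_spec"), length(dim(magnitudes)) == 4L,
            length(dim(chi_map)) == 3L)
  if (spec$model != "magnitude_plus_qsm_gaussian")
    stop("spec$model must be 'magnitude_plus_qsm_gaussian'")
  m1 <- magnitudes[, , , 1]
  if (is.null(mask)) mask <- m1 > 0
  if (!any(mask)) stop("mask is empty")
  sigma <- noise_sigma(mean(m1[mask]), spec$snr_db)
  with_seed(spec$seed, {
    list(magnitudes = magnitudes +
           array(stats::rnorm(length(magnitudes), 0, sigma), dim(magnitudes)),
         chi = chi_map +
           array(stats::rnorm(length(chi_map), 0, sigma_chi), dim(chi_map)),
         sigma = sigma, sigma_chi = sigma_chi)
  })
}
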