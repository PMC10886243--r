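# Shared fixtures, built once per test run and cached.
.fix <- new.env(parent = emptyenv())

fix_acq <- function(n = 16L) acq_params(grid_shape = rep(n, 3L))

fix_phantom <- function(n = 16L, seed = 3L) {
  key <- sprintf("ph_%d_%d", n, seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- make_phantom(phantom_config(grid_shape = rep(n, 3L),
                                               seed = seed))
  .fix[[key]]
}

fix_signal <- function(n = 16L, seed = 3L) {
  key <- sprintf("sig_%d_%d", n, seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_signal(fix_phantom(n, seed)$params, fix_acq(n))
  .fix[[key]]
}

fix_field <- function(n = 16L, seed = 3L) {
  key <- sprintf("fld_%d_%d", n, seed)
  if (is.null(.fix[[key]])) {
    p <- fix_phantom(n, seed)$params
    chi <- chi_qsm(p$Y, p$v, p$chi_n)
    chi[!p$mask] <- 0
    D <- dipole_kernel(rep(n, 3L), fix_acq(n)$voxel_size, fix_acq(n)$B0_dir)
    .fix[[key]] <- list(chi = chi, field = field_from_chi(chi, D),
                        kernel = D)
  }
  .fix[[key]]
}

# bounds that contain the phantom generator's full parameter support
wide_bounds <- function() list(S0 = c(1.0, 2.2), R2 = c(7, 165),
                               Y = c(0, 1), v = c(0.002, 0.08),
                               chi_n = c(-960, 165))
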