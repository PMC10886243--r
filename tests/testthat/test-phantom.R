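test_that("phantom generation is deterministic in its config seed", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), seed = 9)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$lesion_mask, b$lesion_mask)
  d <- make_phantom(phantom_config(grid_shape = c(16, 16, 16), seed = 10))
  expect_false(identical(a$params$Y, d$params$Y))
})

test_that("masked statistics hit the cohort targets within 5% at 48^3", {
  ph <- make_phantom(phantom_config(seed = 1))
  p <- ph$params
  st <- phantom_config()$tissue_stats
  for (nm in c("S0", "R2", "Y", "v", "chi_n")) {
    vals <- p[[nm]][p$mask]
    expect_lt(abs(mean(vals) - st[[nm]][1]) / abs(st[[nm]][1]), 0.05,
              label = paste(nm, "mean"))
    expect_lt(abs(sd(vals) - st[[nm]][2]) / st[[nm]][2], 0.05,
              label = paste(nm, "sd"))
    full <- p[[nm]][p$mask]
    expect_true(all(full >= st[[nm]][3] - 1e-12 &
                      full <= st[[nm]][4] + 1e-12), label = paste(nm, "range"))
  }
})

test_that("lesion lowers Y and v and mirrors to the contralateral mask", {
  ph <- fix_phantom(24L, 5L)
  p <- ph$params
  expect_true(all(ph$lesion_mask[ph$lesion_mask] & p$mask[ph$lesion_mask]))
  expect_lt(mean(p$Y[ph$lesion_mask]), mean(p$Y[ph$contralateral_mask]))
  expect_lt(mean(p$v[ph$lesion_mask]), mean(p$v[ph$contralateral_mask]))
  gs <- dim(p$mask)
  expect_identical(ph$contralateral_mask,
                   ph$lesion_mask[gs[1]:1, , , drop = FALSE])
  expect_false(any(ph$lesion_mask & ph$contralateral_mask))
})

test_that("a null lesion is statistically indistinguishable from its mirror", {
  cfg <- phantom_config(grid_shape = c(24, 24, 24), seed = 2,
                        lesion = list(Y_scale = 1, v_scale = 1))
  ph <- make_phantom(cfg)
  dY <- mean(ph$params$Y[ph$lesion_mask]) -
    mean(ph$params$Y[ph$contralateral_mask])
  # same-field mirror difference: only random-field fluctuation remains
  expect_lt(abs(dY), 3 * sd(ph$params$Y[ph$params$mask]) /
              sqrt(sum(ph$lesion_mask)) * 5)
})

test_that("an oversized lesion is rejected", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16),
                        lesion = list(center = c(12, 0, 0), radii = c(8, 8, 8)))
  expect_error(make_phantom(cfg), "inside the brain")
})

test_that("complex noise has the dB-defined standard deviation", {
  sig <- fix_signal(24L, 1L)
  mask <- fix_phantom(24L, 1L)$params$mask
  # rescale so the masked first-echo mean is exactly 1: snr 20 dB -> 0.1
  scale <- mean(abs(sig$data[, , , 1])[mask])
  unit <- signal_stack(sig$data / scale, sig$acq)
  noisy <- add_complex_noise(unit, noise_spec(20, seed = 3), mask)
  expect_equal(attr(noisy, "sigma"), 0.1, tolerance = 1e-12)
  eps <- noisy$data - unit$data
  draws <- c(Re(eps), Im(eps))      # > 2e5 samples
  expect_gt(length(draws), 1e5)
  expect_lt(abs(sd(draws) - 0.1) / 0.1, 0.01)
  expect_lt(abs(mean(draws)), 3 * 0.1 / sqrt(length(draws)))
})

test_that("infinite SNR reduces the noise injectors to the identity", {
  sig <- fix_signal()
  mask <- fix_phantom()$params$mask
  out <- add_complex_noise(sig, noise_spec(300, seed = 1), mask)
  expect_lt(max(Mod(out$data - sig$data)), 1e-12)
  A <- f_qbold(fix_phantom()$params, fix_acq())
  chi <- fix_field()$chi
  mq <- add_magnitude_qsm_noise(A, chi,
                                noise_spec(300, "magnitude_plus_qsm_gaussian",
                                           seed = 1), mask)
  expect_lt(max(abs(mq$magnitudes - A)), 1e-12)
})

test_that("zero-signal magnitudes are Rayleigh with mean sigma sqrt(pi/2)", {
  # mask region with unit signal defines sigma; the zero-signal voxels give
  # pure-noise magnitudes
  gs <- c(28L, 28L, 28L)
  acq <- acq_params(grid_shape = gs)
  dat <- array(0 + 0i, c(gs, 8L))
  mask <- array(FALSE, gs); mask[1:4, 1:4, 1:4] <- TRUE
  for (j in 1:8) dat[, , , j][mask] <- 1 + 0i
  noisy <- add_complex_noise(signal_stack(dat, acq), noise_spec(20, seed = 8),
                             mask)
  sigma <- attr(noisy, "sigma")
  mags <- Mod(noisy$data[, , , ])[rep(!mask, 8)]
  expect_gt(length(mags), 1e5)
  expect_lt(abs(mean(mags) - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)),
            0.01)
})

test_that("baseline magnitude noise is Gaussian, not Rician", {
  ph <- fix_phantom(24L, 1L)
  A <- f_qbold(ph$params, acq_params(grid_shape = c(24, 24, 24)))
  chi <- chi_qsm(ph$params$Y, ph$params$v, ph$params$chi_n)
  chi[!ph$params$mask] <- 0
  mq <- add_magnitude_qsm_noise(A, chi,
                                noise_spec(5, "magnitude_plus_qsm_gaussian",
                                           seed = 2), ph$params$mask,
                                sigma_chi = 10)
  # unbounded Gaussian support: noisy magnitudes go negative at low SNR
  expect_true(any(mq$magnitudes < 0))
  # chi noise SD within 1% over > 1e4 voxels (13824 here)
  dchi <- (mq$chi - chi)
  expect_lt(abs(sd(dchi) - 10) / 10, 0.015)
  expect_error(add_magnitude_qsm_noise(A, chi, noise_spec(5), ph$params$mask),
               "magnitude_plus_qsm_gaussian")
})

test_that("re-seeding changes the noise but not the clean phantom", {
  sig <- fix_signal()
  mask <- fix_phantom()$params$mask
  n1 <- add_complex_noise(sig, noise_spec(20, seed = 1), mask)
  n2 <- add_complex_noise(sig, noise_spec(20, seed = 2), mask)
  n1b <- add_complex_noise(sig, noise_spec(20, seed = 1), mask)
  expect_identical(n1$data, n1b$data)
  expect_false(identical(n1$data, n2$data))
})
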