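test_that("delta_omega matches hand arithmetic and is linear in its terms", {
  co <- physio_constants()
  # cancellation: chi_n chosen so the bracket vanishes
  Y <- 0.8
  chi_n0 <- co$chi_ba + co$psi_Hb * co$dchi_Hb * (1 - Y)
  expect_equal(delta_omega(Y, chi_n0, co, 3), 0)
  # frozen hand evaluations of (1/3) 2.6751e8 * 3 * (...) * 1e-9
  expect_equal(delta_omega(0.98, 0, co, 3), -22.88147, tolerance = 1e-6)
  expect_equal(delta_omega(0.60, -11.6, co, 3), 95.92906, tolerance = 1e-6)
  # linearity in (1 - Y)
  d1 <- delta_omega(0.9, 0, co, 3) - delta_omega(1.0, 0, co, 3)
  d2 <- delta_omega(0.7, 0, co, 3) - delta_omega(0.8, 0, co, 3)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(delta_omega(NaN, 0), "finite")
  expect_error(delta_omega(1.2, 0), "0, 1")
})

test_that("physio constant defaults are the printed values and validated", {
  co <- physio_constants()
  expect_equal(co$gamma, 267.51e6)
  expect_equal(co$psi_Hb, 0.0909)
  expect_equal(co$dchi_Hb, 12522)
  expect_equal(co$chi_ba, -108.3)
  expect_equal(co$Hct, 0.357)
  expect_equal(co$alpha, 0.77)
  expect_equal(co$Ya, 0.98)
  expect_error(physio_constants(alpha = 0), "alpha")
  expect_error(physio_constants(Ya = 1.2), "Ya")
})

test_that("fs agrees with the quadrature oracle in both regimes", {
  # short-time quadratic law 0.3 x^2 within 2% (quadrature oracle)
  xs <- c(0.05, 0.1, 0.2, 0.3)
  q <- fs_quadrature(xs)
  expect_true(all(abs(q / (0.3 * xs^2) - 1) < 0.02))
  # spline implementation tracks the quadrature closely
  xr <- c(0.01, 0.37, 1.7, 4.2, 9.3, 22, 47)
  expect_equal(fs(xr), fs_quadrature(xr), tolerance = 1e-6)
  # long-time linear regime with unit slope
  slope <- (fs_quadrature(30) - fs_quadrature(20)) / 10
  expect_equal(slope, 1, tolerance = 0.02)
  expect_true(fs_quadrature(20) / 20 > 0.9)
})

test_that("fs is even, vanishes at zero, and increases in |x|", {
  expect_identical(fs(0), 0)
  x <- c(0.2, 1.3, 6)
  expect_equal(fs(-x), fs(x))
  g <- fs(seq(0, 30, length.out = 200))
  expect_true(all(diff(g) > 0))
  expect_true(all(g[-1] > 0))
  # derivative is odd and matches finite differences of the spline
  h <- 1e-5
  for (x0 in c(0.4, 3, 15)) {
    expect_equal(fs_deriv(x0), (fs(x0 + h) - fs(x0 - h)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(fs_deriv(-x0), -fs_deriv(x0))
  }
  expect_error(fs(Inf), "finite")
})

test_that("f_bold is 1 with no blood or at t = 0 and decays with time", {
  co <- physio_constants()
  expect_equal(f_bold(0.5, 0, 20, 0.03), 1)
  expect_equal(f_bold(0.5, 0.03, 20, 0), 1)
  tt <- seq(0, 0.04, by = 0.005)
  fb <- f_bold(0.67, 0.023, 0, tt)
  expect_true(all(diff(fb) < 0))
  expect_true(all(fb > 0 & fb <= 1))
  # composition of the two oracles
  dw <- delta_omega(0.67, 0, co, 3)
  expect_equal(f_bold(0.67, 0.023, 0, 0.0395),
               exp(-0.023 * fs_quadrature(dw * 0.0395)), tolerance = 1e-6)
  expect_error(f_bold(0.5, -0.01, 0, 0.01), "non-negative")
})

test_that("f_qbold reduces to the expected limits and factorizes", {
  n <- 6L
  acq <- acq_params(grid_shape = rep(n, 3L))
  mk <- function(x) array(x, rep(n, 3L))
  mask <- mk(TRUE)
  # all decay channels off -> S0 at every echo
  p0 <- parameter_maps(mk(1.3), mk(0), mk(0.98), mk(0), mk(0), mask)
  A <- f_qbold(p0, acq)
  expect_equal(range(A - 1.3), c(0, 0), tolerance = 1e-12)
  # mono-exponential limit, hand value exp(-19.6 * 0.0045)
  p1 <- parameter_maps(mk(1), mk(19.6), mk(0.98), mk(0), mk(0), mask)
  expect_equal(f_qbold(p1, acq, echo = 1)[1, 1, 1], exp(-19.6 * 0.0045),
               tolerance = 1e-12)
  expect_equal(exp(-19.6 * 0.0045), 0.9156, tolerance = 1e-4)
  # full draw equals product of independently computed factors
  co <- physio_constants()
  p2 <- parameter_maps(mk(1.1), mk(25), mk(0.6), mk(0.03), mk(-40), mask)
  A2 <- f_qbold(p2, acq, echo = 5)[2, 3, 4]
  t5 <- acq$echo_times[5]
  expect_equal(A2, 1.1 * exp(-25 * t5) *
                 f_bold(0.6, 0.03, -40, t5, co, acq$B0), tolerance = 1e-10)
  expect_error(f_qbold(p2, acq, G = array(1, c(2, 2, 2, 8))), "4D")
})

test_that("chi_qsm is the printed mixture with the expected coefficients", {
  co <- physio_constants()
  # no blood -> tissue susceptibility exactly
  expect_equal(chi_qsm(0.7, 0, -23.5), -23.5)
  # frozen hand evaluation at (Y = 0.60, v = 0.03, chi_n = 0)
  expect_equal(chi_qsm(0.60, 0.03, 0), 3.523575, tolerance = 1e-5)
  # chi_n slope equals 1 - v/alpha (finite differences)
  h <- 1e-6
  sl <- (chi_qsm(0.6, 0.023, h) - chi_qsm(0.6, 0.023, 0)) / h
  expect_equal(sl, 1 - 0.023 / co$alpha, tolerance = 1e-8)
  expect_equal(1 - 0.023 / 0.77, 0.9701, tolerance = 1e-4)
  # affine coefficient recovery to 1e-10
  b0 <- chi_qsm(0.6, 0.01, 5)
  cv <- (chi_qsm(0.6, 0.01 + h, 5) - b0) / h
  cn <- (chi_qsm(0.6, 0.01, 5 + h) - b0) / h
  blood <- co$chi_ba / co$alpha +
    co$psi_Hb * co$dchi_Hb * (-0.6 + 1 - (1 - co$alpha) * co$Ya) / co$alpha
  expect_equal(cv, blood - 5 / co$alpha, tolerance = 1e-4)
  expect_equal(cn, 1 - 0.01 / co$alpha, tolerance = 1e-8)
  expect_error(chi_qsm(0.6, 0.8, 0), "alpha")
})

test_that("chi_qsm_mixture matches the explicit three-compartment sum", {
  co <- physio_constants()
  Y <- 0.60; v <- 0.03; chi_n <- 0
  chi_v <- co$chi_ba + co$psi_Hb * co$dchi_Hb * (1 - Y)
  chi_a <- co$chi_ba + co$psi_Hb * co$dchi_Hb * (1 - co$Ya)
  byhand <- v * chi_v + v * (1 - co$alpha) / co$alpha * chi_a +
    (1 - v / co$alpha) * chi_n
  expect_equal(chi_qsm_mixture(Y, v, chi_n), byhand, tolerance = 1e-10)
  expect_equal(byhand, 9.643515, tolerance = 1e-5)
  # the two groupings genuinely differ away from v = 0 (documented)
  expect_gt(abs(chi_qsm_mixture(Y, v, chi_n) - chi_qsm(Y, v, chi_n)), 1)
  expect_equal(chi_qsm_mixture(Y, 0, -7), chi_qsm(Y, 0, -7))
})

test_that("oef_from_Y implements 1 - Y/Ya with its edge cases", {
  expect_equal(oef_from_Y(0.98), 0)
  expect_equal(oef_from_Y(0), 1)
  expect_equal(oef_from_Y(0.67), 1 - 0.67 / 0.98, tolerance = 1e-12)
  expect_equal(oef_from_Y(0.67), 0.3163, tolerance = 1e-4)
  expect_warning(oef_from_Y(0.99), "exceeds")
  expect_error(oef_from_Y(0.5, Ya = 0), "nonzero")
})
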