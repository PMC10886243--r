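#' Accuracy and precision of repeated OEF reconstructions
#'
#' `mean_error()` is the signed mean over masked voxels of
#' `OEF_truth - OEF_avg`, where `OEF_avg` is the across-trial voxel mean
#' (accuracy). `mean_std()` is the across-trial per-voxel standard deviation
#' (population convention, divisor `Nt`) averaged over masked voxels
#' (precision).
#'
#' @param truth 3D truth OEF map.
#' @param trials 4D array (x, y, z, trial) of reconstructed OEF maps, or a
#'   list of 3D maps.
#' @param mask Logical 3D mask.
#' @return Scalar in the units of the input maps.
#' @export
mean_error <- function(truth, trials, mask) {
  trials <- trials_array(trials)
  if (!any(mask)) stop("mask is empty")
  if (!identical(dim(truth), dim(trials)[1:3])) stop("shape mismatch")
  avg <- apply_trials(trials, rowMeans)
  mean(truth[mask] - avg[mask])
}

#' @rdname mean_error
#' @export
mean_std <- function(trials, mask) {
  trials <- trials_array(trials)
  if (!any(mask)) stop("mask is empty")
  nt <- dim(trials)[4]
  if (nt < 2) return(0)
  m <- apply_trials(trials, rowMeans)
  ssq <- apply_trials(trials, function(x) rowMeans(x^2))
  sd_map <- sqrt(pmax(ssq - m^2, 0))  # divisor Nt (population SD)
  mean(sd_map[mask])
}

trials_array <- function(trials) {
  if (is.list(trials)) {
    dm <- dim(trials[[1]])
    trials <- array(unlist(trials), c(dm, length(trials)))
  }
  if (length(dim(trials)) != 4L) stop("trials must be 4D or a list of 3D maps")
  trials
}

apply_trials <- function(trials, f) {
  dm <- dim(trials)
  array(f(matrix(trials, prod(dm[1:3]), dm[4])), dm[1:3])
}

#' Lesion-to-contralateral OEF ratio
#'
#' Ratio of the mean OEF inside the lesion mask to the mean OEF inside the
#' mirrored contralateral normal-tissue mask. Scale-invariant; 1 when the
#' two regions have identical means.
#'
#' @param oef 3D OEF map.
#' @param lesion_mask,contralateral_mask Non-empty logical 3D masks.
#' @return Scalar ratio.
#' @export
oef_ratio <- function(oef, lesion_mask, contralateral_mask) {
  if (!any(lesion_mask) || !any(contralateral_mask))
    stop("masks must be non-empty")
  denom <- mean(oef[contralateral_mask])
  if (denom == 0) stop("contralateral mean OEF is zero; ratio undefined")
  mean(oef[lesion_mask]) / denom
}

#' Structural similarity between two OEF maps
#'
#' Mean SSIM index over masked voxels, with local statistics from a 3D
#' Gaussian window (SD `sigma` voxels), standard constants K1 = 0.01,
#' K2 = 0.03, and the dynamic range set to the pooled masked range of the
#' two maps. Symmetric; 1 for identical maps.
#'
#' @param oef_a,oef_b 3D maps on a common grid.
#' @param mask Logical 3D mask.
#' @param sigma Gaussian window SD in voxels.
#' @param K1,K2 SSIM stabilization constants.
#' @return Scalar in \[-1, 1\].
#' @export
ssim_map <- function(oef_a, oef_b, mask, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(oef_a), dim(oef_b))) stop("shape mismatch")
  if (!any(mask)) stop("mask is empty")
  L <- diff(range(c(oef_a[mask], oef_b[mask])))
  if (L == 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  gs <- dim(oef_a)
  g1 <- function(n, s) {
    x <- (0:(n - 1)); x <- pmin(x, n - x)
    k <- exp(-x^2 / (2 * s^2)); k / sum(k)
  }
  K <- stats::fft(outer(outer(g1(gs[1], sigma), g1(gs[2], sigma)),
                        g1(gs[3], sigma)))
  blur <- function(x) Re(stats::fft(stats::fft(x) * K, inverse = TRUE)) /
    length(x)
  mu_a <- blur(oef_a); mu_b <- blur(oef_b)
  va <- pmax(blur(oef_a^2) - mu_a^2, 0)
  vb <- pmax(blur(oef_b^2) - mu_b^2, 0)
  cab <- blur(oef_a * oef_b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s[mask])
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test; the exact null distribution is used
#' for n <= 25 pairs (no ties or zero differences), the normal approximation
#' with continuity correction above.
#'
#' @param x,y Paired numeric vectors (n >= 5), or `y = NULL` to treat `x`
#'   as differences.
#' @return List with `statistic` (V) and `p.value`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 1, 4, 2, 5), rep(0, 6))$p.value  # 0.03125
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 5) stop("at least 5 pairs required")
  if (all(d == 0)) stop("all differences are zero; test undefined")
  ht <- stats::wilcox.test(d, exact = length(d) <= 25 &&
                             !any(d == 0) && !anyDuplicated(abs(d)),
                           correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
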