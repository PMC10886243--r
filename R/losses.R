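#' Z-score normalization statistics
#'
#' Per-parameter mean and SD used to z-score parameter maps before the L1
#' losses. Computed once from the masked voxels of a (training) set of
#' parameter maps and then frozen.
#'
#' @param params_list A [parameter_maps()] or a list of them.
#' @return Object of class `norm_stats`: named list of `c(mu, sd)`.
#' @export
compute_norm_stats <- function(params_list) {
  if (inherits(params_list, "parameter_maps")) params_list <- list(params_list)
  st <- lapply(param_names, function(nm) {
    v <- unlist(lapply(params_list, function(p) p[[nm]][p$mask]))
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero variance for ", nm)
    c(mu = mean(v), sd = s)
  })
  structure(setNames(st, param_names), class = "norm_stats")
}

#' Z-score parameter maps
#'
#' `z = (x - mu) / sigma` per parameter; exactly invertible via
#' `z_denormalize()`.
#'
#' @param params A [parameter_maps()].
#' @param stats A `norm_stats` object (`sd > 0`).
#' @return Named list of five z-scored 3D arrays plus the mask.
#' @export
z_normalize <- function(params, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  out <- lapply(param_names, function(nm) {
    s <- stats[[nm]]
    if (s[["sd"]] <= 0) stop("sd must be positive")
    (params[[nm]] - s[["mu"]]) / s[["sd"]]
  })
  c(setNames(out, param_names), list(mask = params$mask))
}

#' @rdname z_normalize
#' @param z Output of `z_normalize()`.
#' @export
z_denormalize <- function(z, stats) {
  out <- lapply(param_names, function(nm) {
    s <- stats[[nm]]
    z[[nm]] * s[["sd"]] + s[["mu"]]
  })
  c(setNames(out, param_names), list(mask = z$mask))
}

#' Parameter-map L1 loss
#'
#' Mean absolute difference between two z-scored parameter stacks over the
#' five channels and the masked voxels.
#'
#' @param Z_truth,Z_out Outputs of [z_normalize()] (or any named lists with
#'   the five parameter channels).
#' @param mask Logical 3D mask (defaults to `Z_truth$mask`).
#' @return Non-negative scalar; zero iff the stacks agree on the mask.
#' @export
loss_l1 <- function(Z_truth, Z_out, mask = Z_truth$mask) {
  if (!any(mask)) stop("mask is empty")
  tot <- 0
  for (nm in param_names) {
    if (!identical(dim(Z_truth[[nm]]), dim(Z_out[[nm]])))
      stop("shape mismatch in channel ", nm)
    tot <- tot + sum(abs(Z_truth[[nm]][mask] - Z_out[[nm]][mask]))
  }
  tot / (5 * sum(mask))
}

# Forward difference along one axis with replicate boundary (last slice
# difference is zero).
fwd_diff <- function(x, axis) {
  d <- array(0, dim(x))
  n <- dim(x)[axis]
  if (n < 2) return(d)
  switch(axis,
         `1` = { d[-n, , ] <- x[-1, , ] - x[-n, , ] },
         `2` = { d[, -n, ] <- x[, -1, ] - x[, -n, ] },
         `3` = { d[, , -n] <- x[, , -1] - x[, , -n] })
  d
}

# Adjoint of fwd_diff: (D^T w)[i] = w[i-1] - w[i], w outside = 0.
fwd_diff_adj <- function(w, axis) {
  n <- dim(w)[axis]
  d <- -w
  if (n >= 2) switch(axis,
         `1` = { d[-1, , ] <- d[-1, , ] + w[-n, , ] },
         `2` = { d[, -1, ] <- d[, -1, ] + w[, -n, ] },
         `3` = { d[, , -1] <- d[, , -1] + w[, , -n] })
  # the last forward difference is identically zero, so its cotangent must
  # not propagate
  switch(axis,
         `1` = { d0 <- w[n, , ]; d[n, , ] <- d[n, , ] + d0 },
         `2` = { d0 <- w[, n, ]; d[, n, ] <- d[, n, ] + d0 },
         `3` = { d0 <- w[, , n]; d[, , n] <- d[, , n] + d0 })
  d
}

#' Edge-preserving spatial-gradient L1 loss on Y
#'
#' L1 difference of the spatial gradients (forward differences along the
#' three axes, replicate boundary) of two normalized Y maps, averaged over
#' masked voxels and axes. Invariant to a constant offset between the maps.
#'
#' @param Y_truth,Y_out Normalized 3D Y maps.
#' @param mask Logical 3D mask.
#' @return Non-negative scalar.
#' @export
loss_grad <- function(Y_truth, Y_out, mask) {
  if (!identical(dim(Y_truth), dim(Y_out))) stop("shape mismatch")
  if (!any(mask)) stop("mask is empty")
  tot <- 0
  for (a in 1:3)
    tot <- tot + sum(abs(fwd_diff(Y_truth, a)[mask] -
                           fwd_diff(Y_out, a)[mask]))
  tot / (3 * sum(mask))
}

# Gradient of loss_grad with respect to Y_out.
loss_grad_backward <- function(Y_truth, Y_out, mask) {
  nrm <- 3 * sum(mask)
  g <- array(0, dim(Y_out))
  for (a in 1:3) {
    w <- sign(fwd_diff(Y_out, a) - fwd_diff(Y_truth, a))
    w[!mask] <- 0
    g <- g + fwd_diff_adj(w, a)
  }
  g / nrm
}

#' Physics-consistency model losses
#'
#' `loss_model_mcqq()` is the mean modulus of the difference between the two
#' complex forward signals (the full model including the dipole-convolved
#' phase), over masked voxels and echoes. `loss_model_qq()` is the baseline
#' counterpart without the convolution: mean L1 of the qBOLD magnitude
#' difference plus mean L1 of the voxel-wise susceptibility difference.
#'
#' @param params_truth,params_out [parameter_maps()] on a common grid.
#' @param acq,consts Acquisition and constants.
#' @param mask Logical mask (defaults to the truth mask).
#' @return Non-negative scalar; zero iff the forward signals agree.
#' @export
loss_model_mcqq <- function(params_truth, params_out, acq,
                            consts = physio_constants(),
                            mask = params_truth$mask) {
  S_T <- model_forward(params_truth, acq, consts)$signal
  S_O <- model_forward(params_out, acq, consts)$signal
  ne <- length(acq$echo_times)
  mask4 <- array(mask, c(dim(mask), ne))
  sum(Mod(S_T - S_O)[mask4]) / (ne * sum(mask))
}

#' @rdname loss_model_mcqq
#' @export
loss_model_qq <- function(params_truth, params_out, acq,
                          consts = physio_constants(),
                          mask = params_truth$mask) {
  A_T <- f_qbold(params_truth, acq, consts)
  A_O <- f_qbold(params_out, acq, consts)
  chi_T <- chi_qsm(params_truth$Y, params_truth$v, params_truth$chi_n, consts)
  chi_O <- chi_qsm(params_out$Y, params_out$v, params_out$chi_n, consts)
  ne <- length(acq$echo_times)
  mask4 <- array(mask, c(dim(mask), ne))
  sum(abs(A_T - A_O)[mask4]) / (ne * sum(mask)) +
    sum(abs(chi_T - chi_O)[mask]) / sum(mask)
}

# Gradient of loss_model_mcqq with respect to params_out (5 maps).
loss_model_mcqq_backward <- function(params_truth, params_out, acq, consts,
                                     mask = params_truth$mask) {
  fw_T <- model_forward(params_truth, acq, consts)
  fw_O <- model_forward(params_out, acq, consts)
  ne <- length(acq$echo_times)
  mask4 <- array(mask, c(dim(mask), ne))
  d <- fw_O$signal - fw_T$signal
  md <- Mod(d)
  R <- d / ifelse(md > 0, md, 1)
  R[md == 0] <- 0i
  R[!mask4] <- 0i
  R <- R / (ne * sum(mask))
  model_gradient(fw_O, params_out, acq, consts, R)
}

#' Loss weights
#'
#' @param w_model Weight of the model-consistency loss (default 0.1).
#' @param w_grad Weight of the gradient loss (default 0.1).
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(w_model = 0.1, w_grad = 0.1) {
  if (w_model < 0 || w_grad < 0) stop("loss weights must be non-negative")
  structure(list(w_model = w_model, w_grad = w_grad), class = "loss_weights")
}

#' Total training loss
#'
#' `E = E_L1 + w_model * E_model + w_grad * E_grad`.
#'
#' @param E_l1,E_model,E_grad Non-negative loss components.
#' @param w A [loss_weights()].
#' @return Scalar weighted sum.
#' @export
#' @examples
#' total_loss(1, 1, 1)  # 1.2
total_loss <- function(E_l1, E_model, E_grad, w = loss_weights()) {
  stopifnot(E_l1 >= 0, E_model >= 0, E_grad >= 0)
  E_l1 + w$w_model * E_model + w$w_grad * E_grad
}
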