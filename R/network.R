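#' Network configuration
#'
#' Architecture of one magnitude and one phase sub-network. At the reference
#' settings (`depth = 4`) each sub-network introspects to exactly 18
#' convolutions with 3x3x3 kernel, 4 max-pooling and 4 deconvolution layers
#' with 2x2x2 kernel, 4 feature concatenations and 1 final 1x1x1
#' convolution. `base_channels` scales the width (the default 8 is a
#' CPU-scale width; the layer counts are width-independent).
#'
#' @param depth Number of pooling levels.
#' @param base_channels Channels of the first encoder level.
#' @param in_channels Input channels per sub-network (8 echoes).
#' @param bounds Output bounds applied by the element-wise tanh squashing,
#'   as in [fit_config()].
#' @param expected_layers Optional named vector `c(conv3, pool, deconv,
#'   concat, conv1)`; if supplied, [build_network()] fails unless the
#'   constructed sub-network matches it exactly.
#' @return Object of class `network_config`.
#' @export
network_config <- function(depth = 4L, base_channels = 8L, in_channels = 8L,
                           bounds = fit_config()$bounds,
                           expected_layers = NULL) {
  stopifnot(depth >= 1L, base_channels >= 1L, in_channels >= 1L)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 bounds = bounds, expected_layers = expected_layers),
            class = "network_config")
}

#' Layer counts of a sub-network
#'
#' @param x A `network_config` or built network model.
#' @return Named integer vector `c(conv3, pool, deconv, concat, conv1)`.
#' @export
network_layer_counts <- function(x) {
  cfg <- if (inherits(x, "qq_network")) x$config else x
  d <- cfg$depth
  c(conv3 = 4L * d + 2L, pool = d, deconv = d, concat = d, conv1 = 1L)
}

#' Build the dual sub-network model
#'
#' Constructs two encoder--decoder sub-networks: the magnitude branch maps 8
#' echo-magnitude channels to 5 pre-activation parameter channels
#' (S0, R2, Y, v, chi_n) and the phase branch maps 8 echo-phase channels to
#' 3 (Y, v, chi_n). The three shared channels are merged by learnable
#' per-channel scalar weights (initialized 0.5/0.5) before the element-wise
#' tanh squashing that maps every output channel into its physiological
#' bounds (an open interval, so outputs lie strictly inside).
#'
#' @param cfg A [network_config()].
#' @param seed Seed for weight initialization.
#' @return Object of class `qq_network`.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  counts <- network_layer_counts(cfg)
  if (!is.null(cfg$expected_layers)) {
    exp_ <- cfg$expected_layers
    if (!all(counts[names(exp_)] == exp_))
      stop("configured architecture does not produce the expected layer ",
           "counts (got ", paste(counts, collapse = "/"), ")")
  }
  with_seed(seed, {
    mag <- unet_init(cfg$in_channels, 5L, cfg$depth, cfg$base_channels)
    phase <- unet_init(cfg$in_channels, 3L, cfg$depth, cfg$base_channels)
    structure(list(mag = mag, phase = phase,
                   merge = list(Y = c(0.5, 0.5), v = c(0.5, 0.5),
                                chi_n = c(0.5, 0.5)),
                   config = cfg), class = "qq_network")
  })
}

#' @export
print.qq_network <- function(x, ...) {
  ct <- network_layer_counts(x)
  cat(sprintf(paste0("<qq_network> depth %d, base channels %d; per ",
                     "sub-network: %d conv3, %d pool, %d deconv, %d concat, ",
                     "%d conv1\n"),
              x$config$depth, x$config$base_channels,
              ct["conv3"], ct["pool"], ct["deconv"], ct["concat"],
              ct["conv1"]))
  invisible(x)
}

# Forward pass of the dual model. mag_x / phase_x: (nvox x 8) matrices.
# Returns theta (nvox x 5, bounded), pre-activations, and caches.
network_forward <- function(model, mag_x, phase_x, shape) {
  cfg <- model$config
  cm <- unet_forward(model$mag, mag_x, shape, cfg$depth)
  cp <- unet_forward(model$phase, phase_x, shape, cfg$depth)
  pre <- cm$out  # columns: S0, R2, Y, v, chi_n
  shared <- c("Y", "v", "chi_n")
  for (k in seq_along(shared)) {
    w <- model$merge[[shared[k]]]
    pre[, 2L + k] <- w[1] * cm$out[, 2L + k] + w[2] * cp$out[, k]
  }
  theta <- pre
  for (k in 1:5) {
    b <- cfg$bounds[[param_names[k]]]
    theta[, k] <- squash(pre[, k], b[1], b[2])
  }
  list(theta = theta, pre = pre, cache_mag = cm, cache_phase = cp)
}

# Backward pass: dtheta is (nvox x 5) gradient of the loss w.r.t. the
# bounded outputs. Returns gradients for both sub-networks and the merge
# weights.
network_backward <- function(model, fwd, dtheta) {
  cfg <- model$config
  dpre <- dtheta
  for (k in 1:5) {
    b <- cfg$bounds[[param_names[k]]]
    dpre[, k] <- dtheta[, k] * squash_deriv(fwd$pre[, k], b[1], b[2])
  }
  dmag <- dpre
  dphase <- matrix(0, nrow(dpre), 3L)
  gmerge <- list()
  shared <- c("Y", "v", "chi_n")
  for (k in seq_along(shared)) {
    w <- model$merge[[shared[k]]]
    om <- fwd$cache_mag$out[, 2L + k]
    op <- fwd$cache_phase$out[, k]
    gmerge[[shared[k]]] <- c(sum(om * dpre[, 2L + k]),
                             sum(op * dpre[, 2L + k]))
    dmag[, 2L + k] <- w[1] * dpre[, 2L + k]
    dphase[, k] <- w[2] * dpre[, 2L + k]
  }
  list(mag = unet_backward(model$mag, fwd$cache_mag, dmag, cfg$depth),
       phase = unet_backward(model$phase, fwd$cache_phase, dphase,
                             cfg$depth),
       merge = gmerge)
}

# Flatten/update helpers for Adam ---------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, path) {
    if (is.list(p) && !is.null(names(p)) && all(c("W", "b") %in% names(p))) {
      for (f in c("W", "b")) {
        key <- paste(path, f)
        gv <- g[[f]]
        if (is.null(state$m[[key]])) {
          state$m[[key]] <<- gv * 0; state$v[[key]] <<- gv * 0
        }
        state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * gv
        state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * gv^2
        mhat <- state$m[[key]] / (1 - beta1^state$t)
        vhat <- state$v[[key]] / (1 - beta2^state$t)
        p[[f]] <- p[[f]] - lr * mhat / (sqrt(vhat) + eps)
      }
      p
    } else if (is.numeric(p)) {
      key <- path
      if (is.null(state$m[[key]])) {
        state$m[[key]] <<- p * 0; state$v[[key]] <<- p * 0
      }
      state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^state$t)
      vhat <- state$v[[key]] / (1 - beta2^state$t)
      p - lr * mhat / (sqrt(vhat) + eps)
    } else {
      for (nm in names(p)) p[[nm]] <- walk(p[[nm]], g[[nm]], paste(path, nm))
      p
    }
  }
  params2 <- walk(params, grads, "")
  list(state = state, params = params2)
}
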