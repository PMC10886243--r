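#' Training configuration
#'
#' Desk-scale defaults: small patches and few epochs so that a full training
#' run is a CPU-scale experiment; the reference regime from which it is
#' scaled down uses a 4-level network, whole-brain patches
#' (16 x 200 x 200 x 48), Adam at 1e-4 and 400 epochs. The learning rate
#' default here is larger because the scaled-down run takes few steps.
#'
#' @param epochs Number of epochs (each epoch visits every brain once, in
#'   random order, with a random patch position and a fresh noise instance).
#' @param lr Adam learning rate.
#' @param patch_shape Spatial patch shape; every entry must be divisible by
#'   `2^depth`.
#' @param snr_db First-echo SNR of the per-epoch noise instances, dB.
#' @param weights [loss_weights()] of the total loss
#'   `E = E_L1 + w_model * E_model + w_grad * E_grad`.
#' @param model_loss `"mcqq"` (complex-signal consistency, the dual-network
#'   loss) or `"none"`.
#' @param seed Global training seed (initial shuffling, patch positions and
#'   noise all derive from it; a fixed seed makes the loss history
#'   bit-reproducible).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 0.01,
                         patch_shape = c(16L, 16L, 16L),
                         snr_db = 20, weights = loss_weights(),
                         model_loss = c("mcqq", "none"), seed = 1L) {
  model_loss <- match.arg(model_loss)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 patch_shape = as.integer(patch_shape), snr_db = snr_db,
                 weights = weights, model_loss = model_loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble a training set from phantoms
#'
#' Simulates the clean complex signals of each phantom once; noise instances
#' are drawn afresh at every epoch during training.
#'
#' @param phantoms List of [make_phantom()] outputs.
#' @param acq,consts Acquisition and constants (the acquisition grid must
#'   match the phantom grid).
#' @return List of brains, each with `params`, `signal` (clean
#'   [signal_stack()]), `sigma_ref` (the SNR reference level: masked mean
#'   first-echo magnitude) and `mask`.
#' @export
make_training_set <- function(phantoms, acq, consts = physio_constants()) {
  lapply(phantoms, function(ph) {
    sig <- simulate_signal(ph$params, acq, consts)
    m1 <- abs(sig$data[, , , 1])
    list(params = ph$params, signal = sig,
         sigma_ref = mean(m1[ph$params$mask]), mask = ph$params$mask)
  })
}

# Per-channel input statistics (8 magnitude + 8 phase channels) from the
# clean training signals, frozen for training and inference.
input_norm_stats <- function(dataset) {
  ne <- dim(dataset[[1]]$signal$data)[4]
  mg <- lapply(seq_len(ne), function(j)
    unlist(lapply(dataset, function(b) abs(b$signal$data[, , , j])[b$mask])))
  ph <- lapply(seq_len(ne), function(j)
    unlist(lapply(dataset, function(b) Arg(b$signal$data[, , , j])[b$mask])))
  list(mag = cbind(mu = vapply(mg, mean, 0),
                   sd = pmax(vapply(mg, stats::sd, 0), 1e-12)),
       phase = cbind(mu = vapply(ph, mean, 0),
                     sd = pmax(vapply(ph, stats::sd, 0), 1e-12)))
}

# (nvox x ne) normalized input matrices from a complex 4D patch.
normalize_inputs <- function(patch, norm_in) {
  ne <- dim(patch)[4]
  nv <- prod(dim(patch)[1:3])
  mag <- matrix(abs(patch), nv, ne)
  pha <- matrix(Arg(patch), nv, ne)
  for (j in seq_len(ne)) {
    mag[, j] <- (mag[, j] - norm_in$mag[j, "mu"]) / norm_in$mag[j, "sd"]
    pha[, j] <- (pha[, j] - norm_in$phase[j, "mu"]) / norm_in$phase[j, "sd"]
  }
  list(mag = mag, phase = pha)
}

patch_acq <- function(acq, patch_shape) {
  acq2 <- acq
  acq2$grid_shape <- as.integer(patch_shape)
  acq2
}

theta_to_params <- function(theta, shape, mask) {
  maps <- lapply(1:5, function(k) array(theta[, k], shape))
  names(maps) <- param_names
  maps$mask <- mask
  class(maps) <- "parameter_maps"
  maps
}

#' Train the dual network on phantom data
#'
#' Stochastic training with Adam on the total loss
#' `E = E_L1 + w_model * E_model + w_grad * E_grad`. Each epoch visits the
#' brains in a freshly shuffled order; for each brain a patch position is
#' drawn at random and a fresh complex-Gaussian noise instance at the
#' configured SNR is applied to the clean signal. All randomness derives
#' from `cfg$seed`, making the loss history reproducible bit-for-bit.
#'
#' @param model A [build_network()] model.
#' @param dataset A [make_training_set()] list.
#' @param cfg A [train_config()].
#' @param validation Optional validation dataset (same structure); its
#'   epoch-wise `E_L1` is recorded without affecting training.
#' @param consts [physio_constants()].
#' @return List with the trained `model` (carrying the frozen normalization
#'   statistics and patch shape) and `history`, a data frame of per-step
#'   losses with epoch means in `attr(history, "epoch_loss")`.
#' @export
train <- function(model, dataset, cfg = train_config(), validation = NULL,
                  consts = physio_constants()) {
  stopifnot(inherits(model, "qq_network"), length(dataset) >= 1L)
  ps <- cfg$patch_shape
  if (any(ps %% (2L^model$config$depth) != 0L))
    stop("patch_shape must be divisible by 2^depth")
  if (any(ps > dim(dataset[[1]]$mask)))
    stop("patch_shape exceeds the training volume")
  acq0 <- dataset[[1]]$signal$acq
  acqp <- patch_acq(acq0, ps)
  norm_in <- input_norm_stats(dataset)
  norm_params <- compute_norm_stats(lapply(dataset, `[[`, "params"))
  w <- cfg$weights
  pars <- list(mag = model$mag, phase = model$phase, merge = model$merge)
  opt <- adam_init()
  hist_step <- list()
  epoch_loss <- numeric(cfg$epochs)
  val_l1 <- rep(NA_real_, cfg$epochs)

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(dataset))
      step_losses <- numeric(0)
      for (bi in ord) {
        br <- dataset[[bi]]
        gs <- dim(br$mask)
        # random patch position containing brain voxels
        for (try in 1:50) {
          o <- vapply(1:3, function(d)
            if (gs[d] > ps[d]) sample.int(gs[d] - ps[d] + 1L, 1L) else 1L,
            integer(1))
          sl <- lapply(1:3, function(d) o[d]:(o[d] + ps[d] - 1L))
          mpatch <- br$mask[sl[[1]], sl[[2]], sl[[3]]]
          if (any(mpatch)) break
        }
        if (!any(mpatch)) next
        clean <- br$signal$data[sl[[1]], sl[[2]], sl[[3]], , drop = FALSE]
        sigma <- noise_sigma(br$sigma_ref, cfg$snr_db)
        n <- length(clean)
        noisy <- clean + complex(real = stats::rnorm(n, 0, sigma),
                                 imaginary = stats::rnorm(n, 0, sigma))
        xin <- normalize_inputs(noisy, norm_in)
        fwd <- network_forward(model, xin$mag, xin$phase, ps)

        truth_p <- parameter_maps(
          br$params$S0[sl[[1]], sl[[2]], sl[[3]]],
          br$params$R2[sl[[1]], sl[[2]], sl[[3]]],
          br$params$Y[sl[[1]], sl[[2]], sl[[3]]],
          br$params$v[sl[[1]], sl[[2]], sl[[3]]],
          br$params$chi_n[sl[[1]], sl[[2]], sl[[3]]], mpatch)
        out_p <- theta_to_params(fwd$theta, ps, mpatch)
        zT <- z_normalize(truth_p, norm_params)
        zO <- z_normalize(out_p, norm_params)
        nmask <- sum(mpatch)

        e_l1 <- loss_l1(zT, zO, mpatch)
        e_grad <- loss_grad(zT$Y, zO$Y, mpatch)
        e_model <- if (cfg$model_loss == "mcqq" && w$w_model > 0)
          loss_model_mcqq(truth_p, out_p, acqp, consts, mpatch) else 0
        loss <- total_loss(e_l1, e_model, e_grad, w)
        if (!is.finite(loss)) stop("training loss diverged (non-finite)")
        step_losses <- c(step_losses, loss)

        # gradient w.r.t. bounded outputs theta (nvox x 5)
        dtheta <- matrix(0, nrow(fwd$theta), 5L)
        for (k in 1:5) {
          nm <- param_names[k]
          dz <- sign(zO[[nm]] - zT[[nm]]) / (5 * nmask)
          dz[!mpatch] <- 0
          dtheta[, k] <- as.vector(dz) / norm_params[[nm]][["sd"]]
        }
        gY <- loss_grad_backward(zT$Y, zO$Y, mpatch) /
          norm_params$Y[["sd"]]
        dtheta[, 3] <- dtheta[, 3] + w$w_grad * as.vector(gY)
        if (cfg$model_loss == "mcqq" && w$w_model > 0) {
          gm <- loss_model_mcqq_backward(truth_p, out_p, acqp, consts,
                                         mpatch)
          for (k in 1:5)
            dtheta[, k] <- dtheta[, k] +
              w$w_model * as.vector(gm[[param_names[k]]])
        }
        bwd <- network_backward(model, fwd, dtheta)
        if (cfg$lr > 0) {
          st <- adam_step(opt, pars, bwd, cfg$lr)
          opt <- st$state; pars <- st$params
          model$mag <- pars$mag; model$phase <- pars$phase
          model$merge <- pars$merge
        }
      }
      epoch_loss[ep] <- mean(step_losses)
      hist_step[[ep]] <- step_losses
      if (!is.null(validation))
        val_l1[ep] <- validation_l1(model, validation, norm_in, norm_params,
                                    cfg)
    }
  })
  model$norm_in <- norm_in
  model$norm_params <- norm_params
  model$patch_shape <- ps
  history <- data.frame(step = seq_along(unlist(hist_step)),
                        loss = unlist(hist_step))
  attr(history, "epoch_loss") <- epoch_loss
  attr(history, "val_l1") <- val_l1
  list(model = model, history = history)
}

# Mean E_L1 of direct (single-patch) inference over a dataset, on clean
# signals; used as the validation metric.
validation_l1 <- function(model, dataset, norm_in, norm_params, cfg) {
  ps <- cfg$patch_shape
  mean(vapply(dataset, function(br) {
    gs <- dim(br$mask)
    o <- pmax((gs - ps) %/% 2L, 0L) + 1L
    sl <- lapply(1:3, function(d) o[d]:(o[d] + ps[d] - 1L))
    mpatch <- br$mask[sl[[1]], sl[[2]], sl[[3]]]
    if (!any(mpatch)) return(NA_real_)
    clean <- br$signal$data[sl[[1]], sl[[2]], sl[[3]], , drop = FALSE]
    xin <- normalize_inputs(clean, norm_in)
    fwd <- network_forward(model, xin$mag, xin$phase, ps)
    truth_p <- parameter_maps(
      br$params$S0[sl[[1]], sl[[2]], sl[[3]]],
      br$params$R2[sl[[1]], sl[[2]], sl[[3]]],
      br$params$Y[sl[[1]], sl[[2]], sl[[3]]],
      br$params$v[sl[[1]], sl[[2]], sl[[3]]],
      br$params$chi_n[sl[[1]], sl[[2]], sl[[3]]], mpatch)
    out_p <- theta_to_params(fwd$theta, ps, mpatch)
    loss_l1(z_normalize(truth_p, norm_params),
            z_normalize(out_p, norm_params), mpatch)
  }, numeric(1)), na.rm = TRUE)
}

#' Sliding-window whole-volume inference
#'
#' Covers the volume with overlapping patches, runs the network on each and
#' blends the bounded outputs by uniform averaging in overlap regions. With
#' a volume equal to one patch this reduces to direct inference; constant
#' inputs give seam-free constant output.
#'
#' @param model Trained [build_network()] model (carrying normalization
#'   statistics; override with `norm_in`).
#' @param signal A [signal_stack()].
#' @param overlap Fractional overlap between neighbouring patches, in
#'   `[0, 0.9]`.
#' @param patch_shape Spatial patch shape (default: the training patch).
#' @param norm_in Input normalization statistics.
#' @param mask Mask stored on the returned maps (default: all voxels).
#' @return A [parameter_maps()] of the blended predictions, plus attribute
#'   `"coverage"` (per-voxel patch counts).
#' @export
predict_sliding <- function(model, signal, overlap = 0.3,
                            patch_shape = model$patch_shape,
                            norm_in = model$norm_in, mask = NULL) {
  stopifnot(inherits(model, "qq_network"), inherits(signal, "signal_stack"))
  if (is.na(overlap) || overlap < 0 || overlap > 0.9)
    stop("overlap must lie in [0, 0.9]")
  if (is.null(norm_in)) stop("input normalization statistics required")
  gs <- dim(signal$data)[1:3]
  ps <- pmin(as.integer(patch_shape), gs)  # single-patch fallback
  if (any(ps %% (2L^model$config$depth) != 0L))
    stop("effective patch shape must be divisible by 2^depth")
  starts <- lapply(1:3, function(d) {
    if (gs[d] == ps[d]) return(1L)
    stride <- max(1L, as.integer(round(ps[d] * (1 - overlap))))
    s <- unique(c(seq(1L, gs[d] - ps[d] + 1L, by = stride),
                  gs[d] - ps[d] + 1L))
    as.integer(s)
  })
  acc <- lapply(1:5, function(k) array(0, gs))
  cov <- array(0, gs)
  for (ox in starts[[1]]) for (oy in starts[[2]]) for (oz in starts[[3]]) {
    sl <- list(ox:(ox + ps[1] - 1L), oy:(oy + ps[2] - 1L),
               oz:(oz + ps[3] - 1L))
    patch <- signal$data[sl[[1]], sl[[2]], sl[[3]], , drop = FALSE]
    xin <- normalize_inputs(patch, norm_in)
    fwd <- network_forward(model, xin$mag, xin$phase, ps)
    for (k in 1:5)
      acc[[k]][sl[[1]], sl[[2]], sl[[3]]] <-
        acc[[k]][sl[[1]], sl[[2]], sl[[3]]] + array(fwd$theta[, k], ps)
    cov[sl[[1]], sl[[2]], sl[[3]]] <- cov[sl[[1]], sl[[2]], sl[[3]]] + 1
  }
  if (any(cov == 0)) stop("internal error: incomplete coverage")
  maps <- lapply(acc, function(a) a / cov)
  names(maps) <- param_names
  if (is.null(mask)) mask <- array(TRUE, gs)
  out <- parameter_maps(maps$S0, maps$R2, maps$Y, maps$v, maps$chi_n, mask)
  attr(out, "coverage") <- cov
  out
}

#' Save / load a model checkpoint
#'
#' @param model A `qq_network`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "qq_network")) stop("not a network checkpoint")
  m
}
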