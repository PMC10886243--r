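# 3D convolutional network engine.
#
# Tensors are stored as (nvox x channels) matrices with an associated
# spatial shape (nx, ny, nz), voxels in column-major order, so that every
# convolution reduces to an im2col gather followed by one BLAS matrix
# multiplication. Backward passes are written by hand (the engine exists to
# train the dual sub-network model at configurable scale on a CPU).

# Cache of im2col/pooling index tables, keyed by spatial shape.
conv_indices <- function(shape) {
  key <- paste(shape, collapse = "x")
  if (is.null(.qsmqbold_env$conv_idx)) .qsmqbold_env$conv_idx <- list()
  hit <- .qsmqbold_env$conv_idx[[key]]
  if (!is.null(hit)) return(hit)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  sp <- shape + 2L
  i <- rep(seq_len(nx), times = ny * nz)
  j <- rep(rep(seq_len(ny), each = nx), times = nz)
  k <- rep(seq_len(nz), each = nx * ny)
  off <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  idx <- matrix(0L, nx * ny * nz, 27L)
  for (o in seq_len(27L)) {
    idx[, o] <- (i + off$a[o]) + (j + off$b[o] - 1L) * sp[1] +
      (k + off$c[o] - 1L) * sp[1] * sp[2]
  }
  interior <- (i + 1L) + j * sp[1] + k * sp[1] * sp[2]
  # 2x2x2 pooling tables (only when all dims are even)
  pool <- NULL
  if (all(shape %% 2L == 0L)) {
    hx <- nx %/% 2L; hy <- ny %/% 2L; hz <- nz %/% 2L
    pi <- rep(seq_len(hx), times = hy * hz)
    pj <- rep(rep(seq_len(hy), each = hx), times = hz)
    pk <- rep(seq_len(hz), each = hx * hy)
    poff <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
    pidx <- matrix(0L, hx * hy * hz, 8L)
    for (o in seq_len(8L)) {
      pidx[, o] <- (2L * pi - 1L + poff$a[o]) +
        (2L * pj - 2L + poff$b[o]) * nx +
        (2L * pk - 2L + poff$c[o]) * nx * ny
    }
    pool <- pidx
  }
  out <- list(idx = idx, interior = interior, n_pad = prod(sp), pool = pool)
  .qsmqbold_env$conv_idx[[key]] <- out
  out
}

conv3_forward <- function(x, shape, W, b) {
  ci <- conv_indices(shape)
  C <- ncol(x)
  pad <- matrix(0, ci$n_pad, C)
  pad[ci$interior, ] <- x
  X <- matrix(0, nrow(x), 27L * C)
  for (o in seq_len(27L))
    X[, ((o - 1L) * C + 1L):(o * C)] <- pad[ci$idx[, o], , drop = FALSE]
  y <- X %*% W
  y <- sweep(y, 2L, b, "+")
  list(y = y, X = X)
}

conv3_backward <- function(dy, X, W, shape, Cin) {
  ci <- conv_indices(shape)
  dW <- crossprod(X, dy)
  db <- colSums(dy)
  dX <- tcrossprod(dy, W)
  dpad <- matrix(0, ci$n_pad, Cin)
  for (o in seq_len(27L)) {
    cols <- ((o - 1L) * Cin + 1L):(o * Cin)
    dpad[ci$idx[, o], ] <- dpad[ci$idx[, o], , drop = FALSE] +
      dX[, cols, drop = FALSE]
  }
  list(dx = dpad[ci$interior, , drop = FALSE], dW = dW, db = db)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dy, y) dy * (y > 0)

maxpool_forward <- function(x, shape) {
  ci <- conv_indices(shape)
  if (is.null(ci$pool)) stop("maxpool requires even spatial dimensions")
  P <- ci$pool
  nvo <- nrow(P); C <- ncol(x)
  vals <- x[P[, 1], , drop = FALSE]
  arg <- matrix(1L, nvo, C)
  for (o in 2:8) {
    cand <- x[P[, o], , drop = FALSE]
    better <- cand > vals
    vals[better] <- cand[better]
    arg[better] <- o
  }
  list(y = vals, arg = arg, P = P, n_in = nrow(x))
}

maxpool_backward <- function(dy, pool_cache) {
  P <- pool_cache$P; arg <- pool_cache$arg
  nvo <- nrow(P); C <- ncol(dy)
  dx <- matrix(0, pool_cache$n_in, C)
  rows <- seq_len(nvo)
  for (cch in seq_len(C)) {
    src <- P[cbind(rows, arg[, cch])]
    dx[src, cch] <- dy[, cch]
  }
  dx
}

# Transposed convolution, 2x2x2 kernel, stride 2 (each output voxel receives
# exactly one contribution). W has dim (Cin, 8 * Cout).
deconv_indices <- function(shape_in) {
  key <- paste("up", paste(shape_in, collapse = "x"))
  if (is.null(.qsmqbold_env$conv_idx)) .qsmqbold_env$conv_idx <- list()
  hit <- .qsmqbold_env$conv_idx[[key]]
  if (!is.null(hit)) return(hit)
  nx <- shape_in[1]; ny <- shape_in[2]; nz <- shape_in[3]
  ox <- 2L * nx; oy <- 2L * ny
  i <- rep(seq_len(nx), times = ny * nz)
  j <- rep(rep(seq_len(ny), each = nx), times = nz)
  k <- rep(seq_len(nz), each = nx * ny)
  off <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  oidx <- matrix(0L, nx * ny * nz, 8L)
  for (o in seq_len(8L)) {
    oidx[, o] <- (2L * i - 1L + off$a[o]) + (2L * j - 2L + off$b[o]) * ox +
      (2L * k - 2L + off$c[o]) * ox * oy
  }
  .qsmqbold_env$conv_idx[[key]] <- oidx
  oidx
}

deconv_forward <- function(x, shape_in, W, b) {
  oidx <- deconv_indices(shape_in)
  Cout <- length(b)
  y8 <- x %*% W
  out <- matrix(0, 8L * nrow(x), Cout)
  for (o in seq_len(8L))
    out[oidx[, o], ] <- y8[, ((o - 1L) * Cout + 1L):(o * Cout), drop = FALSE]
  out <- sweep(out, 2L, b, "+")
  list(y = out, x = x)
}

deconv_backward <- function(dy, x, shape_in, W, Cout) {
  oidx <- deconv_indices(shape_in)
  dy8 <- matrix(0, nrow(x), 8L * Cout)
  for (o in seq_len(8L))
    dy8[, ((o - 1L) * Cout + 1L):(o * Cout)] <- dy[oidx[, o], , drop = FALSE]
  list(dx = tcrossprod(dy8, W), dW = crossprod(x, dy8), db = colSums(dy))
}

# One U-Net sub-network -------------------------------------------------

he_w <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0,
                                                     sqrt(2 / fan)),
                                        nin, nout)

unet_init <- function(in_ch, out_ch, depth, base_channels) {
  P <- list()
  ch_in <- in_ch
  for (l in seq_len(depth)) {
    ch <- base_channels * 2^(l - 1)
    P[[sprintf("enc%d_c1", l)]] <- list(W = he_w(27 * ch_in, ch, 27 * ch_in),
                                        b = numeric(ch), Cin = ch_in)
    P[[sprintf("enc%d_c2", l)]] <- list(W = he_w(27 * ch, ch, 27 * ch),
                                        b = numeric(ch), Cin = ch)
    ch_in <- ch
  }
  chb <- base_channels * 2^depth
  P[["bot_c1"]] <- list(W = he_w(27 * ch_in, chb, 27 * ch_in),
                        b = numeric(chb), Cin = ch_in)
  P[["bot_c2"]] <- list(W = he_w(27 * chb, chb, 27 * chb),
                        b = numeric(chb), Cin = chb)
  ch_in <- chb
  for (l in rev(seq_len(depth))) {
    ch <- base_channels * 2^(l - 1)
    P[[sprintf("up%d", l)]] <- list(W = he_w(ch_in, 8 * ch, ch_in),
                                    b = numeric(ch), Cin = ch_in, Cout = ch)
    P[[sprintf("dec%d_c1", l)]] <- list(W = he_w(27 * 2 * ch, ch, 27 * 2 * ch),
                                        b = numeric(ch), Cin = 2 * ch)
    P[[sprintf("dec%d_c2", l)]] <- list(W = he_w(27 * ch, ch, 27 * ch),
                                        b = numeric(ch), Cin = ch)
    ch_in <- ch
  }
  P[["final"]] <- list(W = he_w(base_channels, out_ch, base_channels),
                       b = numeric(out_ch), Cin = base_channels)
  P
}

unet_forward <- function(P, x, shape, depth) {
  cache <- list(shapes = list(), skips = list())
  cur <- x; cur_shape <- shape
  for (l in seq_len(depth)) {
    for (s in 1:2) {
      nm <- sprintf("enc%d_c%d", l, s)
      cf <- conv3_forward(cur, cur_shape, P[[nm]]$W, P[[nm]]$b)
      cur <- relu_forward(cf$y)
      cache[[nm]] <- list(X = cf$X, y = cur, shape = cur_shape)
    }
    cache$skips[[l]] <- cur
    pf <- maxpool_forward(cur, cur_shape)
    cache[[sprintf("pool%d", l)]] <- pf
    cur <- pf$y
    cur_shape <- cur_shape %/% 2L
  }
  for (s in 1:2) {
    nm <- sprintf("bot_c%d", s)
    cf <- conv3_forward(cur, cur_shape, P[[nm]]$W, P[[nm]]$b)
    cur <- relu_forward(cf$y)
    cache[[nm]] <- list(X = cf$X, y = cur, shape = cur_shape)
  }
  for (l in rev(seq_len(depth))) {
    nm <- sprintf("up%d", l)
    df <- deconv_forward(cur, cur_shape, P[[nm]]$W, P[[nm]]$b)
    cache[[nm]] <- list(x = cur, shape_in = cur_shape)
    cur_shape <- cur_shape * 2L
    cur <- cbind(df$y, cache$skips[[l]])
    for (s in 1:2) {
      nm <- sprintf("dec%d_c%d", l, s)
      cf <- conv3_forward(cur, cur_shape, P[[nm]]$W, P[[nm]]$b)
      cur <- relu_forward(cf$y)
      cache[[nm]] <- list(X = cf$X, y = cur, shape = cur_shape)
    }
  }
  out <- sweep(cur %*% P[["final"]]$W, 2L, P[["final"]]$b, "+")
  cache$final_in <- cur
  cache$out <- out
  cache
}

unet_backward <- function(P, cache, dout, depth) {
  G <- list()
  G[["final"]] <- list(W = crossprod(cache$final_in, dout),
                       b = colSums(dout))
  cur <- tcrossprod(dout, P[["final"]]$W)
  dskip <- vector("list", depth)
  for (l in seq_len(depth)) {
    for (s in 2:1) {
      nm <- sprintf("dec%d_c%d", l, s)
      cc <- cache[[nm]]
      cur <- relu_backward(cur, cc$y)
      bb <- conv3_backward(cur, cc$X, P[[nm]]$W, cc$shape, P[[nm]]$Cin)
      G[[nm]] <- list(W = bb$dW, b = bb$db)
      cur <- bb$dx
    }
    ch <- ncol(cur) %/% 2L
    dup <- cur[, seq_len(ch), drop = FALSE]
    dskip[[l]] <- cur[, ch + seq_len(ch), drop = FALSE]
    nm <- sprintf("up%d", l)
    cc <- cache[[nm]]
    bb <- deconv_backward(dup, cc$x, cc$shape_in, P[[nm]]$W, P[[nm]]$Cout)
    G[[nm]] <- list(W = bb$dW, b = bb$db)
    cur <- bb$dx
  }
  for (s in 2:1) {
    nm <- sprintf("bot_c%d", s)
    cc <- cache[[nm]]
    cur <- relu_backward(cur, cc$y)
    bb <- conv3_backward(cur, cc$X, P[[nm]]$W, cc$shape, P[[nm]]$Cin)
    G[[nm]] <- list(W = bb$dW, b = bb$db)
    cur <- bb$dx
  }
  for (l in rev(seq_len(depth))) {
    cur <- maxpool_backward(cur, cache[[sprintf("pool%d", l)]])
    cur <- cur + dskip[[l]]
    for (s in 2:1) {
      nm <- sprintf("enc%d_c%d", l, s)
      cc <- cache[[nm]]
      cur <- relu_backward(cur, cc$y)
      bb <- conv3_backward(cur, cc$X, P[[nm]]$W, cc$shape, P[[nm]]$Cin)
      G[[nm]] <- list(W = bb$dW, b = bb$db)
      cur <- bb$dx
    }
  }
  G
}
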