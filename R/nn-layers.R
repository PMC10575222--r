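# Reverse-mode neural network primitives.
#
# Convolutional activations use a channels-first (C, H, W, N) layout: with
# channels fastest, every im2col block and every conv output reshapes into a
# matrix without permuting memory, so the hot path is sub-array copies plus
# BLAS gemm. Dense stages use (N, D) matrices. Each *_fwd returns the output
# plus the cache its *_bwd needs; *_bwd returns the input gradient and named
# parameter gradients. All parameters live in a flat named list so the
# optimizer, checkpointing and freezing can treat them uniformly.

init_mat <- function(din, dout) {
  # fan-in-scaled uniform init
  s <- sqrt(6 / din)
  matrix(runif(din * dout, -s, s), din, dout)
}

# 3x3 kernel stored as a (9 * cin, cout) matrix whose rows follow the
# im2col block order (channel fastest, then kernel row, then kernel column).
init_conv <- function(cin, cout) init_mat(9 * cin, cout)

# spatial-first (H, W, B, N) user batch -> internal channels-first layout
to_channels_first <- function(x) aperm(x, c(3, 1, 2, 4))

# ---- 3x3 same-padding convolution -----------------------------------------

# The nine kernel offsets are evaluated as nine (C, H*W*N) slices of the
# zero-padded input; the convolution is then nine gemm accumulations. The
# slices are cached for the weight-gradient gemms in the backward pass.
conv_slices <- function(x) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  xp <- array(0, c(C, H + 2, W + 2, N))
  xp[, 2:(H + 1), 2:(W + 1), ] <- x
  sl <- vector("list", 9L)
  k <- 0L
  for (dx in 1:3) for (dy in 1:3) {
    k <- k + 1L
    s <- xp[, dy:(dy + H - 1), dx:(dx + W - 1), , drop = FALSE]
    dim(s) <- c(C, H * W * N)
    sl[[k]] <- s
  }
  sl
}

conv3_fwd <- function(x, W, b) {
  d <- dim(x)
  C <- d[1]
  sl <- conv_slices(x)
  ym <- 0
  for (k in 1:9) {
    ym <- ym + crossprod(W[((k - 1L) * C + 1L):(k * C), , drop = FALSE],
                         sl[[k]])
  }
  ym <- ym + b                               # (cout, HWN)
  dim(ym) <- c(ncol(W), d[2], d[3], d[4])
  list(out = ym, cache = list(sl = sl, W = W, dims = d))
}

conv3_bwd <- function(dy, cache, need_dx = TRUE) {
  d <- cache$dims
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  cout <- ncol(cache$W)
  dim(dy) <- c(cout, H * W * N)
  db <- rowSums(dy)
  dW <- matrix(0, 9 * C, cout)
  dyt <- t(dy)
  dxp <- if (need_dx) array(0, c(C, H + 2, W + 2, N)) else NULL
  k <- 0L
  for (dx in 1:3) for (dyo in 1:3) {
    k <- k + 1L
    rows <- ((k - 1L) * C + 1L):(k * C)
    dW[rows, ] <- cache$sl[[k]] %*% dyt
    if (need_dx) {
      blk <- cache$W[rows, , drop = FALSE] %*% dy
      dim(blk) <- c(C, H, W, N)
      dxp[, dyo:(dyo + H - 1), dx:(dx + W - 1), ] <-
        dxp[, dyo:(dyo + H - 1), dx:(dx + W - 1), ] + blk
    }
  }
  list(dx = if (need_dx) dxp[, 2:(H + 1), 2:(W + 1), , drop = FALSE],
       dW = dW, db = db)
}

# ---- 3x3 stride-2 max pooling ---------------------------------------------

# Output size is ceil((in - 1) / 2): window starts 1, 3, 5, ... with the last
# window clipped at the border. Geometry (candidate plane-index table) is
# cached per spatial size.
.pool_geom_cache <- new.env(parent = emptyenv())

pool_geom <- function(H, W) {
  key <- paste(H, W, sep = "x")
  g <- .pool_geom_cache[[key]]
  if (!is.null(g)) return(g)
  oh <- ceiling((H - 1) / 2); ow <- ceiling((W - 1) / 2)
  ys <- 2 * seq_len(oh) - 1; xs <- 2 * seq_len(ow) - 1
  P <- oh * ow
  idx <- matrix(NA_integer_, P, 9)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    y <- ys + dy; x <- xs + dx
    yv <- ifelse(y <= H, y, NA_integer_)
    xv <- ifelse(x <= W, x, NA_integer_)
    idx[, k] <- as.integer(outer(yv, (xv - 1L) * H, "+"))
  }
  g <- list(oh = oh, ow = ow, idx = idx)
  .pool_geom_cache[[key]] <- g
  g
}

pool_fwd <- function(x) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  g <- pool_geom(H, W)
  P <- g$oh * g$ow
  x2 <- matrix(x, C)                         # column = plane + (n-1) * H * W
  noff <- (seq_len(N) - 1L) * (H * W)
  poff <- (seq_len(N) - 1L) * P
  best <- matrix(-Inf, C, P * N)
  arg <- matrix(1L, C, P * N)
  for (k in 1:9) {
    li <- g$idx[, k]
    pv <- which(!is.na(li))
    if (!length(pv)) next
    cols <- as.vector(outer(li[pv], noff, "+"))
    bcols <- as.vector(outer(pv, poff, "+"))
    vals <- x2[, cols, drop = FALSE]
    bsub <- best[, bcols, drop = FALSE]
    upd <- vals > bsub
    if (any(upd)) {
      asub <- arg[, bcols, drop = FALSE]
      ia <- matrix(cols, C, length(cols), byrow = TRUE)
      bsub[upd] <- vals[upd]
      asub[upd] <- ia[upd]
      best[, bcols] <- bsub
      arg[, bcols] <- asub
    }
  }
  list(out = array(best, c(C, g$oh, g$ow, N)),
       cache = list(arg = arg, dims = d))
}

pool_bwd <- function(dy, cache) {
  d <- cache$dims
  C <- d[1]
  dy2 <- matrix(dy, C)
  gi <- (cache$arg - 1L) * C + seq_len(C)    # flat channels-first index
  acc <- rowsum(as.vector(dy2), as.vector(gi))  # overlap-safe scatter-add
  dxf <- numeric(prod(d))
  dxf[as.integer(rownames(acc))] <- acc
  list(dx = array(dxf, d))
}

# ---- batch normalization (per conv channel) -------------------------------

bn_fwd <- function(x, gamma, beta, rm, rv, training, update_stats = TRUE,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[1]
  m <- matrix(x, C)                          # (C, H*W*N)
  if (training) {
    mu <- rowMeans(m)
    va <- rowMeans(m^2) - mu^2
    if (update_stats) {
      rm <- (1 - momentum) * rm + momentum * mu
      rv <- (1 - momentum) * rv + momentum * va
    }
  } else {
    mu <- rm; va <- rv
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (m - mu) * istd                    # length-C vectors recycle by row
  y <- xhat * gamma + beta
  list(out = array(y, d), rm = rm, rv = rv,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, dims = d,
                    training = training))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  C <- d[1]
  dm <- matrix(dy, C)
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  if (cache$training) {
    n <- ncol(dm)
    dxh <- (dm - dbeta / n) - xhat * (dgamma / n)
  } else {
    dxh <- dm
  }
  dx <- dxh * (cache$gamma * cache$istd)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- dense layers ----------------------------------------------------------

fc_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, "+"), cache = list(x = x, W = W))
}

fc_bwd <- function(dy, cache) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

flatten_fwd <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, prod(d[1:3]), d[4])), cache = d)
}
flatten_bwd <- function(dy, dims) array(t(dy), dims)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(par) {
  zeros <- lapply(par, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

# One Adam step over the names present in `grads`; parameters without a
# gradient entry (frozen blocks, heads not in use) are left untouched.
# `lr_mult` maps parameter-name prefixes to learning-rate multipliers
# (two-time-scale updates for adversarial heads).
adam_step <- function(opt, par, grads, lr, beta1, beta2, eps = 1e-8,
                      lr_mult = NULL) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    lr_nm <- lr
    if (!is.null(lr_mult)) {
      hit <- which(startsWith(nm, names(lr_mult)))
      if (length(hit)) lr_nm <- lr * lr_mult[[hit[1]]]
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr_nm * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, par = par)
}

# Merge named gradient lists, summing entries that appear more than once
# (a parameter reached through several heads).
merge_grads <- function(...) {
  gs <- list(...)
  out <- list()
  for (g in gs) {
    for (nm in names(g)) {
      out[[nm]] <- if (is.null(out[[nm]])) g[[nm]] else out[[nm]] + g[[nm]]
    }
  }
  out
}
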