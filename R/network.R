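# Architecture: a convolutional base extractor G consumes the seed cube with
# spectral bands as input channels (blocks of conv 3x3 (32 kernels) -> batch
# norm -> ReLU -> max-pool 3x3 stride 2), followed by flatten. Three branch
# extractors G_n (shared), G_c (class-specific), G_d (domain-specific) map
# the flat code through a small dense stack to feature_dim. Heads: h2 (class,
# C outputs) on [F_n; F_c], h3 (domain, 2 outputs) on [F_n; F_d], h1
# (domain-class, 2C outputs) on [F_n; F_c; F_d]; each head is FC 20 -> ReLU
# -> output layer -> softmax.

conv_out_shape <- function(hw, n_blocks) {
  for (i in seq_len(n_blocks)) hw <- ceiling((hw - 1) / 2)
  hw
}

#' Build an adaptive domain feature separation model
#'
#' Constructs the parameter container for the base extractor `G`, the three
#' branch extractors `G_n`, `G_c`, `G_d`, and the heads `h1` (domain-class,
#' `2 * n_classes` outputs), `h2` (class, `n_classes` outputs) and `h3`
#' (domain, 2 outputs). Weights use fan-in-scaled uniform initialization and
#' are a deterministic function of `seed`. The domain-class label for `h1`
#' uses the fixed encoding `index = domain_index * C + variety_index`
#' (domain 0 = source, 1 = target).
#'
#' @param n_classes number of varieties C (>= 2).
#' @param n_bands spectral bands (input channels of the first conv).
#' @param feature_dim width of each branch output vector, default 64.
#' @param seed initialization seed.
#' @param input_shape spatial `(rows, cols)` the model will consume,
#'   default the canonical `c(60, 80)`.
#' @param conv_channels kernels per conv block, default 32.
#' @param n_blocks number of conv blocks in `G`, default 3.
#' @param branch_hidden hidden width of the branch extractors, default 128.
#' @param head_hidden hidden width of the classifier heads, default 20.
#' @return An object of class `adfs_model`.
#' @examples
#' m <- build_model(4, 94, feature_dim = 32, seed = 1, input_shape = c(12, 16))
#' m$config$n_params
#' @export
build_model <- function(n_classes, n_bands, feature_dim = 64L, seed = 0L,
                        input_shape = c(60L, 80L), conv_channels = 32L,
                        n_blocks = 3L, branch_hidden = 128L, head_hidden = 20L) {
  if (n_classes < 2L || n_bands < 1L || feature_dim < 1L || conv_channels < 1L ||
      n_blocks < 1L || branch_hidden < 1L || head_hidden < 1L) {
    abort("Model dimensions must be positive (and n_classes >= 2).",
          class = "adfs_construction_error")
  }
  cfg <- list(n_classes = as.integer(n_classes), n_bands = as.integer(n_bands),
              feature_dim = as.integer(feature_dim),
              input_shape = as.integer(input_shape),
              conv_channels = as.integer(conv_channels),
              n_blocks = as.integer(n_blocks),
              branch_hidden = as.integer(branch_hidden),
              head_hidden = as.integer(head_hidden))
  oh <- conv_out_shape(input_shape[1], n_blocks)
  ow <- conv_out_shape(input_shape[2], n_blocks)
  if (oh < 1 || ow < 1) {
    abort("Input spatial shape too small for the number of conv blocks.",
          class = "adfs_construction_error")
  }
  cfg$flat_dim <- as.integer(oh * ow * conv_channels)
  par <- list(); buf <- list()
  with_seed(seed, {
    cin <- cfg$n_bands
    for (i in seq_len(n_blocks)) {
      par[[sprintf("G.conv%d.W", i)]] <- init_conv(cin, conv_channels)
      par[[sprintf("G.conv%d.b", i)]] <- numeric(conv_channels)
      par[[sprintf("G.bn%d.gamma", i)]] <- rep(1, conv_channels)
      par[[sprintf("G.bn%d.beta", i)]] <- numeric(conv_channels)
      buf[[sprintf("G.bn%d.rm", i)]] <- numeric(conv_channels)
      buf[[sprintf("G.bn%d.rv", i)]] <- rep(1, conv_channels)
      cin <- conv_channels
    }
    for (br in c("Gn", "Gc", "Gd")) {
      par[[paste0(br, ".fc1.W")]] <- init_mat(cfg$flat_dim, branch_hidden)
      par[[paste0(br, ".fc1.b")]] <- numeric(branch_hidden)
      par[[paste0(br, ".fc2.W")]] <- init_mat(branch_hidden, feature_dim)
      par[[paste0(br, ".fc2.b")]] <- numeric(feature_dim)
    }
    head_dims <- list(h1 = c(3L * feature_dim, 2L * n_classes),
                      h2 = c(2L * feature_dim, n_classes),
                      h3 = c(2L * feature_dim, 2L))
    for (hn in names(head_dims)) {
      hd <- head_dims[[hn]]
      par[[paste0(hn, ".fc1.W")]] <- init_mat(hd[1], head_hidden)
      par[[paste0(hn, ".fc1.b")]] <- numeric(head_hidden)
      par[[paste0(hn, ".out.W")]] <- init_mat(head_hidden, hd[2])
      par[[paste0(hn, ".out.b")]] <- numeric(hd[2])
    }
  })
  cfg$n_params <- sum(vapply(par, length, 1L))
  structure(list(par = par, buf = buf, config = cfg), class = "adfs_model")
}

#' @export
print.adfs_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<adfs_model: %d classes, %d bands, %d x %d input, ",
                     "%d conv blocks x %d ch, feature_dim %d, %d parameters>\n"),
              cfg$n_classes, cfg$n_bands, cfg$input_shape[1], cfg$input_shape[2],
              cfg$n_blocks, cfg$conv_channels, cfg$feature_dim, cfg$n_params))
  invisible(x)
}

# Copy the conv-block weights and batch-norm state of a source-trained
# model into another model sharing the same extractor family.
warm_start_extractor <- function(model, source_model) {
  src_cfg <- source_model$config
  cfg <- model$config
  if (!identical(src_cfg$input_shape, cfg$input_shape) ||
      src_cfg$n_bands != cfg$n_bands ||
      src_cfg$conv_channels != cfg$conv_channels ||
      src_cfg$n_blocks != cfg$n_blocks) {
    abort("Warm-start source model has an incompatible extractor geometry.",
          class = "adfs_construction_error")
  }
  g_names <- grep("^G\\.", names(source_model$par), value = TRUE)
  model$par[g_names] <- source_model$par[g_names]
  model$buf[names(source_model$buf)] <- source_model$buf
  model
}

# ---- base extractor --------------------------------------------------------

g_fwd <- function(x, par, buf, cfg, training, frozen_blocks = 0L) {
  caches <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    cv <- conv3_fwd(x, par[[sprintf("G.conv%d.W", i)]],
                    par[[sprintf("G.conv%d.b", i)]])
    bn <- bn_fwd(cv$out, par[[sprintf("G.bn%d.gamma", i)]],
                 par[[sprintf("G.bn%d.beta", i)]],
                 buf[[sprintf("G.bn%d.rm", i)]],
                 buf[[sprintf("G.bn%d.rv", i)]],
                 training = training, update_stats = training && i > frozen_blocks)
    buf[[sprintf("G.bn%d.rm", i)]] <- bn$rm
    buf[[sprintf("G.bn%d.rv", i)]] <- bn$rv
    rl <- relu_fwd(bn$out)
    pl <- pool_fwd(rl$out)
    caches[[i]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache,
                        pl = pl$cache)
    x <- pl$out
  }
  fl <- flatten_fwd(x)
  list(out = fl$out, caches = caches, flat_dims = fl$cache, buf = buf)
}

# Backpropagate through G. Blocks below `min_block` are treated as frozen:
# their parameter gradients are omitted and the pass stops early.
g_bwd <- function(dflat, fw, par, cfg, min_block = 1L) {
  grads <- list()
  dx <- flatten_bwd(dflat, fw$flat_dims)
  for (i in rev(seq_len(cfg$n_blocks))) {
    if (i < min_block) break
    ch <- fw$caches[[i]]
    dx <- pool_bwd(dx, ch$pl)$dx
    dx <- relu_bwd(dx, ch$rl)
    bb <- bn_bwd(dx, ch$bn)
    grads[[sprintf("G.bn%d.gamma", i)]] <- bb$dgamma
    grads[[sprintf("G.bn%d.beta", i)]] <- bb$dbeta
    cb <- conv3_bwd(bb$dx, ch$cv, need_dx = i > min_block)
    grads[[sprintf("G.conv%d.W", i)]] <- cb$dW
    grads[[sprintf("G.conv%d.b", i)]] <- cb$db
    dx <- cb$dx
  }
  list(grads = grads, dx = dx)
}

# ---- dense branch / head stacks -------------------------------------------

mlp_fwd <- function(z, par, prefix, layers, final_act = "linear") {
  caches <- list()
  n <- length(layers)
  for (j in seq_len(n)) {
    fc <- fc_fwd(z, par[[sprintf("%s.%s.W", prefix, layers[j])]],
                 par[[sprintf("%s.%s.b", prefix, layers[j])]])
    caches[[j]] <- list(fc = fc$cache)
    z <- fc$out
    if (j < n || final_act == "relu") {
      rl <- relu_fwd(z)
      caches[[j]]$rl <- rl$cache
      z <- rl$out
    }
  }
  list(out = z, caches = caches, prefix = prefix, layers = layers)
}

mlp_bwd <- function(dy, fw) {
  grads <- list()
  for (j in rev(seq_along(fw$layers))) {
    ch <- fw$caches[[j]]
    if (!is.null(ch$rl)) dy <- relu_bwd(dy, ch$rl)
    fb <- fc_bwd(dy, ch$fc)
    grads[[sprintf("%s.%s.W", fw$prefix, fw$layers[j])]] <- fb$dW
    grads[[sprintf("%s.%s.b", fw$prefix, fw$layers[j])]] <- fb$db
    dy <- fb$dx
  }
  list(grads = grads, dx = dy)
}

branch_fwd <- function(z, par, prefix) mlp_fwd(z, par, prefix, c("fc1", "fc2"))
head_fwd <- function(z, par, prefix) mlp_fwd(z, par, prefix, c("fc1", "out"))

# ---- feature separation (inference surface) --------------------------------

as_batch_array <- function(x, cfg) {
  if (inherits(x, "seed_cube")) x <- x$values
  if (is.array(x) && length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_shape[1] ||
      d[2] != cfg$input_shape[2] || d[3] != cfg$n_bands) {
    abort(sprintf("Expected cubes of %d x %d x %d, got %s.",
                  cfg$input_shape[1], cfg$input_shape[2], cfg$n_bands,
                  paste(d, collapse = " x ")),
          class = "adfs_geometry_error")
  }
  to_channels_first(x)
}

#' Separate a seed cube into shared and private features
#'
#' Runs the base extractor and the three branch extractors in inference mode
#' (batch norm uses running statistics, so results are independent of how
#' samples are batched) and returns the feature triple
#' `F_n = G_n(G(x))`, `F_c = G_c(G(x))`, `F_d = G_d(G(x))`.
#'
#' @param model an [build_model()] result.
#' @param x a [seed_cube()], a 3-D array, or a 4-D `(rows, cols, bands, n)`
#'   batch array (already standardized the same way as during training).
#' @return An object of class `separated_features` with matrices `F_n`,
#'   `F_c`, `F_d` of `n` rows; for a single cube the matrices have one row.
#' @export
separate <- function(model, x) {
  stopifnot(inherits(model, "adfs_model"))
  separate_cf(model, as_batch_array(x, model$config))
}

# channels-first fast path used by the prediction helpers
separate_cf <- function(model, xcf) {
  fw <- g_fwd(xcf, model$par, model$buf, model$config, training = FALSE)
  out <- list(F_n = branch_fwd(fw$out, model$par, "Gn")$out,
              F_c = branch_fwd(fw$out, model$par, "Gc")$out,
              F_d = branch_fwd(fw$out, model$par, "Gd")$out)
  if (any(!is.finite(out$F_n)) || any(!is.finite(out$F_c)) ||
      any(!is.finite(out$F_d))) {
    abort("Non-finite values in separated features.", class = "adfs_numeric_error")
  }
  structure(out, class = "separated_features")
}

feat_mat <- function(f, which) {
  m <- f[[which]]
  if (is.null(dim(m))) m <- matrix(m, 1L)
  m
}

#' Classifier heads over separated features
#'
#' `classify_class()` applies the class head `h2` to `[F_n; F_c]` and returns
#' per-variety probabilities (length C). `classify_domain()` applies `h3` to
#' `[F_n; F_d]` (length 2, source/target). `classify_domain_class()` applies
#' `h1` to `[F_n; F_c; F_d]` (length `2C`, encoding
#' `domain_index * C + variety_index`). All outputs are softmax-normalized
#' rows summing to 1.
#'
#' @param model an `adfs_model`.
#' @param f a `separated_features` object from [separate()].
#' @return A probability matrix with one row per sample.
#' @export
classify_class <- function(model, f) {
  z <- cbind(feat_mat(f, "F_n"), feat_mat(f, "F_c"))
  softmax_rows(head_fwd(z, model$par, "h2")$out)
}

#' @rdname classify_class
#' @export
classify_domain <- function(model, f) {
  z <- cbind(feat_mat(f, "F_n"), feat_mat(f, "F_d"))
  softmax_rows(head_fwd(z, model$par, "h3")$out)
}

#' @rdname classify_class
#' @export
classify_domain_class <- function(model, f) {
  z <- cbind(feat_mat(f, "F_n"), feat_mat(f, "F_c"), feat_mat(f, "F_d"))
  softmax_rows(head_fwd(z, model$par, "h1")$out)
}

#' Gradient reversal operator
#'
#' The adversarial coupling used by the DANN baseline: the forward pass is
#' the identity, while during backpropagation the gradient flowing through
#' the operator is multiplied by `-lambda`. In this package's explicit
#' reverse-mode engine the two directions are separate functions:
#' `gradient_reverse()` is the forward map and
#' `gradient_reverse_backward()` is applied to the upstream gradient where
#' the training loop crosses the reversal point.
#'
#' @param x numeric vector/matrix of features.
#' @param lambda nonnegative reversal strength.
#' @return `gradient_reverse()`: `x` unchanged. `gradient_reverse_backward()`:
#'   `-lambda * grad`.
#' @export
gradient_reverse <- function(x, lambda = 1) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  x
}

#' @rdname gradient_reverse
#' @param grad upstream gradient arriving at the operator output.
#' @export
gradient_reverse_backward <- function(grad, lambda = 1) {
  -lambda * grad
}
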