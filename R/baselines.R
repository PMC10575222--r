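# The three comparison strategies: a plain supervised CNN (no transfer),
# parameter-update transfer (pre-training update = all parameters;
# fine-tuning update = shallow conv blocks frozen), and DANN (adversarial
# domain confusion through a gradient reversal layer).

#' Build the plain CNN classifier
#'
#' The no-transfer baseline and the initial model for the pre-training and
#' fine-tuning updates. Uses the same convolutional extractor family as the
#' separation network, followed by a dense classifier head
#' (FC 128 -> ReLU -> FC 20 -> ReLU -> FC C -> softmax).
#'
#' @inheritParams build_model
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(n_classes, n_bands, seed = 0L, input_shape = c(60L, 80L),
                      conv_channels = 32L, n_blocks = 3L,
                      branch_hidden = 128L, head_hidden = 20L, ...) {
  if (n_classes < 2L || n_bands < 1L) {
    abort("n_classes >= 2 and n_bands >= 1 required.",
          class = "adfs_construction_error")
  }
  cfg <- list(n_classes = as.integer(n_classes), n_bands = as.integer(n_bands),
              input_shape = as.integer(input_shape),
              conv_channels = as.integer(conv_channels),
              n_blocks = as.integer(n_blocks),
              branch_hidden = as.integer(branch_hidden),
              head_hidden = as.integer(head_hidden))
  oh <- conv_out_shape(input_shape[1], n_blocks)
  ow <- conv_out_shape(input_shape[2], n_blocks)
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
    par[["head.fc1.W"]] <- init_mat(cfg$flat_dim, branch_hidden)
    par[["head.fc1.b"]] <- numeric(branch_hidden)
    par[["head.fc2.W"]] <- init_mat(branch_hidden, head_hidden)
    par[["head.fc2.b"]] <- numeric(head_hidden)
    par[["head.out.W"]] <- init_mat(head_hidden, n_classes)
    par[["head.out.b"]] <- numeric(n_classes)
  })
  cfg$n_params <- sum(vapply(par, length, 1L))
  structure(list(par = par, buf = buf, config = cfg), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cnn_model: %d classes, %d bands, %d conv blocks, %d parameters>\n",
              cfg$n_classes, cfg$n_bands, cfg$n_blocks, cfg$n_params))
  invisible(x)
}

cnn_head_fwd <- function(z, par) mlp_fwd(z, par, "head", c("fc1", "fc2", "out"))

# Supervised step on labeled cubes; blocks <= frozen_blocks receive no
# gradient and keep their batch-norm statistics.
cnn_step <- function(par, buf, cfg, xb, yv, frozen_blocks = 0L) {
  fw <- g_fwd(xb, par, buf, cfg, training = TRUE, frozen_blocks = frozen_blocks)
  hf <- cnn_head_fwd(fw$out, par)
  p <- softmax_rows(hf$out)
  loss <- cross_entropy(one_hot(yv, cfg$n_classes), p)
  if (!is.finite(loss)) {
    abort("Non-finite classification loss.", class = "adfs_numeric_error")
  }
  dlog <- (p - one_hot(yv, cfg$n_classes)) / nrow(p)
  hb <- mlp_bwd(dlog, hf)
  gb <- g_bwd(hb$dx, fw, par, cfg, min_block = frozen_blocks + 1L)
  list(grads = merge_grads(hb$grads, gb$grads), buf = fw$buf, loss = loss)
}

run_cnn_epochs <- function(model, data, ids, config, epochs,
                           frozen_blocks = 0L) {
  cfg <- model$config
  vidx <- setNames(data$manifest$variety_index, data$manifest$sample_id)
  X <- to_channels_first(assemble_batch(data, ids, model$stats))
  yv <- unname(vidx[ids])
  bs <- min(config$batch_size, length(ids))
  n_steps <- ceiling(length(ids) / bs)
  par <- model$par; buf <- model$buf
  opt <- adam_init(par)
  log_rows <- vector("list", max(epochs, 0L))
  with_seed(config$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(ids))
      tot <- 0
      for (st in seq_len(n_steps)) {
        take <- ord[((st - 1L) * bs + 1L):min(st * bs, length(ids))]
        step <- cnn_step(par, buf, cfg, X[, , , take, drop = FALSE], yv[take],
                         frozen_blocks = frozen_blocks)
        buf <- step$buf
        upd <- adam_step(opt, par, step$grads, config$lr, config$beta1,
                         config$beta2)
        opt <- upd$opt; par <- upd$par
        tot <- tot + step$loss
      }
      log_rows[[ep]] <- tibble(epoch = ep, loss = tot / n_steps)
    }
  })
  model$par <- par; model$buf <- buf
  list(model = model, log = dplyr::bind_rows(log_rows))
}

#' Train the no-transfer CNN baseline
#'
#' Plain supervised training on a labeled id list, with per-band
#' standardization fitted on the training ids.
#'
#' @param data a [cube_set()].
#' @param split list with character vectors `train` and `test` (sample ids).
#' @param config a [train_config()].
#' @param model_args extra arguments to [build_cnn()].
#' @return A `cnn_fit`: trained `model`, per-epoch `log`, and `report`, the
#'   [evaluate()] result (per-class recall/precision, average accuracy) on
#'   the test list.
#' @export
train_cnn <- function(data, split, config, model_args = list()) {
  stopifnot(is.character(split$train), length(split$train) > 0L)
  man <- data$manifest
  model <- do.call(build_cnn, c(list(
    n_classes = length(attr(man, "class_names")),
    n_bands = attr(man, "band_count"), seed = config$seed), model_args))
  model$stats <- fit_band_stats(data, split$train)
  run <- run_cnn_epochs(model, data, split$train, config, config$epochs)
  report <- if (length(split$test %||% character(0))) {
    evaluate(run$model, split$test, data)
  } else NULL
  structure(list(model = run$model, log = run$log, report = report,
                 split = split, config = config),
            class = c("cnn_fit", "seed_fit"))
}

#' Transfer by updating a source-trained CNN on labeled target samples
#'
#' `update_pretrained()` continues training *all* parameters of a
#' source-trained CNN on a small labeled target set (the "pre-training
#' update"). `update_finetuned()` does the same but freezes the first
#' `frozen_blocks` shallow conv blocks bitwise (weights and batch-norm
#' statistics). Standardization statistics stay frozen from source training.
#'
#' @param model a trained `cnn_model` (from [train_cnn()]`$model`).
#' @param target_labeled nonempty character vector of labeled target ids.
#' @param config a [train_config()].
#' @param data a [cube_set()].
#' @param epochs update epochs; defaults to `config$epochs`. `0` returns the
#'   model unchanged.
#' @return The updated `cnn_model`.
#' @export
update_pretrained <- function(model, target_labeled, config, data,
                              epochs = config$epochs) {
  stopifnot(inherits(model, "cnn_model"))
  if (!length(target_labeled)) {
    abort("Empty update set.", class = "adfs_protocol_error")
  }
  if (epochs == 0L) return(model)
  run_cnn_epochs(model, data, target_labeled, config, epochs)$model
}

#' @rdname update_pretrained
#' @param frozen_blocks number of shallow conv blocks to freeze (>= 1,
#'   < total blocks).
#' @export
update_finetuned <- function(model, target_labeled, config, data,
                             frozen_blocks = 1L, epochs = config$epochs) {
  stopifnot(inherits(model, "cnn_model"))
  if (!length(target_labeled)) {
    abort("Empty update set.", class = "adfs_protocol_error")
  }
  if (frozen_blocks < 1L || frozen_blocks >= model$config$n_blocks) {
    abort(sprintf("frozen_blocks must be in [1, %d).", model$config$n_blocks),
          class = "adfs_protocol_error")
  }
  if (epochs == 0L) return(model)
  run_cnn_epochs(model, data, target_labeled, config, epochs,
                 frozen_blocks = frozen_blocks)$model
}

# ---- DANN ------------------------------------------------------------------

build_dann <- function(n_classes, n_bands, feature_dim = 64L, seed = 0L,
                       input_shape = c(60L, 80L), conv_channels = 32L,
                       n_blocks = 3L, branch_hidden = 128L, head_hidden = 20L,
                       ...) {
  base <- build_cnn(n_classes, n_bands, seed = seed, input_shape = input_shape,
                    conv_channels = conv_channels, n_blocks = n_blocks,
                    branch_hidden = branch_hidden, head_hidden = head_hidden)
  cfg <- base$config
  cfg$feature_dim <- as.integer(feature_dim)
  par <- base$par
  par[["head.fc1.W"]] <- NULL; par[["head.fc1.b"]] <- NULL
  par[["head.fc2.W"]] <- NULL; par[["head.fc2.b"]] <- NULL
  par[["head.out.W"]] <- NULL; par[["head.out.b"]] <- NULL
  with_seed(child_seed(seed, 17L), {
    par[["feat.fc1.W"]] <- init_mat(cfg$flat_dim, branch_hidden)
    par[["feat.fc1.b"]] <- numeric(branch_hidden)
    par[["feat.fc2.W"]] <- init_mat(branch_hidden, feature_dim)
    par[["feat.fc2.b"]] <- numeric(feature_dim)
    par[["hc.fc1.W"]] <- init_mat(feature_dim, head_hidden)
    par[["hc.fc1.b"]] <- numeric(head_hidden)
    par[["hc.out.W"]] <- init_mat(head_hidden, n_classes)
    par[["hc.out.b"]] <- numeric(n_classes)
    par[["hd.fc1.W"]] <- init_mat(feature_dim, head_hidden)
    par[["hd.fc1.b"]] <- numeric(head_hidden)
    par[["hd.out.W"]] <- init_mat(head_hidden, 2L)
    par[["hd.out.b"]] <- numeric(2L)
  })
  cfg$n_params <- sum(vapply(par, length, 1L))
  structure(list(par = par, buf = base$buf, config = cfg),
            class = "dann_model")
}

#' @export
print.dann_model <- function(x, ...) {
  cat(sprintf("<dann_model: %d classes, %d bands, feature_dim %d, %d parameters>\n",
              x$config$n_classes, x$config$n_bands, x$config$feature_dim,
              x$config$n_params))
  invisible(x)
}

#' Train the DANN baseline
#'
#' Domain-adversarial training: a shared feature extractor feeds a class
#' head (trained on label-bearing rows) and a domain head whose gradient
#' reaches the extractor through [gradient_reverse()] (all rows). Batches
#' mix source-train and target-update samples as in [train_adfs()]. As in
#' the reference DANN training procedure, the reversal strength follows the
#' schedule `lambda_p = lambda_grl * (2 / (1 + exp(-10 p)) - 1)` over
#' training progress `p`, reaching `config$lambda_grl` at the end; starting
#' the adversarial pressure at full strength destabilizes the minimax game.
#'
#' @param data a [cube_set()].
#' @param split a [make_transfer_split()].
#' @param config a [train_config()].
#' @param model_args extra arguments to the model constructor.
#' @param init_from optional source-trained [build_cnn()] model whose
#'   extractor weights seed the feature extractor (see [train_adfs()]).
#' @return A `dann_fit` with the trained `model`, per-epoch `log`, `split`
#'   and `config`.
#' @export
train_dann <- function(data, split, config, model_args = list(),
                       init_from = NULL) {
  man <- data$manifest
  model <- do.call(build_dann, c(list(
    n_classes = length(attr(man, "class_names")),
    n_bands = attr(man, "band_count"), seed = config$seed), model_args))
  if (!is.null(init_from)) model <- warm_start_extractor(model, init_from)
  cfg <- model$config
  stats <- fit_band_stats(data, split$source_train)
  model$stats <- stats
  vidx <- setNames(man$variety_index, man$sample_id)

  src_ids <- split$source_train
  tgt_ids <- c(split$target_labeled, split$target_unlabeled)
  pool_ids <- c(src_ids, tgt_ids)
  X <- to_channels_first(assemble_batch(data, pool_ids, stats))
  slot <- setNames(seq_along(pool_ids), pool_ids)
  yv_pool <- unname(vidx[pool_ids]); yv_pool[is.na(yv_pool)] <- 0L
  dom_pool <- as.integer(pool_ids %in% tgt_ids)
  lab_pool <- pool_ids %in% c(src_ids, split$target_labeled)

  bs <- min(config$batch_size, length(pool_ids))
  half <- if (length(tgt_ids)) max(1L, bs %/% 2L) else bs
  half_src <- min(half, length(src_ids))
  n_steps <- ceiling(length(src_ids) / half_src)

  par <- model$par; buf <- model$buf
  opt <- adam_init(par)
  log_rows <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      # reference DANN schedules over training progress p: reversal strength
      # ramps up while the learning rate anneals, keeping the minimax game
      # from oscillating once the domains are nearly confused
      p_prog <- (ep - 1) / max(1, config$epochs - 1)
      lam <- config$lambda_grl * (2 / (1 + exp(-10 * p_prog)) - 1)
      lr_ep <- config$lr / (1 + 10 * p_prog)^0.75
      ord <- sample(length(src_ids))
      lcl <- 0; ldo <- 0
      for (st in seq_len(n_steps)) {
        s_take <- ord[((st - 1L) * half_src + 1L):min(st * half_src, length(src_ids))]
        b_tgt <- if (length(tgt_ids)) {
          slot[sample(tgt_ids, min(half, length(s_take)),
                      replace = length(tgt_ids) < min(half, length(s_take)))]
        } else integer(0)
        idx <- c(slot[src_ids[s_take]], b_tgt)
        xb <- X[, , , idx, drop = FALSE]
        yv <- yv_pool[idx]; dom <- dom_pool[idx]; labm <- lab_pool[idx]

        fw <- g_fwd(xb, par, buf, cfg, training = TRUE)
        buf <- fw$buf
        ft <- mlp_fwd(fw$out, par, "feat", c("fc1", "fc2"))
        z <- ft$out
        dz <- matrix(0, nrow(z), ncol(z))
        grads <- list()
        # class head on label-bearing rows
        lab_rows <- which(labm)
        l_class <- 0
        if (length(lab_rows)) {
          hf <- head_fwd(z[lab_rows, , drop = FALSE], par, "hc")
          p <- softmax_rows(hf$out)
          l_class <- cross_entropy(one_hot(yv[lab_rows], cfg$n_classes), p)
          hb <- mlp_bwd((p - one_hot(yv[lab_rows], cfg$n_classes)) / nrow(p), hf)
          grads <- merge_grads(grads, hb$grads)
          dz[lab_rows, ] <- dz[lab_rows, ] + hb$dx
        }
        # domain head behind the gradient reversal layer, all rows
        hfd <- head_fwd(gradient_reverse(z, lam), par, "hd")
        pd <- softmax_rows(hfd$out)
        l_domain <- cross_entropy(one_hot(dom, 2L), pd)
        hbd <- mlp_bwd((pd - one_hot(dom, 2L)) / nrow(pd), hfd)
        grads <- merge_grads(grads, hbd$grads)
        dz <- dz + gradient_reverse_backward(hbd$dx, lam)

        ftb <- mlp_bwd(dz, ft)
        gb <- g_bwd(ftb$dx, fw, par, cfg)
        grads <- merge_grads(grads, ftb$grads, gb$grads)
        if (!is.finite(l_class) || !is.finite(l_domain)) {
          abort(sprintf("Non-finite DANN loss (%s).",
                        if (!is.finite(l_class)) "l_class" else "l_domain"),
                class = "adfs_numeric_error")
        }
        # two-time-scale updates: the domain discriminator moves faster than
        # the features it judges, so the game settles at confusion instead of
        # the degenerate inverted-boundary state
        upd <- adam_step(opt, par, grads, lr_ep, config$beta1, config$beta2,
                         lr_mult = c("hd." = 10))
        opt <- upd$opt; par <- upd$par
        lcl <- lcl + l_class; ldo <- ldo + l_domain
      }
      acc <- NA_real_
      if (config$log_target_accuracy && length(split$target_test)) {
        m_now <- model; m_now$par <- par; m_now$buf <- buf
        acc <- mean(predict_variety(m_now, data, split$target_test) ==
                      vidx[split$target_test])
      }
      log_rows[[ep]] <- tibble(epoch = ep, l_class = lcl / n_steps,
                               l_domain = ldo / n_steps,
                               total = (lcl + ldo) / n_steps,
                               target_accuracy = acc)
    }
  })
  model$par <- par; model$buf <- buf
  structure(list(model = model, log = dplyr::bind_rows(log_rows),
                 split = split, config = config, trained_ids = pool_ids),
            class = c("dann_fit", "seed_fit"))
}
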