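#' Training configuration
#'
#' Optimizer and loop settings shared by all training functions. Defaults
#' follow the reference experimental setup: Adam with learning rate 1.5e-3,
#' gradient decay rate `beta1 = 0.88`, squared-gradient decay rate
#' `beta2 = 0.95`, batch size 400 (auto-capped at the available training
#' pool with a warning) and 200 epochs; loss weights
#' `alpha = beta = gamma = 1` and GRL strength `lambda_grl = 1` for DANN.
#' Scale `epochs` down for desk-scale experiments.
#'
#' @param lr learning rate (> 0).
#' @param beta1,beta2 Adam decay rates in (0, 1).
#' @param batch_size samples per step (>= 2); for transfer training the
#'   batch is composed half of source-train and half of target-update
#'   samples.
#' @param epochs training epochs (>= 1).
#' @param weights a [loss_weights()].
#' @param lambda_grl gradient reversal strength (DANN only).
#' @param seed RNG seed controlling shuffling, pairing and initialization
#'   of any model built inside the training helpers.
#' @param log_target_accuracy if `TRUE`, target-test accuracy is logged each
#'   epoch (adds a forward pass over the test list).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1.5e-3, beta1 = 0.88, beta2 = 0.95,
                         batch_size = 400L, epochs = 200L,
                         weights = loss_weights(), lambda_grl = 1,
                         seed = 0L, log_target_accuracy = TRUE) {
  if (lr <= 0 || beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1 ||
      batch_size < 2L || epochs < 1L) {
    abort("Invalid training configuration (lr > 0, 0 < beta < 1, batch_size >= 2, epochs >= 1).")
  }
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weights = weights,
                 lambda_grl = lambda_grl, seed = as.integer(seed),
                 log_target_accuracy = isTRUE(log_target_accuracy)),
            class = "train_config")
}

# Distribute a global category count over classes proportionally to the
# remaining per-class pool (largest remainder), capped by what is left.
allocate_stratified <- function(n_cat, remaining) {
  if (n_cat == 0L) return(integer(length(remaining)))
  tot <- sum(remaining)
  cnt <- largest_remainder(n_cat, remaining / tot)
  pmin(cnt, remaining)
}

#' Partition a two-domain dataset for transfer training
#'
#' Splits the source domain 4:1 into train and test (stratified by variety)
#' and the target domain into a labeled update set, an unlabeled update set
#' and a held-out test set, stratified by variety with exact global counts
#' (per-class counts differ by at most one sample from proportionality).
#' Any target fraction not claimed by the update sets goes to the test set,
#' so the union of the three target lists is always the whole target domain.
#' The reference semi-supervised protocol is `labeled_frac = 0.1,
#' unlabeled_frac = 0.1, test_frac = 0.8`; `labeled_frac = 0` is the
#' unsupervised-update regime.
#'
#' @param manifest a [as_manifest()] tibble covering both domains.
#' @param labeled_frac fraction of target samples used with labels
#'   (in \[0, 0.2\] for the reference protocol; any value in \[0, 1\] works).
#' @param unlabeled_frac fraction of target samples used without labels.
#' @param test_frac fraction of target samples held out for testing.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return A `transfer_split` list of id vectors `source_train, source_test,
#'   target_labeled, target_unlabeled, target_test` plus the generating
#'   fractions and seed.
#' @export
make_transfer_split <- function(manifest, labeled_frac = 0.1,
                                unlabeled_frac = 0.1, test_frac = 0.8,
                                seed = 0L) {
  if (labeled_frac < 0 || unlabeled_frac < 0 || test_frac < 0) {
    abort("Fractions must be nonnegative.", class = "adfs_split_error")
  }
  if (labeled_frac + unlabeled_frac > 1 - test_frac + 1e-9) {
    abort("labeled_frac + unlabeled_frac must not exceed 1 - test_frac.",
          class = "adfs_split_error")
  }
  man <- as_tibble(manifest)
  src <- man[man$domain == "source", ]
  tgt <- man[man$domain == "target", ]
  if (nrow(src) == 0L || nrow(tgt) == 0L) {
    abort("Manifest must contain both source and target samples.",
          class = "adfs_split_error")
  }
  class_names <- attr(manifest, "class_names")
  with_seed(seed, {
    # source: stratified 4:1 train:test
    s_train <- character(0); s_test <- character(0)
    for (cl in sort(unique(src$variety_index))) {
      ids <- sample(src$sample_id[src$variety_index == cl])
      if (length(ids) < 2L) {
        abort(sprintf("Class %s has too few source samples to stratify.",
                      class_names[cl + 1L] %||% cl),
              class = "adfs_split_error")
      }
      n_tr <- largest_remainder(length(ids), c(0.8, 0.2))[1]
      s_train <- c(s_train, ids[seq_len(n_tr)])
      s_test <- c(s_test, ids[-seq_len(n_tr)])
    }
    # target: global category counts, distributed over classes
    classes <- sort(unique(tgt$variety_index))
    pools <- lapply(classes, function(cl) sample(tgt$sample_id[tgt$variety_index == cl]))
    remaining <- vapply(pools, length, 1L)
    n_tot <- nrow(tgt)
    n_lab <- round(labeled_frac * n_tot)
    n_unl <- round(unlabeled_frac * n_tot)
    take <- function(n_cat, frac_name) {
      cnt <- allocate_stratified(n_cat, remaining)
      if (n_cat > 0L && any(cnt == 0L)) {
        bad <- classes[which(cnt == 0L)[1]]
        abort(sprintf("Class %s has too few target samples to stratify the %s set.",
                      class_names[bad + 1L] %||% bad, frac_name),
              class = "adfs_split_error")
      }
      out <- character(0)
      for (i in seq_along(pools)) {
        if (cnt[i] > 0L) {
          out <- c(out, pools[[i]][seq_len(cnt[i])])
          pools[[i]] <<- pools[[i]][-seq_len(cnt[i])]
        }
      }
      remaining <<- remaining - cnt
      out
    }
    t_lab <- take(n_lab, "labeled")
    t_unl <- take(n_unl, "unlabeled")
    t_test <- unlist(pools, use.names = FALSE)
    structure(list(source_train = s_train, source_test = s_test,
                   target_labeled = t_lab, target_unlabeled = t_unl,
                   target_test = t_test,
                   ratios = c(labeled = labeled_frac, unlabeled = unlabeled_frac,
                              test = test_frac),
                   seed = as.integer(seed)),
              class = "transfer_split")
  })
}

#' @export
print.transfer_split <- function(x, ...) {
  cat(sprintf(paste0("<transfer_split: source %d train / %d test; target ",
                     "%d labeled / %d unlabeled / %d test>\n"),
              length(x$source_train), length(x$source_test),
              length(x$target_labeled), length(x$target_unlabeled),
              length(x$target_test)))
  invisible(x)
}

#' Pair source and target samples for alignment
#'
#' Each target sample is paired with one source sample drawn uniformly (with
#' replacement) from the source batch; the shared-feature alignment loss is
#' averaged over these pairs.
#'
#' @param source_batch,target_batch nonempty vectors of sample ids.
#' @param seed RNG seed; deterministic pairing given the seed.
#' @return A tibble with columns `source_id`, `target_id`
#'   (`nrow = length(target_batch)`).
#' @export
make_pairs <- function(source_batch, target_batch, seed = 0L) {
  if (length(source_batch) == 0L || length(target_batch) == 0L) {
    abort("Both batches must be nonempty to form pairs.",
          class = "adfs_pairing_error")
  }
  with_seed(seed, {
    tibble(source_id = sample(source_batch, length(target_batch),
                              replace = TRUE),
           target_id = target_batch)
  })
}

# ---- ADFS training ---------------------------------------------------------

# Per-batch forward/backward for the full separation network.
# lab_mask marks rows whose class labels may be used (source-train and
# labeled-target rows); the class and domain-class losses see only those
# rows, the domain and alignment losses see all rows. Loss components are
# always evaluated; a zero-weighted component contributes no gradient.
adfs_step <- function(par, buf, cfg, xb, yv, dom, lab_mask, weights) {
  n <- dim(xb)[4]
  Cc <- cfg$n_classes
  fdim <- cfg$feature_dim
  fw <- g_fwd(xb, par, buf, cfg, training = TRUE)
  bn <- branch_fwd(fw$out, par, "Gn")
  bc <- branch_fwd(fw$out, par, "Gc")
  bd <- branch_fwd(fw$out, par, "Gd")
  Fn <- bn$out; Fc <- bc$out; Fd <- bd$out
  dFn <- matrix(0, n, fdim); dFc <- matrix(0, n, fdim); dFd <- matrix(0, n, fdim)
  grads <- list()

  head_pass <- function(z, prefix, labels, k, weight) {
    hf <- head_fwd(z, par, prefix)
    p <- softmax_rows(hf$out)
    lval <- cross_entropy(one_hot(labels, k), p)
    dlog <- NULL
    if (weight > 0) {
      dlog <- weight * (p - one_hot(labels, k)) / nrow(p)
      hb <- mlp_bwd(dlog, hf)
      grads <<- merge_grads(grads, hb$grads)
      return(list(loss = lval, dz = hb$dx))
    }
    list(loss = lval, dz = NULL)
  }

  lab_rows <- which(lab_mask)
  # class head h2 on [F_n; F_c], labeled rows only
  l_class <- 0
  if (length(lab_rows)) {
    hp <- head_pass(cbind(Fn[lab_rows, , drop = FALSE], Fc[lab_rows, , drop = FALSE]),
                    "h2", yv[lab_rows], Cc, weight = 1)
    l_class <- hp$loss
    dFn[lab_rows, ] <- dFn[lab_rows, ] + hp$dz[, 1:fdim]
    dFc[lab_rows, ] <- dFc[lab_rows, ] + hp$dz[, fdim + 1:fdim]
  }
  # domain head h3 on [F_n; F_d], all rows
  hp <- head_pass(cbind(Fn, Fd), "h3", dom, 2L, weight = weights$alpha)
  l_domain <- hp$loss
  if (!is.null(hp$dz)) {
    dFn <- dFn + hp$dz[, 1:fdim]
    dFd <- dFd + hp$dz[, fdim + 1:fdim]
  }
  # domain-class head h1 on [F_n; F_c; F_d], labeled rows only
  l_domain_class <- 0
  if (length(lab_rows)) {
    hp <- head_pass(cbind(Fn[lab_rows, , drop = FALSE], Fc[lab_rows, , drop = FALSE],
                          Fd[lab_rows, , drop = FALSE]),
                    "h1", dom[lab_rows] * Cc + yv[lab_rows], 2L * Cc,
                    weight = weights$beta)
    l_domain_class <- hp$loss
    if (!is.null(hp$dz)) {
      dFn[lab_rows, ] <- dFn[lab_rows, ] + hp$dz[, 1:fdim]
      dFc[lab_rows, ] <- dFc[lab_rows, ] + hp$dz[, fdim + 1:fdim]
      dFd[lab_rows, ] <- dFd[lab_rows, ] + hp$dz[, 2 * fdim + 1:fdim]
    }
  }
  # alignment on F_n over random source-target pairs in the batch
  l_dist <- 0
  s_rows <- which(dom == 0L); t_rows <- which(dom == 1L)
  if (length(s_rows) && length(t_rows)) {
    psrc <- sample(s_rows, length(t_rows), replace = TRUE)
    a <- Fn[psrc, , drop = FALSE]; b <- Fn[t_rows, , drop = FALSE]
    l_dist <- alignment_loss(a, b)
    if (weights$gamma > 0) {
      g <- alignment_loss_grad(a, b)
      acc <- rowsum(g$da, psrc)                 # source rows may repeat
      dFn[as.integer(rownames(acc)), ] <-
        dFn[as.integer(rownames(acc)), ] + weights$gamma * acc
      dFn[t_rows, ] <- dFn[t_rows, ] + weights$gamma * g$db
    }
  }

  bnb <- mlp_bwd(dFn, bn); bcb <- mlp_bwd(dFc, bc); bdb <- mlp_bwd(dFd, bd)
  grads <- merge_grads(grads, bnb$grads, bcb$grads, bdb$grads)
  gb <- g_bwd(bnb$dx + bcb$dx + bdb$dx, fw, par, cfg)
  grads <- merge_grads(grads, gb$grads)
  list(grads = grads, buf = fw$buf,
       losses = total_loss(l_class, l_domain, l_domain_class, l_dist, weights))
}

#' Train the feature separation network
#'
#' Semi-supervised transfer training: each step draws a mixed batch (half
#' source-train, half target-update samples), computes the three separated
#' features for every sample, evaluates the class loss (`h2`) and the joint
#' domain-class loss (`h1`) on label-bearing rows only, the domain loss
#' (`h3`) on all rows, and the cosine alignment loss over random
#' source-target pairs of shared features, then takes one Adam step on the
#' weighted total. All modules are trained jointly by a single optimizer.
#' Training is bit-deterministic given `config$seed`.
#'
#' @param model an [build_model()] result (untouched; a trained copy is
#'   returned).
#' @param split a [make_transfer_split()].
#' @param config a [train_config()].
#' @param data a [cube_set()]; cubes must share the model's geometry.
#'   Per-band standardization statistics are fitted on the source training
#'   ids only and reused for every other partition.
#' @param init_from optional source-trained [build_cnn()] model; its
#'   convolutional extractor weights and batch-norm state seed the base
#'   extractor `G`, so the adaptive stage starts from the same initial CNN
#'   as the parameter-update transfer strategies. Branches and heads always
#'   start fresh.
#' @return An `adfs_fit`: list with the trained `model` (standardization
#'   stats attached), the per-epoch `log` tibble (loss breakdown and,
#'   optionally, target-test accuracy), `split`, `config` and the id set the
#'   gradients actually saw (`trained_ids`).
#' @export
train_adfs <- function(model, split, config, data, init_from = NULL) {
  stopifnot(inherits(model, "adfs_model"), inherits(split, "transfer_split"),
            inherits(config, "train_config"), inherits(data, "cube_set"))
  if (!is.null(init_from)) model <- warm_start_extractor(model, init_from)
  cfg <- model$config
  stats <- fit_band_stats(data, split$source_train)
  man <- data$manifest
  vidx <- setNames(man$variety_index, man$sample_id)

  src_ids <- split$source_train
  tgt_ids <- c(split$target_labeled, split$target_unlabeled)
  pool_ids <- c(src_ids, tgt_ids)
  X <- to_channels_first(assemble_batch(data, pool_ids, stats))
  slot <- setNames(seq_along(pool_ids), pool_ids)
  yv_pool <- unname(vidx[pool_ids])
  dom_pool <- as.integer(pool_ids %in% tgt_ids)
  lab_pool <- pool_ids %in% c(src_ids, split$target_labeled)
  yv_pool[!lab_pool] <- 0L                      # placeholder, masked out

  bs <- config$batch_size
  avail <- length(pool_ids)
  if (bs > avail) {
    warn(sprintf("batch_size %d exceeds the %d available training samples; capped.",
                 bs, avail))
    bs <- avail
  }
  half <- if (length(tgt_ids)) max(1L, bs %/% 2L) else bs
  half_src <- min(half, length(src_ids))
  n_steps <- ceiling(length(src_ids) / half_src)

  par <- model$par; buf <- model$buf
  opt <- adam_init(par)
  log_rows <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(src_ids))
      comp <- c(l_class = 0, l_domain = 0, l_domain_class = 0, l_dist = 0,
                total = 0)
      for (st in seq_len(n_steps)) {
        s_take <- ord[((st - 1L) * half_src + 1L):min(st * half_src, length(src_ids))]
        b_src <- slot[src_ids[s_take]]
        b_tgt <- if (length(tgt_ids)) {
          slot[sample(tgt_ids, min(half, length(s_take)),
                      replace = length(tgt_ids) < min(half, length(s_take)))]
        } else integer(0)
        idx <- c(b_src, b_tgt)
        step <- adfs_step(par, buf, cfg, X[, , , idx, drop = FALSE],
                          yv_pool[idx], dom_pool[idx], lab_pool[idx],
                          config$weights)
        buf <- step$buf
        upd <- adam_step(opt, par, step$grads, config$lr, config$beta1,
                         config$beta2)
        opt <- upd$opt; par <- upd$par
        comp <- comp + unlist(step$losses)[names(comp)]
      }
      comp <- comp / n_steps
      acc <- NA_real_
      if (config$log_target_accuracy && length(split$target_test)) {
        m_now <- model; m_now$par <- par; m_now$buf <- buf; m_now$stats <- stats
        acc <- mean(predict_variety(m_now, data, split$target_test) ==
                      vidx[split$target_test])
      }
      log_rows[[ep]] <- tibble(epoch = ep, l_class = comp["l_class"],
                               l_domain = comp["l_domain"],
                               l_domain_class = comp["l_domain_class"],
                               l_dist = comp["l_dist"], total = comp["total"],
                               target_accuracy = acc)
    }
  })
  model$par <- par; model$buf <- buf; model$stats <- stats
  structure(list(model = model, log = dplyr::bind_rows(log_rows),
                 split = split, config = config, trained_ids = pool_ids),
            class = c("adfs_fit", "seed_fit"))
}

#' @export
print.adfs_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<adfs_fit: %d epochs, final total loss %.4f%s>\n",
              nrow(x$log), last$total,
              if (is.finite(last$target_accuracy %||% NA))
                sprintf(", target-test accuracy %.3f", last$target_accuracy)
              else ""))
  invisible(x)
}

#' Sweep the labeled target fraction
#'
#' Re-runs transfer training while varying the fraction of labeled target
#' samples, keeping the total update pool at 20% of the target domain
#' (`unlabeled_frac = 0.2 - fraction`); fraction 0 is the
#' unsupervised-update regime. Splits within one replicate share a seed, so
#' the source train/test partition is identical across fractions and one
#' source-trained CNN per replicate serves as the warm start for every
#' fraction (and as the no-transfer reference, reported as method `"cnn"`
#' with `fraction = NA`).
#'
#' @param fractions labeled fractions, each in \[0, 0.2\].
#' @param base_config a [train_config()]; per-replicate seeds are derived
#'   from `base_config$seed` and the replicate index.
#' @param data a [cube_set()].
#' @param n_seeds replicates per fraction.
#' @param methods any of `"adfs"`, `"dann"`.
#' @param model_args extra arguments passed to [build_model()] /
#'   [build_cnn()] (e.g. `input_shape`, `feature_dim`).
#' @param warm_start if `TRUE` (default), the separation network in each
#'   cell starts from the replicate's source-trained CNN extractor; DANN
#'   always trains from scratch per its reference procedure.
#' @return A tibble of class `adfs_sweep` with columns
#'   `method, fraction, seed, accuracy`.
#' @export
sweep_labeled_fraction <- function(fractions, base_config, data, n_seeds = 5L,
                                   methods = "adfs", model_args = list(),
                                   warm_start = TRUE) {
  if (any(fractions < 0 | fractions > 0.2 + 1e-9)) {
    abort("`fractions` must lie in [0, 0.2] (update pool is 20% of target).")
  }
  man <- data$manifest
  n_classes <- length(attr(man, "class_names"))
  n_bands <- attr(man, "band_count")
  rows <- list()
  for (s in seq_len(n_seeds)) {
    sd_rep <- as.integer(child_seed(base_config$seed, s))
    cfg_rep <- base_config
    cfg_rep$seed <- sd_rep
    splits <- lapply(fractions, function(f) {
      make_transfer_split(man, labeled_frac = f, unlabeled_frac = 0.2 - f,
                          test_frac = 0.8, seed = sd_rep)
    })
    cnn_rep <- NULL
    if (warm_start) {
      cnn_rep <- train_cnn(data, list(train = splits[[1]]$source_train,
                                      test = NULL), cfg_rep,
                           model_args = model_args)$model
      rows[[length(rows) + 1L]] <- tibble(
        method = "cnn", fraction = NA_real_, seed = s,
        accuracy = evaluate(cnn_rep, splits[[1]]$target_test,
                            data)$average_accuracy)
    }
    for (i in seq_along(fractions)) {
      split <- splits[[i]]
      for (m in methods) {
        fit <- if (m == "adfs") {
          mdl <- do.call(build_model, c(list(n_classes = n_classes,
                                             n_bands = n_bands,
                                             seed = sd_rep), model_args))
          train_adfs(mdl, split, cfg_rep, data, init_from = cnn_rep)
        } else if (m == "dann") {
          train_dann(data, split, cfg_rep, model_args = model_args)
        } else {
          abort(sprintf("Unknown method '%s'.", m))
        }
        rep <- evaluate(fit$model, split$target_test, data)
        rows[[length(rows) + 1L]] <-
          tibble(method = m, fraction = fractions[i], seed = s,
                 accuracy = rep$average_accuracy)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("adfs_sweep", class(out))
  out
}
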