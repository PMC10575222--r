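make_tiny_manifest <- function(n_src_per_class = 10L, n_tgt_per_class = 25L,
                               n_classes = 4L) {
  cls <- paste0("class_", seq_len(n_classes) - 1L)
  rows <- list()
  for (c in cls) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = paste0("s_", c, "_", seq_len(n_src_per_class)),
      variety = c, domain = "source", labeled = TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = paste0("t_", c, "_", seq_len(n_tgt_per_class)),
      variety = c, domain = "target", labeled = TRUE)
  }
  as_manifest(dplyr::bind_rows(rows))
}

test_that("the reference protocol splits a 100-sample target 10/10/80", {
  man <- make_tiny_manifest(10, 25)
  sp <- make_transfer_split(man, 0.1, 0.1, 0.8, seed = 1)
  expect_length(sp$target_labeled, 10)
  expect_length(sp$target_unlabeled, 10)
  expect_length(sp$target_test, 80)
  # source 4:1 exactly
  expect_length(sp$source_train, 32)
  expect_length(sp$source_test, 8)
  # pairwise disjoint, union covers the target domain
  all_t <- c(sp$target_labeled, sp$target_unlabeled, sp$target_test)
  expect_equal(sort(all_t), sort(man$sample_id[man$domain == "target"]))
  expect_false(anyDuplicated(c(all_t, sp$source_train, sp$source_test)) > 0)
})

test_that("splits are stratified by variety within one sample per class", {
  man <- make_tiny_manifest(10, 25)
  sp <- make_transfer_split(man, 0.1, 0.1, 0.8, seed = 3)
  cls_of <- function(ids) substr(ids, 3, 9)
  for (ids in list(sp$target_labeled, sp$target_unlabeled)) {
    counts <- table(cls_of(ids))
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_true(all(table(cls_of(sp$target_test)) == 20))
})

test_that("split edge cases: determinism, 0% regime, class too small", {
  man <- make_tiny_manifest(10, 25)
  expect_identical(make_transfer_split(man, seed = 7),
                   make_transfer_split(man, seed = 7))
  expect_false(identical(make_transfer_split(man, seed = 7),
                         make_transfer_split(man, seed = 8)))
  sp0 <- make_transfer_split(man, 0, 0.2, 0.8, seed = 1)
  expect_length(sp0$target_labeled, 0)
  expect_length(sp0$target_unlabeled, 20)
  tiny <- make_tiny_manifest(10, 2)
  expect_error(make_transfer_split(tiny, 0.1, 0.1, 0.8, seed = 1),
               "class_", class = "adfs_split_error")
  expect_error(make_transfer_split(man, 0.3, 0.3, 0.8, seed = 1),
               class = "adfs_split_error")
})

test_that("pairing draws one source per target, deterministically", {
  p <- make_pairs(paste0("s", 1:5), paste0("t", 1:5), seed = 2)
  expect_equal(nrow(p), 5)
  expect_identical(p$target_id, paste0("t", 1:5))
  expect_true(all(p$source_id %in% paste0("s", 1:5)))
  expect_identical(p, make_pairs(paste0("s", 1:5), paste0("t", 1:5), seed = 2))
  one <- make_pairs("s1", paste0("t", 1:3), seed = 1)
  expect_identical(unique(one$source_id), "s1")
  expect_error(make_pairs(character(0), "t1"), class = "adfs_pairing_error")
})

test_that("training reduces the composite loss and is reproducible", {
  for (s in 1:3) {
    data <- tiny_data(seed = s, shift = 0, n_per_class = 8)
    sp <- make_transfer_split(data$manifest, 0.125, 0.125, 0.75, seed = s)
    fit <- train_adfs(tiny_model(data, seed = s), sp, tiny_config(seed = s), data)
    expect_lt(fit$log$total[5], fit$log$total[1])
  }
  # bit-identical re-run
  data <- tiny_data(seed = 1, shift = 0, n_per_class = 8)
  sp <- make_transfer_split(data$manifest, 0.125, 0.125, 0.75, seed = 1)
  f1 <- train_adfs(tiny_model(data), sp, tiny_config(), data)
  f2 <- train_adfs(tiny_model(data), sp, tiny_config(), data)
  expect_identical(f1$model$par, f2$model$par)
  expect_identical(f1$log, f2$log)
})

test_that("zero-weighted loss terms are reported but train nothing", {
  data <- tiny_data(seed = 2, shift = 0.2, n_per_class = 8)
  sp <- make_transfer_split(data$manifest, 0.125, 0.125, 0.75, seed = 2)
  mdl <- tiny_model(data, seed = 2)
  cfg <- tiny_config(seed = 2, weights = loss_weights(0, 0, 0))
  fit <- train_adfs(mdl, sp, cfg, data)
  # components are still evaluated and logged
  expect_true(all(fit$log$l_domain > 0))
  expect_true(all(fit$log$l_dist > 0))
  # but the heads they weight receive no updates
  for (nm in grep("^(h1|h3)\\.", names(mdl$par), value = TRUE)) {
    expect_identical(fit$model$par[[nm]], mdl$par[[nm]])
  }
  # while the class path does train
  expect_false(identical(fit$model$par[["h2.out.W"]], mdl$par[["h2.out.W"]]))
})

test_that("no target-test sample ever contributes to a gradient", {
  data <- tiny_data(seed = 3, shift = 0.2, n_per_class = 8)
  sp <- make_transfer_split(data$manifest, 0.125, 0.125, 0.75, seed = 3)
  fit <- train_adfs(tiny_model(data, seed = 3), sp, tiny_config(seed = 3), data)
  expect_length(intersect(fit$trained_ids, sp$target_test), 0)
  expect_length(intersect(fit$trained_ids, sp$source_test), 0)
})

test_that("with no shift and zero transfer weights, training matches the CNN", {
  # degenerate case: the separation network reduces to supervised training
  accs <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    data <- tiny_data(seed = s, shift = 0, n_per_class = 25,
                      hard_pair = FALSE, within_class_sd = 0.04)
    sp <- make_transfer_split(data$manifest, 0.1, 0.1, 0.8, seed = s)
    cfg <- tiny_config(epochs = 100L, seed = s, weights = loss_weights(0, 0, 0))
    fit <- train_adfs(tiny_model(data, seed = s), sp, cfg, data)
    accs[s, 1] <- evaluate(fit$model, sp$source_test, data)$average_accuracy
    cnn <- train_cnn(data, list(train = sp$source_train, test = sp$source_test),
                     cfg, model_args = list(input_shape = c(8, 10),
                                            conv_channels = 4L, n_blocks = 2L,
                                            branch_hidden = 12L,
                                            head_hidden = 6L))
    accs[s, 2] <- cnn$report$average_accuracy
  }
  expect_lt(abs(mean(accs[, 1]) - mean(accs[, 2])), 0.02)
})

test_that("training logs expose tidy and glance views", {
  data <- tiny_data(seed = 4, shift = 0, n_per_class = 6)
  sp <- make_transfer_split(data$manifest, 0.25, 0.25, 0.5, seed = 4)
  cfg <- train_config(batch_size = 16, epochs = 3, seed = 4,
                      log_target_accuracy = TRUE)
  fit <- train_adfs(tiny_model(data, seed = 4), sp, cfg, data)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_true(all(is.finite(td$target_accuracy)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$n_params, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the labeled-fraction sweep returns one row per cell plus baselines", {
  data <- tiny_data(seed = 6, shift = 0.2, n_per_class = 10)
  cfg <- tiny_config(epochs = 2L, seed = 6)
  sw <- sweep_labeled_fraction(c(0, 0.1), cfg, data, n_seeds = 1L,
                               model_args = list(
                                 input_shape = c(8, 10), conv_channels = 4L,
                                 n_blocks = 2L, feature_dim = 8L,
                                 branch_hidden = 12L, head_hidden = 6L))
  expect_s3_class(sw, "adfs_sweep")
  expect_equal(sum(sw$method == "adfs"), 2)
  expect_equal(sum(sw$method == "cnn"), 1)   # one warm-start CNN per replicate
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  expect_s3_class(autoplot(sw[sw$method == "adfs", ]), "ggplot")
})
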