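cnn_args <- list(input_shape = c(8, 10), conv_channels = 4L, n_blocks = 2L,
                 branch_hidden = 12L, head_hidden = 6L)

test_that("the CNN learns well-separated classes and is reproducible", {
  # well-separated regime: no hard pair, modest jitter (the >90% sanity
  # threshold presumes separable classes)
  data <- tiny_data(seed = 1, shift = 0, n_per_class = 15,
                    hard_pair = FALSE, within_class_sd = 0.04)
  man <- tibble::as_tibble(data$manifest)
  src <- man$sample_id[man$domain == "source"]
  set.seed(41)
  tr <- unlist(lapply(split(src, man$variety_index[match(src, man$sample_id)]),
                      function(x) sample(x, 12)))
  te <- setdiff(src, tr)
  cfg <- tiny_config(epochs = 60L)
  f1 <- train_cnn(data, list(train = tr, test = te), cfg, cnn_args)
  expect_gt(f1$report$average_accuracy, 0.9)
  f2 <- train_cnn(data, list(train = tr, test = te), cfg, cnn_args)
  expect_identical(f1$model$par, f2$model$par)
})

test_that("pre-training update moves every parameter, zero epochs none", {
  data <- tiny_data(seed = 2, shift = 0.3, n_per_class = 8)
  sp <- make_transfer_split(data$manifest, 0.25, 0, 0.75, seed = 2)
  cfg <- tiny_config(epochs = 2L, seed = 2)
  base <- train_cnn(data, list(train = sp$source_train, test = NULL), cfg,
                    cnn_args)$model
  expect_identical(update_pretrained(base, sp$target_labeled, cfg, data,
                                     epochs = 0L), base)
  upd <- update_pretrained(base, sp$target_labeled, cfg, data, epochs = 1L)
  for (nm in names(base$par)) {
    expect_false(identical(upd$par[[nm]], base$par[[nm]]),
                 label = sprintf("parameter %s updated", nm))
  }
  expect_error(update_pretrained(base, character(0), cfg, data),
               class = "adfs_protocol_error")
})

test_that("fine-tuning leaves frozen shallow blocks bitwise unchanged", {
  data <- tiny_data(seed = 3, shift = 0.3, n_per_class = 8)
  sp <- make_transfer_split(data$manifest, 0.25, 0, 0.75, seed = 3)
  cfg <- tiny_config(epochs = 2L, seed = 3)
  base <- train_cnn(data, list(train = sp$source_train, test = NULL), cfg,
                    cnn_args)$model
  upd <- update_finetuned(base, sp$target_labeled, cfg, data,
                          frozen_blocks = 1L, epochs = 1L)
  frozen <- grep("1\\.", names(base$par), value = TRUE)
  for (nm in grep("^G\\.(conv|bn)1\\.", names(base$par), value = TRUE)) {
    expect_identical(upd$par[[nm]], base$par[[nm]])
  }
  expect_identical(upd$buf[["G.bn1.rm"]], base$buf[["G.bn1.rm"]])
  expect_false(identical(upd$par[["G.conv2.W"]], base$par[["G.conv2.W"]]))
  expect_error(update_finetuned(base, sp$target_labeled, cfg, data,
                                frozen_blocks = 2L),
               class = "adfs_protocol_error")
})

test_that("DANN trains, is deterministic, and lambda gates the reversal", {
  data <- tiny_data(seed = 4, shift = 0.2, n_per_class = 8)
  sp <- make_transfer_split(data$manifest, 0.125, 0.125, 0.75, seed = 4)
  cfg <- tiny_config(epochs = 4L, seed = 4)
  f1 <- train_dann(data, sp, cfg, model_args = cnn_args)
  expect_lt(f1$log$l_class[4], f1$log$l_class[1])
  f2 <- train_dann(data, sp, cfg, model_args = cnn_args)
  expect_identical(f1$model$par, f2$model$par)
  # the reversal operator carries -lambda to the extractor; lambda = 0 blocks it
  expect_identical(gradient_reverse_backward(c(1, -2), 0), c(0, 0))
  expect_identical(gradient_reverse_backward(c(1, -2), 1), c(-1, 2))
})

test_that("evaluation plumbing works for every model family", {
  data <- tiny_data(seed = 5, shift = 0, n_per_class = 6)
  sp <- make_transfer_split(data$manifest, 0.25, 0.25, 0.5, seed = 5)
  cfg <- tiny_config(epochs = 2L, seed = 5)
  fits <- list(
    adfs = train_adfs(tiny_model(data, seed = 5), sp, cfg, data)$model,
    dann = train_dann(data, sp, cfg, model_args = cnn_args)$model,
    cnn = train_cnn(data, list(train = sp$source_train, test = NULL), cfg,
                    cnn_args)$model)
  for (m in fits) {
    rep <- evaluate(m, sp$target_test, data)
    expect_s3_class(rep, "classification_report")
    expect_equal(rep$n, length(sp$target_test))
  }
})
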