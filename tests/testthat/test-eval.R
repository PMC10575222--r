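test_that("report statistics match a hand-computed confusion matrix", {
  rep <- classification_report(matrix(c(8, 3, 2, 7), 2), c("a", "b"))
  expect_equal(unname(rep$per_class_recall), c(0.8, 0.7))
  expect_equal(unname(rep$per_class_precision), c(8 / 11, 7 / 9))
  expect_equal(rep$average_accuracy, 0.75)
  expect_equal(rep$n, 20)
  td <- tidy(rep)
  expect_equal(td$support, c(10, 10))
  expect_equal(glance(rep)$average_accuracy, 0.75)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("perfect balanced predictions give a diagonal confusion matrix", {
  data <- tiny_data(seed = 6, shift = 0, n_per_class = 10)
  man <- tibble::as_tibble(data$manifest)
  ids <- man$sample_id[man$domain == "source"]
  # an oracle model: predict from the stored variety directly
  oracle <- structure(list(truth = setNames(man$variety_index, man$sample_id)),
                      class = "oracle_model")
  .S3method("predict_class_probs", "oracle_model",
            function(model, data, ids, chunk = 64L) {
              adfsnet:::one_hot(unname(model$truth[ids]), 4L)
            })
  rep <- evaluate(oracle, ids, data)
  expect_equal(unname(diag(rep$confusion)), rep(10, 4))
  expect_equal(rep$average_accuracy, 1)
  expect_equal(sum(rep$confusion) - sum(diag(rep$confusion)), 0)
})

test_that("evaluate validates its id list and ignores ordering", {
  data <- tiny_data(seed = 7, shift = 0, n_per_class = 4)
  m <- tiny_model(data, seed = 7)
  m$stats <- fit_band_stats(data)
  ids <- data$manifest$sample_id
  expect_error(evaluate(m, character(0), data), class = "adfs_evaluation_error")
  r1 <- evaluate(m, ids, data)
  r2 <- evaluate(m, rev(ids), data)
  expect_identical(r1$confusion, r2$confusion)
  expect_true(all(r1$per_class_recall >= 0 & r1$per_class_recall <= 1))
  expect_true(all(r1$confusion >= 0 & r1$confusion == round(r1$confusion)))
  # unlabeled ids are rejected
  data$manifest$variety_index[1] <- NA_integer_
  expect_error(evaluate(m, ids, data), class = "adfs_evaluation_error")
})

test_that("the standard feature-set path equals plain evaluation exactly", {
  data <- tiny_data(seed = 8, shift = 0.2, n_per_class = 5)
  m <- tiny_model(data, seed = 8)
  m$stats <- fit_band_stats(data)
  ids <- data$manifest$sample_id
  expect_identical(ablation_predict(m, ids, "FN_FC", data)$confusion,
                   evaluate(m, ids, data)$confusion)
  # single-sample input yields a valid one-sample report
  one <- ablation_predict(m, ids[1], "FN", data)
  expect_equal(one$n, 1)
  expect_error(ablation_predict(m, ids, "FC", data))
})

test_that("feature-set choices change the prediction path", {
  data <- tiny_data(seed = 9, shift = 0.2, n_per_class = 5)
  m <- tiny_model(data, seed = 9)
  m$stats <- fit_band_stats(data)
  ids <- data$manifest$sample_id
  f <- separate(m, adfsnet:::assemble_batch(data, ids[1:3], m$stats))
  # marginalizing h1 over domains yields valid class probabilities
  p1 <- classify_domain_class(m, f)
  marg <- p1[, 1:4] + p1[, 4 + 1:4]
  expect_equal(rowSums(marg), rep(1, 3), tolerance = 1e-9)
})

test_that("embedding export returns the requested widths and rows", {
  data <- tiny_data(seed = 10, shift = 0.2, n_per_class = 4)
  m <- tiny_model(data, seed = 10)   # feature_dim 8
  m$stats <- fit_band_stats(data)
  ids <- data$manifest$sample_id
  for (fs in c("FN", "FN_FC", "FN_FC_FD")) {
    emb <- export_embeddings(m, ids, fs, data)
    expect_equal(nrow(emb), length(ids))
    expect_equal(ncol(emb$embedding),
                 8L * switch(fs, FN = 1L, FN_FC = 2L, FN_FC_FD = 3L))
  }
  emb <- export_embeddings(m, ids, "FN", data)
  cd <- cross_domain_cosine(emb)
  expect_gte(cd, 0); expect_lte(cd, 2)
  expect_error(cross_domain_cosine(emb[emb$domain == "source", ]),
               class = "adfs_evaluation_error")
})
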