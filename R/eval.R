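# Inference-mode prediction, classification reports, feature-set ablation
# and embedding export. All prediction paths run in inference mode (batch
# norm uses running statistics) and process ids in fixed-size chunks so
# memory stays bounded for canonical-size cubes.

predict_chunks <- function(data, ids, stats, chunk, fn) {
  out <- vector("list", ceiling(length(ids) / chunk))
  for (i in seq_along(out)) {
    take <- ids[((i - 1L) * chunk + 1L):min(i * chunk, length(ids))]
    out[[i]] <- fn(to_channels_first(assemble_batch(data, take, stats)))
  }
  do.call(rbind, out)
}

#' Class probabilities for a set of samples
#'
#' Dispatches on the model type: the separation network classifies through
#' `h2` on `[F_n; F_c]`, the plain CNN and DANN through their class heads.
#' Argmax ties are broken toward the lowest class index.
#'
#' @param model a trained `adfs_model`, `cnn_model` or `dann_model` (with
#'   standardization stats attached by its training function).
#' @param data a [cube_set()].
#' @param ids sample ids to predict.
#' @param chunk samples per forward chunk.
#' @return `predict_class_probs()`: matrix `length(ids) x C`;
#'   `predict_variety()`: integer vector of 0-based class indices.
#' @export
predict_class_probs <- function(model, data, ids, chunk = 64L) {
  UseMethod("predict_class_probs")
}

#' @export
predict_class_probs.adfs_model <- function(model, data, ids, chunk = 64L) {
  predict_chunks(data, ids, model$stats, chunk, function(xb) {
    f <- separate_cf(model, xb)
    classify_class(model, f)
  })
}

#' @export
predict_class_probs.cnn_model <- function(model, data, ids, chunk = 64L) {
  cfg <- model$config
  predict_chunks(data, ids, model$stats, chunk, function(xb) {
    fw <- g_fwd(xb, model$par, model$buf, cfg, training = FALSE)
    softmax_rows(cnn_head_fwd(fw$out, model$par)$out)
  })
}

#' @export
predict_class_probs.dann_model <- function(model, data, ids, chunk = 64L) {
  cfg <- model$config
  predict_chunks(data, ids, model$stats, chunk, function(xb) {
    fw <- g_fwd(xb, model$par, model$buf, cfg, training = FALSE)
    z <- mlp_fwd(fw$out, model$par, "feat", c("fc1", "fc2"))$out
    softmax_rows(head_fwd(z, model$par, "hc")$out)
  })
}

#' @rdname predict_class_probs
#' @export
predict_variety <- function(model, data, ids, chunk = 64L) {
  max.col(predict_class_probs(model, data, ids, chunk), ties.method = "first") - 1L
}

#' Classification report from a confusion matrix
#'
#' @param confusion square integer matrix, rows = true class, columns =
#'   predicted class.
#' @param class_names optional row/column names.
#' @return A `classification_report` with per-class recall and precision
#'   (0 for empty rows/columns, recorded in the `degenerate` attribute) and
#'   overall average accuracy `trace / total`.
#' @export
classification_report <- function(confusion, class_names = NULL) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  if (!is.null(class_names)) dimnames(confusion) <- list(class_names, class_names)
  rs <- rowSums(confusion); cs <- colSums(confusion)
  recall <- ifelse(rs > 0, diag(confusion) / rs, 0)
  precision <- ifelse(cs > 0, diag(confusion) / cs, 0)
  structure(list(confusion = confusion,
                 per_class_recall = recall,
                 per_class_precision = precision,
                 average_accuracy = sum(diag(confusion)) / sum(confusion),
                 n = sum(confusion)),
            degenerate = which(rs == 0 | cs == 0),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report: %d samples, average accuracy %.4f>\n",
              x$n, x$average_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on labeled samples
#'
#' Deterministic inference-mode prediction (argmax of the class head, ties
#' to the lowest class index) followed by a confusion-matrix report.
#'
#' @param model a trained model (see [predict_class_probs()]).
#' @param ids nonempty vector of labeled sample ids.
#' @param data a [cube_set()].
#' @return A [classification_report()].
#' @export
evaluate <- function(model, ids, data) {
  if (!length(ids)) abort("Empty id list.", class = "adfs_evaluation_error")
  man <- data$manifest
  vidx <- setNames(man$variety_index, man$sample_id)
  truth <- vidx[ids]
  if (any(is.na(truth))) {
    abort(sprintf("Unlabeled sample in evaluation list: %s",
                  ids[which(is.na(truth))[1]]),
          class = "adfs_evaluation_error")
  }
  k <- length(attr(man, "class_names"))
  pred <- predict_variety(model, data, ids)
  lev <- seq_len(k) - 1L
  confusion <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  classification_report(unclass(as.matrix(confusion)),
                        class_names = attr(man, "class_names"))
}

#' Classify from restricted feature sets (ablation)
#'
#' Scores the target task using only parts of the separated feature triple,
#' without retraining: `"FN"` zeroes the class-specific features at the
#' class head's input (shared features alone), `"FN_FC"` is the standard
#' `h2` path, and `"FN_FC_FD"` predicts through the domain-class head `h1`
#' with the two domain blocks of each variety summed (marginalized over
#' domain).
#'
#' @param model a trained `adfs_model`.
#' @param ids labeled sample ids.
#' @param feature_set one of `"FN"`, `"FN_FC"`, `"FN_FC_FD"`.
#' @param data a [cube_set()].
#' @return A [classification_report()].
#' @export
ablation_predict <- function(model, ids, feature_set = c("FN_FC", "FN", "FN_FC_FD"),
                             data) {
  stopifnot(inherits(model, "adfs_model"))
  feature_set <- match.arg(feature_set)
  if (!length(ids)) abort("Empty id list.", class = "adfs_evaluation_error")
  man <- data$manifest
  k <- length(attr(man, "class_names"))
  vidx <- setNames(man$variety_index, man$sample_id)
  truth <- vidx[ids]
  probs <- predict_chunks(data, ids, model$stats, 64L, function(xb) {
    f <- separate_cf(model, xb)
    switch(feature_set,
      FN = {
        f$F_c <- f$F_c * 0
        classify_class(model, f)
      },
      FN_FC = classify_class(model, f),
      FN_FC_FD = {
        p1 <- classify_domain_class(model, f)   # columns: domain * C + class
        p1[, 1:k, drop = FALSE] + p1[, k + 1:k, drop = FALSE]
      })
  })
  pred <- max.col(probs, ties.method = "first") - 1L
  lev <- seq_len(k) - 1L
  confusion <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  classification_report(unclass(as.matrix(confusion)),
                        class_names = attr(man, "class_names"))
}

#' Export feature embeddings
#'
#' Returns the concatenated feature vectors for a feature set, one row per
#' sample, for downstream 2-D projection (e.g. t-SNE or UMAP) or alignment
#' diagnostics.
#'
#' @inheritParams ablation_predict
#' @return A tibble with `sample_id`, `domain`, `variety` and a matrix
#'   column `embedding` (`feature_dim`, `2 * feature_dim` or
#'   `3 * feature_dim` columns depending on the set).
#' @export
export_embeddings <- function(model, ids, feature_set = c("FN", "FN_FC", "FN_FC_FD"),
                              data) {
  stopifnot(inherits(model, "adfs_model"))
  feature_set <- match.arg(feature_set)
  emb <- predict_chunks(data, ids, model$stats, 64L, function(xb) {
    f <- separate_cf(model, xb)
    switch(feature_set,
      FN = feat_mat(f, "F_n"),
      FN_FC = cbind(feat_mat(f, "F_n"), feat_mat(f, "F_c")),
      FN_FC_FD = cbind(feat_mat(f, "F_n"), feat_mat(f, "F_c"),
                       feat_mat(f, "F_d")))
  })
  man <- data$manifest
  i <- match(ids, man$sample_id)
  tibble(sample_id = ids, domain = man$domain[i], variety = man$variety[i],
         embedding = emb)
}

#' Mean cross-domain cosine distance of embeddings
#'
#' The alignment diagnostic for the shared feature space: the average cosine
#' distance between every source-domain and every target-domain embedding
#' row. A well-aligned shared space drives this toward zero.
#'
#' @param embeddings a tibble from [export_embeddings()].
#' @return A single number in \[0, 2\].
#' @export
cross_domain_cosine <- function(embeddings) {
  e <- embeddings$embedding
  nrm <- sqrt(rowSums(e^2))
  nrm[nrm == 0] <- 1
  en <- e / nrm
  a <- en[embeddings$domain == "source", , drop = FALSE]
  b <- en[embeddings$domain == "target", , drop = FALSE]
  if (!nrow(a) || !nrow(b)) {
    abort("Need embeddings from both domains.", class = "adfs_evaluation_error")
  }
  1 - mean(a %*% t(b))
}
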