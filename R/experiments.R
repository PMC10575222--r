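#' Cross-season transfer benchmark on synthetic seed data
#'
#' Runs the full method comparison on one synthetic two-season dataset per
#' replicate: a source-only CNN (evaluated on both the source test and the
#' target test to expose the domain-shift collapse), the pre-training and
#' fine-tuning updates (which consume the whole 20% target update pool with
#' labels), DANN and the feature separation network (which consume 10%
#' labeled + 10% unlabeled target samples). Alongside accuracies it records
#' the feature-set ablation of the trained separation model and the
#' cross-domain alignment of the shared features before and after training.
#'
#' @param seeds integer vector of replicate seeds; each replicate draws its
#'   own dataset, split and initializations.
#' @param n_per_class seeds per variety per season.
#' @param epochs training epochs for every method.
#' @param spec_args overrides for [synthetic_spec()] (e.g. `shift_magnitude`).
#' @param model_args overrides for the model constructors; `input_shape` is
#'   set to the generator frame automatically.
#' @param methods subset of `c("cnn", "pretrain", "finetune", "dann", "adfs")`.
#' @param batch_size,lr optimizer settings for the desk-scale runs.
#' @return A `transfer_benchmark` list: `accuracy` (tibble: seed, method,
#'   split, accuracy), `ablation` (tibble: seed, feature_set, accuracy) and
#'   `alignment` (tibble: seed, stage, cosine_distance).
#' @export
run_transfer_benchmark <- function(seeds = 1:5, n_per_class = 50L, epochs = 20L,
                                   spec_args = list(), model_args = list(),
                                   methods = c("cnn", "pretrain", "finetune",
                                               "dann", "adfs"),
                                   batch_size = 80L, lr = 1.5e-3) {
  acc <- list(); abl <- list(); ali <- list()
  for (s in seeds) {
    spec <- do.call(synthetic_spec, c(list(seed = s), spec_args))
    data <- generate_dataset(spec, n_per_class)
    man <- data$manifest
    vidx <- setNames(man$variety_index, man$sample_id)
    margs <- c(list(input_shape = spec$spatial_shape), model_args)
    cfg <- train_config(lr = lr, batch_size = batch_size, epochs = epochs,
                        seed = child_seed(s, 3L), log_target_accuracy = FALSE)
    split <- make_transfer_split(man, 0.1, 0.1, 0.8, seed = child_seed(s, 5L))
    update_pool <- c(split$target_labeled, split$target_unlabeled)

    note <- function(method, part, a) {
      acc[[length(acc) + 1L]] <<- tibble(seed = s, method = method,
                                         split = part, accuracy = a)
    }
    # every transfer strategy starts from the same source-trained CNN
    cnn_fit <- train_cnn(data, list(train = split$source_train,
                                    test = split$source_test), cfg,
                         model_args = margs)
    {
      if ("cnn" %in% methods) {
        note("cnn", "source_test", cnn_fit$report$average_accuracy)
        note("cnn", "target_test",
             evaluate(cnn_fit$model, split$target_test, data)$average_accuracy)
      }
    }
    if ("pretrain" %in% methods) {
      m <- update_pretrained(cnn_fit$model, update_pool, cfg, data)
      note("pretrain", "target_test",
           evaluate(m, split$target_test, data)$average_accuracy)
    }
    if ("finetune" %in% methods) {
      m <- update_finetuned(cnn_fit$model, update_pool, cfg, data,
                            frozen_blocks = 1L)
      note("finetune", "target_test",
           evaluate(m, split$target_test, data)$average_accuracy)
    }
    if ("dann" %in% methods) {
      fit <- train_dann(data, split, cfg, model_args = margs)
      note("dann", "target_test",
           evaluate(fit$model, split$target_test, data)$average_accuracy)
    }
    if ("adfs" %in% methods) {
      mdl <- do.call(build_model, c(list(
        n_classes = length(attr(man, "class_names")),
        n_bands = attr(man, "band_count"), seed = cfg$seed), margs))
      mdl$stats <- fit_band_stats(data, split$source_train)
      test_ids <- c(split$source_test, split$target_test)
      before <- cross_domain_cosine(export_embeddings(mdl, test_ids, "FN", data))
      fit <- train_adfs(mdl, split, cfg, data, init_from = cnn_fit$model)
      note("adfs", "target_test",
           evaluate(fit$model, split$target_test, data)$average_accuracy)
      after <- cross_domain_cosine(export_embeddings(fit$model, test_ids, "FN",
                                                     data))
      ali[[length(ali) + 1L]] <- tibble(seed = s,
                                        stage = c("initial", "trained"),
                                        cosine_distance = c(before, after))
      for (fs in c("FN", "FN_FC", "FN_FC_FD")) {
        abl[[length(abl) + 1L]] <- tibble(
          seed = s, feature_set = fs,
          accuracy = ablation_predict(fit$model, split$target_test, fs,
                                      data)$average_accuracy)
      }
    }
  }
  structure(list(accuracy = dplyr::bind_rows(acc),
                 ablation = dplyr::bind_rows(abl),
                 alignment = dplyr::bind_rows(ali)),
            class = "transfer_benchmark")
}

#' @export
print.transfer_benchmark <- function(x, ...) {
  cat("<transfer_benchmark>\n")
  print(benchmark_summary(x))
  invisible(x)
}

#' Mean accuracy per method over benchmark replicates
#'
#' @param bench a [run_transfer_benchmark()] result.
#' @return A tibble `method, split, mean_accuracy, n_seeds`.
#' @export
benchmark_summary <- function(bench) {
  bench$accuracy |>
    dplyr::group_by(.data$method, .data$split) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     n_seeds = dplyr::n(), .groups = "drop")
}

#' Labeled-fraction sweep study with a no-transfer reference
#'
#' Convenience wrapper for the stability analysis: draws one synthetic
#' two-season dataset, sweeps the labeled target fraction over
#' `{0, 5, 10, 15, 20}%` of the target domain (update pool fixed at 20%)
#' with [sweep_labeled_fraction()], and trains a source-only CNN reference
#' per replicate so the unsupervised (0%) point can be compared against
#' no transfer.
#'
#' @param seed master seed; the dataset, splits and replicate seeds derive
#'   from it.
#' @param fractions labeled fractions to visit.
#' @param n_seeds replicates per fraction.
#' @param n_per_class seeds per variety per season.
#' @param epochs training epochs per cell.
#' @param spec_args overrides for [synthetic_spec()].
#' @return A list with `sweep` (an `adfs_sweep` tibble) and `baseline`
#'   (tibble of no-transfer CNN target accuracies, one per replicate; the
#'   same source-trained CNNs that warm-start the sweep cells).
#' @export
run_sweep_study <- function(seed = 1L, fractions = c(0, 0.05, 0.1, 0.15, 0.2),
                            n_seeds = 5L, n_per_class = 25L, epochs = 15L,
                            spec_args = list()) {
  spec <- do.call(synthetic_spec, c(list(seed = seed), spec_args))
  data <- generate_dataset(spec, n_per_class)
  margs <- list(input_shape = spec$spatial_shape)
  cfg <- train_config(batch_size = 80L, epochs = epochs,
                      seed = child_seed(seed, 23L), log_target_accuracy = FALSE)
  all_rows <- sweep_labeled_fraction(fractions, cfg, data, n_seeds = n_seeds,
                                     methods = "adfs", model_args = margs,
                                     warm_start = TRUE)
  base <- all_rows[all_rows$method == "cnn", c("seed", "accuracy")]
  sweep <- all_rows[all_rows$method != "cnn", ]
  list(sweep = sweep, baseline = base)
}
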