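#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   geom_point geom_errorbar labs facet_wrap theme_minimal
#'   scale_fill_gradient stat_summary
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a classification report
#'
#' @param x a [classification_report()].
#' @param ... unused.
#' @return `tidy()`: one row per class with recall, precision and support;
#'   `glance()`: one row with average accuracy and sample count.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  cls <- rownames(x$confusion) %||% paste0("class_", seq_along(x$per_class_recall) - 1L)
  tibble(class = cls,
         recall = unname(x$per_class_recall),
         precision = unname(x$per_class_precision),
         support = unname(rowSums(x$confusion)))
}

#' @rdname tidy.classification_report
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble(average_accuracy = x$average_accuracy, n = x$n)
}

#' @rdname tidy.classification_report
#' @param object a [classification_report()].
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "prediction", "count")
  ggplot(df, aes(x = .data$prediction, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "Predicted variety", y = "True variety") +
    theme_minimal()
}

#' Tidy a training run
#'
#' @param x an `adfs_fit`, `cnn_fit` or `dann_fit`.
#' @param ... unused.
#' @return `tidy()`: the per-epoch training log; `glance()`: one row with
#'   the final losses, final target-test accuracy (if logged), epoch and
#'   parameter counts.
#' @method tidy seed_fit
#' @export
tidy.seed_fit <- function(x, ...) x$log

#' @rdname tidy.seed_fit
#' @method glance seed_fit
#' @export
glance.seed_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  out <- last[setdiff(names(last), "epoch")]
  out$epochs <- nrow(x$log)
  out$n_params <- x$model$config$n_params
  as_tibble(out)
}

#' @rdname tidy.seed_fit
#' @param object a training run.
#' @method autoplot seed_fit
#' @export
autoplot.seed_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log,
                            dplyr::any_of(c("l_class", "l_domain",
                                            "l_domain_class", "l_dist",
                                            "loss", "total")),
                            names_to = "component", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value, colour = .data$component)) +
    geom_line() +
    labs(x = "Epoch", y = "Loss") +
    theme_minimal()
}

#' Plot a labeled-fraction sweep
#'
#' Mean target-test accuracy (with the spread over replicate seeds) against
#' the fraction of labeled target samples.
#'
#' @param object an [sweep_labeled_fraction()] result.
#' @param ... unused.
#' @method autoplot adfs_sweep
#' @export
autoplot.adfs_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$fraction, y = .data$accuracy,
                     colour = .data$method)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point") +
    geom_point(alpha = 0.3) +
    labs(x = "Labeled target fraction", y = "Target-test accuracy") +
    theme_minimal()
}
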