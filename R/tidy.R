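# broom-style accessors and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy tdmnet_fit
#' @export
tidy.tdmnet_fit <- function(x, ...) x$history

#' @method glance tdmnet_fit
#' @export
glance.tdmnet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), ce = h$ce, mmd = h$mmd,
                 total = h$total, train_accuracy = h$accuracy,
                 n_parameters = n_parameters(x$model))
}

#' @method tidy tdmnet_cv
#' @export
tidy.tdmnet_cv <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$reports),
    accuracy = x$fold_accuracies,
    precision = vapply(x$reports, `[[`, numeric(1L), "precision"),
    recall = vapply(x$reports, `[[`, numeric(1L), "recall"),
    macro_f1 = vapply(x$reports, `[[`, numeric(1L), "macro_f1"),
    n_test = vapply(x$reports, `[[`, integer(1L), "n")
  )
}

#' @method glance tdmnet_cv
#' @export
glance.tdmnet_cv <- function(x, ...) {
  tibble::tibble(mean_acc = x$mean_acc, std_acc = x$std_acc,
                 n_folds = length(x$reports))
}

#' @method tidy tdmnet_eval
#' @export
tidy.tdmnet_eval <- function(x, ...) x$per_class

#' @method glance tdmnet_eval
#' @export
glance.tdmnet_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, macro_f1 = x$macro_f1, n = x$n)
}

#' @method tidy tdmnet_sweep
#' @export
tidy.tdmnet_sweep <- function(x, ...) x$summary

#' @method glance tdmnet_sweep
#' @export
glance.tdmnet_sweep <- function(x, ...) {
  tibble::tibble(across_T_std = x$across_T_std, n_T = length(x$T_values))
}

#' @method tidy tdmnet_ablation
#' @export
tidy.tdmnet_ablation <- function(x, ...) x$summary

#' Training-history loss curves
#' @param object A `tdmnet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tdmnet_fit
#' @export
autoplot.tdmnet_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("ce", "mmd"),
                            names_to = "component", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss component",
                  title = "Training loss: cross-entropy and temporal difference") +
    ggplot2::theme_minimal()
}

#' Per-fold cross-validation accuracies
#' @param object A `tdmnet_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tdmnet_cv
#' @export
autoplot.tdmnet_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_hline(yintercept = object$mean_acc, linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = sprintf("Cross-validation: %.2f +/- %.2f%%",
                                  object$mean_acc, object$std_acc)) +
    ggplot2::theme_minimal()
}

#' Row-normalized confusion matrix heatmap
#' @param object A `tdmnet_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tdmnet_eval
#' @export
autoplot.tdmnet_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion_pct))
  names(df) <- c("truth", "predicted", "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "%",
                  title = "Confusion matrix (row %)") +
    ggplot2::theme_minimal()
}

#' Segment-length sensitivity curve
#' @param object A `tdmnet_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tdmnet_sweep
#' @export
autoplot.tdmnet_sweep <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T, y = .data$mean_acc)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_acc - .data$std_acc,
                                          ymax = .data$mean_acc + .data$std_acc)) +
    ggplot2::labs(x = "segment length T (s)", y = "mean CV accuracy (%)",
                  title = sprintf("Segment-length sweep (across-T std %.2f%%)",
                                  object$across_T_std)) +
    ggplot2::theme_minimal()
}
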