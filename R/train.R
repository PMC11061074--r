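#' Training configuration
#'
#' Defaults follow the reference experimental setup: segment length `T = 3`
#' s, batch size 64, at most 150 epochs of Adam at learning rate 0.001,
#' three branches, temporal-difference weight 1, fivefold cross-validation.
#'
#' @param T Segment length in seconds (`2T` must be an integer).
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Adam learning rate.
#' @param n_branches Number of branches.
#' @param mmd_weight Weight of the temporal-difference loss term.
#' @param kernel,bandwidth MMD options, see [mmd()].
#' @param squared Use squared MMD as the loss term (default `TRUE`: its
#'   gradient vanishes as the groups merge, which keeps the penalty from
#'   overwhelming the classification loss late in training; set `FALSE` for
#'   the plain norm).
#' @param plan_refresh `"per_batch"` redraws the scramble plan for every
#'   batch; `"fixed"` draws one plan per training run.
#' @param ablate_mmd Drop the temporal-difference term (plans still drawn).
#' @param ablate_multibranch Use a single branch (no voting).
#' @param ce_mode `"sum"` or `"mean"` over the branch cross-entropies.
#' @param n_folds Cross-validation folds.
#' @param seed Master seed (initialization, shuffling, plans, folds).
#' @param patience Optional early-stopping patience on training accuracy
#'   (`NULL` = train to `max_epochs`).
#' @return A `train_config` list.
#' @export
train_config <- function(T = 3, batch_size = 64L, max_epochs = 150L,
                         learning_rate = 0.001, n_branches = 3L,
                         mmd_weight = 1, kernel = "linear", bandwidth = NULL,
                         squared = TRUE, plan_refresh = c("per_batch", "fixed"),
                         ablate_mmd = FALSE, ablate_multibranch = FALSE,
                         ce_mode = c("sum", "mean"), n_folds = 5L, seed = 1L,
                         patience = NULL) {
  plan_refresh <- match.arg(plan_refresh)
  ce_mode <- match.arg(ce_mode)
  if (abs(2 * T - round(2 * T)) > 1e-9) stop("2*T must be an integer (T = ", T, ")")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  structure(
    list(T = T, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
         n_branches = as.integer(n_branches), mmd_weight = mmd_weight,
         kernel = kernel, bandwidth = bandwidth, squared = squared,
         plan_refresh = plan_refresh, ablate_mmd = ablate_mmd,
         ablate_multibranch = ablate_multibranch, ce_mode = ce_mode,
         n_folds = as.integer(n_folds), seed = as.integer(seed),
         patience = patience),
    class = "train_config"
  )
}

.encode_labels <- function(labels, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- sort(unique(labels))
  y <- match(labels, alphabet)
  if (anyNA(y)) stop("labels outside the alphabet")
  list(y = y, alphabet = alphabet)
}

#' Train the temporal-difference minimizing network
#'
#' Mini-batch Adam on the combined cross-entropy + temporal-difference
#' objective. Fully reproducible given `config$seed` (weight initialization,
#' shuffling and scramble plans all derive from it).
#'
#' @param features A `feature_tensor_4d` or `[N x 9 x 8 x 4 x 2T]` array.
#' @param labels Vector of class labels, one per segment; every class needs
#'   at least 2 segments.
#' @param config A [train_config()].
#' @param spec Optional `network_spec`; defaults to the full-size
#'   architecture for the label alphabet found in `labels`.
#' @param verbose Print per-epoch progress.
#' @return A `tdmnet_fit`: the trained model, a per-epoch `history` tibble
#'   (`ce`, `mmd`, `total`, `accuracy`), the evaluation plan and config.
#' @export
train_tdmnet <- function(features, labels, config = train_config(),
                         spec = NULL, verbose = FALSE) {
  x <- .feature_values(features)
  N <- dim(x)[1L]; S <- dim(x)[5L]
  if (length(labels) != N) stop("need one label per segment")
  enc <- .encode_labels(labels)
  tab <- table(enc$y)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 segments; worst class has ", min(tab))
  }
  n_classes <- length(enc$alphabet)
  nb <- if (config$ablate_multibranch) 1L else config$n_branches
  if (is.null(spec)) {
    spec <- network_spec(n_classes, alphabet = enc$alphabet, n_branches = nb)
  } else {
    spec$n_classes <- n_classes
    spec$alphabet <- enc$alphabet
    spec$n_branches <- nb
  }
  .with_seed(config$seed, {
    model <- init_network(spec, seed = sample.int(.Machine$integer.max, 1L))
    adam <- .adam_init(model$params)
    fixed_plan <- make_branch_plan(S, nb, seed = sample.int(.Machine$integer.max, 1L))
    eval_plan <- fixed_plan
    hist <- vector("list", config$max_epochs)
    best_acc <- -Inf; stall <- 0L
    n_epochs <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(N)
      ce_sum <- 0; mmd_sum <- 0; correct <- 0L; nbatch <- 0L
      for (start in seq(1L, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, N)]
        plan <- if (config$plan_refresh == "per_batch") {
          make_branch_plan(S, nb, seed = sample.int(.Machine$integer.max, 1L))
        } else fixed_plan
        res <- .loss_and_grads(model, x[idx, , , , , drop = FALSE], enc$y[idx],
                               plan, mmd_weight = config$mmd_weight,
                               kernel = config$kernel,
                               bandwidth = config$bandwidth,
                               squared = config$squared,
                               ablate_mmd = config$ablate_mmd,
                               ce_mode = config$ce_mode)
        if (config$learning_rate > 0) {
          upd <- .adam_step(model$params, res$grads, adam,
                            lr = config$learning_rate)
          model$params <- upd$params
          adam <- upd$state
        }
        ce_sum <- ce_sum + res$ce
        mmd_sum <- mmd_sum + res$mmd
        nbatch <- nbatch + 1L
        if (nb == 1L) {
          voted <- res$branches[[1L]]$label
        } else {
          labmat <- matrix(unlist(lapply(res$branches, `[[`, "label")),
                           ncol = nb)
          voted <- apply(labmat, 1L, function(r) vote(r)$label)
        }
        correct <- correct + sum(voted == spec$alphabet[enc$y[idx]])
      }
      acc <- correct / N
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, ce = ce_sum / nbatch, mmd = mmd_sum / nbatch,
        total = (ce_sum + config$mmd_weight * mmd_sum) / nbatch,
        accuracy = 100 * acc
      )
      n_epochs <- epoch
      if (verbose) {
        message(sprintf("epoch %3d | CE %.4f | MMD %.4f | train acc %.1f%%",
                        epoch, ce_sum / nbatch, mmd_sum / nbatch, 100 * acc))
      }
      if (!is.null(config$patience)) {
        if (acc > best_acc + 1e-12) { best_acc <- acc; stall <- 0L }
        else stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    structure(
      list(model = model, history = dplyr::bind_rows(hist[seq_len(n_epochs)]),
           plan = eval_plan, config = config, alphabet = enc$alphabet),
      class = "tdmnet_fit"
    )
  })
}

#' @export
print.tdmnet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<tdmnet_fit> %d epochs | final CE %.4f, MMD %.4f, train acc %.1f%%\n",
              nrow(x$history), h$ce, h$mmd, h$accuracy))
  invisible(x)
}

#' @export
predict.tdmnet_fit <- function(object, features, plan = object$plan, ...) {
  predict(object$model, features, plan = plan, ...)
}

#' Stratified k-fold cross-validation
#'
#' Splits segments into stratified folds, trains a fresh model per fold and
#' evaluates on the held-out fold. Accuracy is reported as mean and standard
#' deviation over folds.
#'
#' @inheritParams train_tdmnet
#' @param keep_models Keep the per-fold `tdmnet_fit` objects.
#' @return A `tdmnet_cv`: per-fold `tdmnet_eval`s, a `folds` tibble, summary
#'   statistics and training histories.
#' @export
cross_validate <- function(features, labels, config = train_config(),
                           spec = NULL, keep_models = FALSE, verbose = FALSE) {
  x <- .feature_values(features)
  N <- dim(x)[1L]
  if (length(labels) != N) stop("need one label per segment")
  if (N < config$n_folds) stop("fewer segments (", N, ") than folds (", config$n_folds, ")")
  enc <- .encode_labels(labels)
  assignment <- .with_seed(config$seed + 777L, {
    fold <- integer(N)
    for (k in sort(unique(enc$y))) {
      idx <- sample(which(enc$y == k))
      fold[idx] <- rep_len(seq_len(config$n_folds), length(idx))
    }
    fold
  })
  reports <- vector("list", config$n_folds)
  histories <- vector("list", config$n_folds)
  models <- if (keep_models) vector("list", config$n_folds)
  accs <- numeric(config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- which(assignment != f); te <- which(assignment == f)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_tdmnet(x[tr, , , , , drop = FALSE], labels[tr],
                        config = cfg_f, spec = spec, verbose = verbose)
    pred <- predict(fit, x[te, , , , , drop = FALSE])
    reports[[f]] <- evaluate(pred$label, labels[te], alphabet = enc$alphabet)
    accs[f] <- reports[[f]]$accuracy
    histories[[f]] <- dplyr::mutate(fit$history, fold = f)
    if (keep_models) models[[f]] <- fit
  }
  structure(
    list(reports = reports, fold_accuracies = accs,
         mean_acc = mean(accs), std_acc = stats::sd(accs),
         folds = tibble::tibble(segment = seq_len(N), fold = assignment,
                                label = labels),
         histories = dplyr::bind_rows(histories),
         models = models, config = config),
    class = "tdmnet_cv"
  )
}

#' @export
print.tdmnet_cv <- function(x, ...) {
  cat(sprintf("<tdmnet_cv> %d folds | ACC %.2f +/- %.2f%%\n",
              length(x$fold_accuracies), x$mean_acc, x$std_acc))
  invisible(x)
}

#' Build one labeled feature set from many recordings
#'
#' Converts each recording to its 4D tensor and stacks all segments, labeling
#' every segment with its recording's label.
#'
#' @param recordings List of `eeg_recording`s.
#' @param labels Per-recording labels; defaults to each recording's own label.
#' @inheritParams build_4d_features
#' @return List with `x` (stacked 5D array) and `y` (per-segment labels).
#' @export
dataset_features <- function(recordings, labels = NULL, T = 3,
                             bands = default_bands(),
                             grid = default_grid_map("seed62"),
                             working_rate = 200) {
  if (is.null(labels)) {
    labels <- vapply(recordings, function(r) r$label, FUN.VALUE = numeric(1L))
  }
  if (length(labels) != length(recordings)) stop("need one label per recording")
  tensors <- lapply(recordings, build_4d_features, T = T, bands = bands,
                    grid = grid, working_rate = working_rate)
  ns <- vapply(tensors, function(t) dim(t$values)[1L], integer(1L))
  d1 <- dim(tensors[[1L]]$values)
  x <- array(0, dim = c(sum(ns), d1[-1L]))
  at <- 0L
  for (i in seq_along(tensors)) {
    x[(at + 1L):(at + ns[i]), , , , ] <- tensors[[i]]$values
    at <- at + ns[i]
  }
  list(x = x, y = rep(labels, times = ns))
}

#' Segment-length sensitivity sweep
#'
#' Rebuilds the feature tensors for each candidate segment length `T` and
#' runs [cross_validate()] on each, reporting the mean accuracy per `T` and
#' the across-`T` standard deviation of those means (the sensitivity
#' statistic).
#'
#' @param recordings List of `eeg_recording`s.
#' @param labels Per-recording labels (defaults to recording labels).
#' @param T_values Candidate segment lengths in seconds (default
#'   `c(2, 2.5, 3, 3.5, 4)`).
#' @inheritParams cross_validate
#' @inheritParams build_4d_features
#' @return A `tdmnet_sweep`: per-`T` summaries, the across-`T` std and the
#'   `tdmnet_cv` objects.
#' @export
sweep_T <- function(recordings, labels = NULL,
                    T_values = c(2, 2.5, 3, 3.5, 4),
                    config = train_config(), spec = NULL,
                    bands = default_bands(),
                    grid = default_grid_map("seed62"), working_rate = 200,
                    verbose = FALSE) {
  for (T in T_values) {
    if (abs(2 * T - round(2 * T)) > 1e-9) stop("invalid T = ", T, ": 2*T must be an integer")
  }
  cvs <- vector("list", length(T_values))
  rows <- vector("list", length(T_values))
  for (i in seq_along(T_values)) {
    cfg <- config
    cfg$T <- T_values[i]
    ds <- dataset_features(recordings, labels, T = T_values[i], bands = bands,
                           grid = grid, working_rate = working_rate)
    cvs[[i]] <- cross_validate(ds$x, ds$y, config = cfg, spec = spec,
                               verbose = verbose)
    rows[[i]] <- tibble::tibble(
      T = T_values[i], n_segments = length(ds$y),
      mean_acc = cvs[[i]]$mean_acc, std_acc = cvs[[i]]$std_acc
    )
  }
  summary <- dplyr::bind_rows(rows)
  structure(
    list(summary = summary, across_T_std = stats::sd(summary$mean_acc),
         cvs = cvs, T_values = T_values, config = config),
    class = "tdmnet_sweep"
  )
}

#' @export
print.tdmnet_sweep <- function(x, ...) {
  print(x$summary)
  cat(sprintf("across-T std of mean accuracy: %.2f%%\n", x$across_T_std))
  invisible(x)
}

#' Ablation study of the temporal-difference and multibranch modules
#'
#' Cross-validates four configurations: the full model, the model without the
#' temporal-difference loss (scramble plans still drawn), the model without
#' the multibranch strategy (single branch, no voting), and the model with
#' both removed. For each configuration a model is also trained on the full
#' data to measure the mean within-segment feature MMD at convergence
#' ([feature_drift_mmd()]).
#'
#' @inheritParams cross_validate
#' @param measure_drift Also train one model per configuration on all data
#'   and record `feature_mmd` (default `TRUE`).
#' @return A `tdmnet_ablation` with a 4-row summary tibble (ACC +/- STD, P,
#'   R, macro-F1, feature MMD) and the underlying `tdmnet_cv` objects.
#' @export
run_ablation <- function(features, labels, config = train_config(),
                         spec = NULL, measure_drift = TRUE, verbose = FALSE) {
  variants <- list(
    full = list(ablate_mmd = FALSE, ablate_multibranch = FALSE),
    no_temporal_difference = list(ablate_mmd = TRUE, ablate_multibranch = FALSE),
    no_multibranch = list(ablate_mmd = FALSE, ablate_multibranch = TRUE),
    no_both = list(ablate_mmd = TRUE, ablate_multibranch = TRUE)
  )
  cvs <- vector("list", length(variants))
  names(cvs) <- names(variants)
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    cfg <- config
    cfg$ablate_mmd <- variants[[i]]$ablate_mmd
    cfg$ablate_multibranch <- variants[[i]]$ablate_multibranch
    cvs[[i]] <- cross_validate(features, labels, config = cfg, spec = spec,
                               verbose = verbose)
    macro <- .cv_macro(cvs[[i]])
    drift <- NA_real_
    if (measure_drift) {
      fit <- train_tdmnet(features, labels, config = cfg, spec = spec)
      drift <- feature_drift_mmd(fit, features)
    }
    rows[[i]] <- tibble::tibble(
      model = names(variants)[i],
      acc_mean = cvs[[i]]$mean_acc, acc_std = cvs[[i]]$std_acc,
      precision = macro["precision"], recall = macro["recall"],
      macro_f1 = macro["macro_f1"], feature_mmd = drift
    )
  }
  structure(
    list(summary = dplyr::bind_rows(rows), cvs = cvs, config = config),
    class = "tdmnet_ablation"
  )
}

.cv_macro <- function(cv) {
  c(precision = mean(vapply(cv$reports, `[[`, numeric(1L), "precision")),
    recall = mean(vapply(cv$reports, `[[`, numeric(1L), "recall")),
    macro_f1 = mean(vapply(cv$reports, `[[`, numeric(1L), "macro_f1")))
}

#' @export
print.tdmnet_ablation <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
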