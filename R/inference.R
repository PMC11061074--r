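#' Fuse three branch labels by voting
#'
#' Majority vote over the branch labels: any label carried by at least two
#' branches wins. When all labels disagree the label of the first branch in
#' `branch_order` (the time-ranked branch) is returned and the decision is
#' flagged as tie-broken.
#'
#' @param branch_labels Vector of branch labels (typically length 3).
#' @param branch_order Branch indices ranked by time; the first entry breaks
#'   full disagreements (default `1:length(branch_labels)`).
#' @return List with `label` and `tie_broken`.
#' @examples
#' vote(c(1, 1, 0))           # label 1, no tie-break
#' vote(c(1, 0, -1))          # full disagreement -> branch 1 wins, tie-broken
#' @export
vote <- function(branch_labels, branch_order = seq_along(branch_labels)) {
  if (length(branch_labels) < 1L) stop("need at least one branch label")
  tab <- table(branch_labels)
  if (max(tab) >= 2L || length(tab) == 1L) {
    winner <- names(tab)[which.max(tab)]
    lab <- branch_labels[match(winner, as.character(branch_labels))]
    return(list(label = lab, tie_broken = FALSE))
  }
  list(label = branch_labels[branch_order[1L]], tie_broken = TRUE)
}

#' Predict labels for feature segments
#'
#' Runs the full network on each segment and fuses the branch labels with
#' [vote()]. The branch plan defaults to a deterministic draw from `seed`.
#'
#' @param object A `tdmnet_model`.
#' @param features A `feature_tensor_4d` or `[N x 9 x 8 x 4 x 2T]` array.
#' @param plan Optional `branch_plan`; drawn from `seed` when `NULL`.
#' @param seed Seed for the default plan.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A tibble with one row per segment: branch labels, `label` (voted,
#'   in the model's alphabet) and `tie_broken`.
#' @export
predict.tdmnet_model <- function(object, features, plan = NULL, seed = 1L,
                                 batch_size = 64L, ...) {
  x <- .feature_values(features)
  S <- dim(x)[5L]
  if (is.null(plan)) plan <- make_branch_plan(S, object$spec$n_branches, seed = seed)
  N <- dim(x)[1L]
  nb <- object$spec$n_branches
  branch_lab <- matrix(NA, N, nb)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fw <- .forward_full(object, x[idx, , , , , drop = FALSE], plan)
    for (k in seq_len(nb)) branch_lab[idx, k] <- fw$branches[[k]]$label
  }
  voted <- lapply(seq_len(N), function(i) vote(branch_lab[i, ]))
  out <- tibble::tibble(segment = seq_len(N))
  for (k in seq_len(nb)) out[[paste0("branch", k)]] <- branch_lab[, k]
  out$label <- vapply(voted, function(v) v$label, branch_lab[1L, 1L])
  out$tie_broken <- vapply(voted, function(v) v$tie_broken, logical(1L))
  out
}

.feature_values <- function(features) {
  if (inherits(features, "feature_tensor_4d")) features$values
  else if (is.array(features) && length(dim(features)) == 5L) features
  else stop("features must be a feature_tensor_4d or a 5D array")
}

#' Evaluate predictions against true labels
#'
#' Computes accuracy, the row-normalized confusion matrix (percentage of
#' samples in class i classified as class j), and macro-averaged precision,
#' recall and F1, all in percent.
#'
#' @param predicted Vector of predicted labels.
#' @param truth Vector of true labels, same length.
#' @param alphabet Label alphabet; defaults to the sorted union.
#' @return A `tdmnet_eval` object.
#' @export
evaluate <- function(predicted, truth, alphabet = NULL) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    stop("predicted and truth must be non-empty vectors of equal length")
  }
  if (is.null(alphabet)) alphabet <- sort(unique(c(predicted, truth)))
  if (!all(predicted %in% alphabet) || !all(truth %in% alphabet)) {
    stop("labels outside the alphabet")
  }
  p <- factor(predicted, levels = alphabet)
  t_ <- factor(truth, levels = alphabet)
  counts <- table(truth = t_, predicted = p)
  acc <- 100 * sum(diag(counts)) / length(truth)
  rs <- rowSums(counts)
  conf_pct <- 100 * sweep(unclass(counts), 1L, pmax(rs, 1L), "/")
  present <- which(rs > 0)
  prec <- rec <- f1 <- numeric(length(present))
  for (i in seq_along(present)) {
    k <- present[i]
    tp <- counts[k, k]
    prec[i] <- if (sum(counts[, k]) > 0) tp / sum(counts[, k]) else 0
    rec[i] <- tp / rs[k]
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  per_class <- tibble::tibble(
    class = alphabet[present],
    precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
    support = as.integer(rs[present])
  )
  structure(
    list(accuracy = acc, confusion_counts = unclass(counts),
         confusion_pct = conf_pct, precision = 100 * mean(prec),
         recall = 100 * mean(rec), macro_f1 = 100 * mean(f1),
         per_class = per_class, n = length(truth), alphabet = alphabet),
    class = "tdmnet_eval"
  )
}

#' @export
print.tdmnet_eval <- function(x, ...) {
  cat(sprintf("<tdmnet_eval> n = %d | ACC %.2f%% | P %.2f%% | R %.2f%% | macro-F1 %.2f%%\n",
              x$n, x$accuracy, x$precision, x$recall, x$macro_f1))
  cat("confusion (row %):\n")
  print(round(x$confusion_pct, 2))
  invisible(x)
}

#' Mean within-segment feature discrepancy of a model
#'
#' Encodes every section of every segment with the model's CNN and measures
#' the linear-kernel MMD between the chronological first and second halves of
#' each segment's section features, averaged over segments. This probes how
#' temporally stable the learned spatial features are, independently of any
#' scrambling plan.
#'
#' @param model A `tdmnet_model` (or `tdmnet_fit`).
#' @param features A `feature_tensor_4d` or 5D array.
#' @param batch_size Sections per CNN forward pass.
#' @return Mean within-segment MMD (nonnegative scalar).
#' @export
feature_drift_mmd <- function(model, features, batch_size = 512L) {
  if (inherits(model, "tdmnet_fit")) model <- model$model
  x <- .feature_values(features)
  N <- dim(x)[1L]; S <- dim(x)[5L]
  d <- model$spec$cnn_output_dim
  nA <- ceiling(S / 2)
  total <- 0
  for (start in seq(1L, N, by = max(1L, batch_size %/% S))) {
    idx <- start:min(start + max(1L, batch_size %/% S) - 1L, N)
    B <- length(idx)
    secs <- array(aperm(x[idx, , , , , drop = FALSE], c(1L, 5L, 2L, 3L, 4L)),
                  dim = c(B * S, dim(x)[2L], dim(x)[3L], dim(x)[4L]))
    Pt <- array(cnn_encode(model, secs), dim = c(B, S, d))
    for (i in seq_len(B)) {
      Pm <- matrix(Pt[i, , ], S, d)
      total <- total + mmd(Pm[seq_len(nA), , drop = FALSE],
                           Pm[(nA + 1L):S, , drop = FALSE])
    }
  }
  total / N
}
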