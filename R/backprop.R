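# Hand-derived gradients for the CNN + parallel LSTM + heads, and the
# combined cross-entropy + temporal-difference objective. All passes are
# vectorized across the batch; convolution gradients reuse the column
# matrices cached by the forward pass.

# dh_final: [B x H] gradient on the final hidden state.
.lstm_backward <- function(p, fw, dh_final) {
  B <- fw$B; S <- fw$S; H <- fw$H; din <- fw$din
  dWx <- matrix(0, din, 4L * H); dWh <- matrix(0, H, 4L * H); db <- rep(0, 4L * H)
  dX <- array(0, dim = c(B, S, din))
  dh <- dh_final
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(S))) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh)
    dc <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

# dOut: [M x cnn_output_dim] gradient on the section features.
.cnn_backward <- function(model, cache, dOut) {
  s <- model$spec
  M <- cache$M; HW <- cache$HW
  # fc backward; ReLU mask from the recomputed pre-activation
  out <- sweep(cache$conv_out %*% model$params$fc$W, 2L, model$params$fc$b, "+")
  dZ <- dOut * (out > 0)
  g_fc <- list(W = crossprod(cache$conv_out, dZ), b = colSums(dZ))
  dx <- dZ %*% t(model$params$fc$W)
  g_conv <- vector("list", length(s$conv_filters))
  for (l in rev(seq_along(s$conv_filters))) {
    # ReLU mask: the layer output is the next layer's cached input
    layer_out <- if (l == length(s$conv_filters)) cache$conv_out else cache$inputs[[l + 1L]]
    dim(dx) <- c(M * HW, s$conv_filters[l])
    dim(layer_out) <- dim(dx)
    dz <- dx * (layer_out > 0)
    g_conv[[l]] <- list(W = crossprod(cache$cols[[l]], dz), b = colSums(dz))
    if (l > 1L) {
      dcol <- dz %*% t(model$params$conv[[l]]$W)
      dx <- .conv_cols_backward(dcol, cache$geoms[[l]], M, HW)
    }
  }
  list(conv = g_conv, fc = g_fc)
}

#' Combined training objective
#'
#' The total loss is the sum over the three heads of the cross-entropy with
#' the true label plus `mmd_weight` times the temporal-difference loss on the
#' section features (0 when ablated). Components are reported separately and
#' add up exactly.
#'
#' @param model A `tdmnet_model`.
#' @param x Feature batch `[B x 9 x 8 x 4 x 2T]` (or one segment).
#' @param y Integer class indices in `1..n_classes`.
#' @param plan A `branch_plan`.
#' @param mmd_weight Weight of the temporal-difference term (default 1).
#' @param kernel,bandwidth,squared MMD options, see [mmd()].
#' @param ablate_mmd Force the temporal-difference term to exactly 0.
#' @param ce_mode `"sum"` (default) adds the branch cross-entropies,
#'   `"mean"` averages them.
#' @return List with `total`, `ce`, `mmd` and the per-branch probabilities.
#' @export
total_loss <- function(model, x, y, plan, mmd_weight = 1, kernel = "linear",
                       bandwidth = NULL, squared = FALSE, ablate_mmd = FALSE,
                       ce_mode = c("sum", "mean")) {
  ce_mode <- match.arg(ce_mode)
  res <- .loss_and_grads(model, .as_batch5(x), y, plan,
                         mmd_weight = mmd_weight, kernel = kernel,
                         bandwidth = bandwidth, squared = squared,
                         ablate_mmd = ablate_mmd, ce_mode = ce_mode,
                         want_grads = FALSE)
  res[c("total", "ce", "mmd", "probabilities")]
}

.loss_and_grads <- function(model, x, y, plan, mmd_weight = 1,
                            kernel = "linear", bandwidth = NULL,
                            squared = FALSE, ablate_mmd = FALSE,
                            ce_mode = "sum", want_grads = TRUE) {
  s <- model$spec
  B <- dim(x)[1L]; S <- dim(x)[5L]
  y <- as.integer(y)
  if (any(y < 1L | y > s$n_classes)) {
    stop("labels must be class indices in 1..", s$n_classes)
  }
  fw <- .forward_full(model, x, plan, keep_cache = want_grads)
  branch_scale <- if (ce_mode == "mean") 1 / s$n_branches else 1
  ce <- 0
  dPt <- if (want_grads) array(0, dim = dim(fw$Pt_arr))
  grads <- if (want_grads) list(conv = NULL, fc = NULL,
                                lstm = vector("list", s$n_branches),
                                head = vector("list", s$n_branches))
  probs <- vector("list", s$n_branches)
  for (k in seq_len(s$n_branches)) {
    pr <- fw$branches[[k]]$probabilities
    probs[[k]] <- pr
    picked <- pr[cbind(seq_len(B), y)]
    ce <- ce + branch_scale * mean(-log(pmax(picked, 1e-300)))
    if (want_grads) {
      onehot <- matrix(0, B, s$n_classes)
      onehot[cbind(seq_len(B), y)] <- 1
      dlog <- branch_scale * (pr - onehot) / B
      hrep <- fw$branches[[k]]$representation
      grads$head[[k]] <- list(A = crossprod(hrep, dlog), b = colSums(dlog))
      dh <- dlog %*% t(model$params$head[[k]]$A)
      lb <- .lstm_backward(model$params$lstm[[k]], fw$lstm_caches[[k]], dh)
      grads$lstm[[k]] <- lb[c("Wx", "Wh", "b")]
      perm <- plan$permutations[[k]]
      dPt[, perm, ] <- dPt[, perm, , drop = FALSE] + lb$dX
    }
  }
  mmd_val <- 0
  if (!ablate_mmd && mmd_weight != 0) {
    if (want_grads) {
      td <- .td_loss_grad(fw$Pt_arr, plan, kernel = kernel,
                          bandwidth = bandwidth, squared = squared)
      mmd_val <- td$loss
      dPt <- dPt + mmd_weight * td$grad
    } else {
      mmd_val <- temporal_difference_loss(fw$Pt_arr, plan, kernel = kernel,
                                          bandwidth = bandwidth,
                                          squared = squared)
    }
  }
  total <- ce + mmd_weight * mmd_val
  out <- list(total = total, ce = ce, mmd = mmd_val, probabilities = probs,
              branches = fw$branches)
  if (want_grads) {
    dOut <- matrix(dPt, nrow = B * S)
    cb <- .cnn_backward(model, fw$cnn_cache, dOut)
    grads$conv <- cb$conv
    grads$fc <- cb$fc
    out$grads <- grads
  }
  out
}

# ---- Adam ----

.map_params <- function(f, ...) {
  walk <- function(...) {
    xs <- list(...)
    if (is.list(xs[[1L]])) {
      keys <- if (!is.null(names(xs[[1L]]))) names(xs[[1L]]) else seq_along(xs[[1L]])
      out <- vector("list", length(keys))
      names(out) <- names(xs[[1L]])
      for (i in seq_along(keys)) {
        out[[i]] <- do.call(walk, lapply(xs, `[[`, keys[[i]]))
      }
      out
    } else {
      do.call(f, xs)
    }
  }
  walk(...)
}

.zeros_like <- function(params) .map_params(function(p) p * 0, params)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .map_params(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- .map_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}
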