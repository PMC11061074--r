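#' Describe the network architecture
#'
#' The backbone is a per-section CNN encoder over the 9x8x4 DE map (four
#' same-padded convolution stages with ReLU, then a fully connected layer to
#' a 512-dimensional section feature), followed by three structurally
#' identical LSTM branches (128 units) over the permuted section sequences
#' and one linear-softmax head per branch.
#'
#' @param n_classes Number of output classes.
#' @param conv_filters Filter counts of the four convolution stages
#'   (default `c(64, 128, 256, 64)`; scale down for desk-scale runs).
#' @param conv_kernels Square kernel sizes per stage (default `c(5, 4, 4, 1)`).
#' @param cnn_output_dim Dimension of the per-section spatial feature
#'   (default 512).
#' @param lstm_units Hidden units per LSTM branch (default 128).
#' @param n_branches Number of parallel branches (default 3).
#' @param grid_dims Spatial map dimensions (default `c(9, 8)`).
#' @param in_channels Number of stacked band maps (default 4).
#' @param alphabet Optional label alphabet reported by prediction (e.g.
#'   `c(-1, 0, 1)` for negative/neutral/positive); defaults to `1:n_classes`.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_classes, conv_filters = c(64L, 128L, 256L, 64L),
                         conv_kernels = c(5L, 4L, 4L, 1L),
                         cnn_output_dim = 512L, lstm_units = 128L,
                         n_branches = 3L, grid_dims = c(9L, 8L),
                         in_channels = 4L, alphabet = NULL) {
  stopifnot(n_classes >= 2, length(conv_filters) == length(conv_kernels),
            cnn_output_dim >= 1, lstm_units >= 1, n_branches >= 1)
  if (is.null(alphabet)) alphabet <- seq_len(n_classes)
  if (length(alphabet) != n_classes) stop("alphabet length must equal n_classes")
  structure(
    list(n_classes = as.integer(n_classes),
         conv_filters = as.integer(conv_filters),
         conv_kernels = as.integer(conv_kernels),
         cnn_output_dim = as.integer(cnn_output_dim),
         lstm_units = as.integer(lstm_units),
         n_branches = as.integer(n_branches),
         grid_dims = as.integer(grid_dims),
         in_channels = as.integer(in_channels),
         alphabet = alphabet),
    class = "network_spec"
  )
}

#' Initialize network weights
#'
#' Glorot-uniform initialization for all dense and convolutional weights,
#' zero biases except the LSTM forget gate (bias 1). Deterministic given the
#' seed.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed.
#' @return A `tdmnet_model` holding `spec` and `params`.
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  glorot <- function(nin, nout, dims = c(nin, nout)) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(prod(dims), -lim, lim), dims[1L], dims[2L])
  }
  .with_seed(seed, {
    params <- list(conv = list(), lstm = list(), head = list())
    cin <- spec$in_channels
    for (l in seq_along(spec$conv_filters)) {
      k <- spec$conv_kernels[l]; f <- spec$conv_filters[l]
      fan_in <- k * k * cin
      params$conv[[l]] <- list(W = glorot(fan_in, f), b = rep(0, f))
      cin <- f
    }
    flat <- prod(spec$grid_dims) * cin
    params$fc <- list(W = glorot(flat, spec$cnn_output_dim),
                      b = rep(0, spec$cnn_output_dim))
    H <- spec$lstm_units; din <- spec$cnn_output_dim
    for (k in seq_len(spec$n_branches)) {
      b0 <- rep(0, 4L * H)
      b0[(H + 1L):(2L * H)] <- 1  # forget gate
      params$lstm[[k]] <- list(Wx = glorot(din, 4L * H, c(din, 4L * H)),
                               Wh = glorot(H, 4L * H, c(H, 4L * H)),
                               b = b0)
      params$head[[k]] <- list(A = glorot(H, spec$n_classes),
                               b = rep(0, spec$n_classes))
    }
    structure(list(spec = spec, params = params), class = "tdmnet_model")
  })
}

#' Number of trainable parameters
#' @param model A `tdmnet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "tdmnet_model"))
  sum(unlist(rapply(model$params, length, how = "unlist")))
}

#' @export
print.tdmnet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<tdmnet_model> conv [%s] -> fc %d -> %d x lstm(%d) -> %d classes; %s parameters\n",
              paste(s$conv_filters, collapse = ","), s$cnn_output_dim,
              s$n_branches, s$lstm_units, s$n_classes,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- convolution primitives (same padding, index-map gather + BLAS) ----
#
# The 9x8 spatial map is small, so convolutions are expressed as one padded
# scatter, one gather through a precomputed index map, and one BLAS matmul.
# Activations travel as [M x (H*W*C)] matrices (position-major, channel
# outer), which keeps every reshape an O(1) `dim<-`.

# Index geometry for a k x k same-padded convolution on an H x W x C input.
.conv_geom <- function(H, W, C, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + k - 1L; Wp <- W + k - 1L
  pos_h <- rep(seq_len(H), times = W)
  pos_w <- rep(seq_len(W), each = H)
  base <- function(i, j, c) (pos_h + i - 1L) + Hp * (pos_w + j - 2L) + Hp * Wp * (c - 1L)
  gather <- matrix(0L, H * W, k * k * C)
  n <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) for (c in seq_len(C)) {
    n <- n + 1L
    gather[, n] <- base(i, j, c)
  }
  interior <- vapply(seq_len(C), function(c) base(p + 1L, p + 1L, c),
                     integer(H * W))
  list(k = k, C = C, Hp = Hp, Wp = Wp, gather = gather,
       interior = as.vector(interior))
}

# x: [M x (H*W*C)] activation matrix -> [(M*H*W) x (k*k*C)] column matrix.
.conv_cols <- function(x, g, M, HW) {
  if (g$k == 1L) {
    dim(x) <- c(M * HW, g$C)
    return(x)
  }
  Xp <- matrix(0, M, g$Hp * g$Wp * g$C)
  Xp[, g$interior] <- x
  col <- Xp[, as.vector(g$gather)]
  dim(col) <- c(M * HW, g$k * g$k * g$C)
  col
}

# Scatter-add the column gradient back to the activation layout.
.conv_cols_backward <- function(dcol, g, M, HW) {
  if (g$k == 1L) {
    dim(dcol) <- c(M, HW * g$C)
    return(dcol)
  }
  dim(dcol) <- c(M, HW * g$k * g$k * g$C)
  dXp <- matrix(0, M, g$Hp * g$Wp * g$C)
  blk <- HW * g$C
  for (off in seq_len(g$k * g$k)) {
    gidx <- as.vector(g$gather[, ((off - 1L) * g$C + 1L):(off * g$C)])
    dXp[, gidx] <- dXp[, gidx] + dcol[, ((off - 1L) * blk + 1L):(off * blk)]
  }
  dXp[, g$interior]
}

# Forward through the conv stack + fc. sections: [M, H, W, C].
# Returns list(out = M x cnn_output_dim, cache).
.cnn_forward <- function(model, sections) {
  s <- model$spec
  d <- dim(sections)
  if (length(d) != 4L || d[2L] != s$grid_dims[1L] || d[3L] != s$grid_dims[2L] ||
      d[4L] != s$in_channels) {
    stop("sections must be [M x ", s$grid_dims[1L], " x ", s$grid_dims[2L],
         " x ", s$in_channels, "]")
  }
  M <- d[1L]; H <- d[2L]; W <- d[3L]; HW <- H * W
  nl <- length(s$conv_filters)
  x <- sections
  dim(x) <- c(M, HW * s$in_channels)
  inputs <- cols <- geoms <- vector("list", nl)
  cin <- s$in_channels
  for (l in seq_len(nl)) {
    inputs[[l]] <- x
    g <- .conv_geom(H, W, cin, s$conv_kernels[l])
    geoms[[l]] <- g
    col <- .conv_cols(x, g, M, HW)
    cols[[l]] <- col
    z <- col %*% model$params$conv[[l]]$W
    z <- sweep(z, 2L, model$params$conv[[l]]$b, "+")
    z[z < 0] <- 0
    x <- z
    dim(x) <- c(M, HW * s$conv_filters[l])
    cin <- s$conv_filters[l]
  }
  conv_out <- x
  z <- x %*% model$params$fc$W
  z <- sweep(z, 2L, model$params$fc$b, "+")
  z[z < 0] <- 0
  list(out = z, cache = list(inputs = inputs, cols = cols, geoms = geoms,
                             conv_out = conv_out, M = M, HW = HW))
}

#' Encode DE section maps into spatial feature vectors
#'
#' Applies the shared CNN encoder independently to each section map.
#'
#' @param model A `tdmnet_model`.
#' @param sections A single `9x8x4` array or a batch `[M x 9 x 8 x 4]`.
#' @return A `M x cnn_output_dim` matrix, or a plain vector for a single
#'   section.
#' @export
cnn_encode <- function(model, sections) {
  stopifnot(inherits(model, "tdmnet_model"))
  single <- length(dim(sections)) == 3L
  if (single) sections <- array(sections, dim = c(1L, dim(sections)))
  out <- .cnn_forward(model, sections)$out
  if (single) drop(out) else out
}

# ---- LSTM ----

# Xseq: [B, S, din]; returns final hidden state and cache for BPTT.
.lstm_forward <- function(p, Xseq) {
  d <- dim(Xseq); B <- d[1L]; S <- d[2L]; din <- d[3L]
  H <- length(p$b) %/% 4L
  if (nrow(p$Wx) != din) {
    stop("LSTM input dimension mismatch: expected ", nrow(p$Wx), ", got ", din)
  }
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  cache <- vector("list", S)
  for (t in seq_len(S)) {
    xt <- matrix(Xseq[, t, ], B, din)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2L, p$b, "+")
    i <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, (H + 1):(2 * H), drop = FALSE]))
    o <- 1 / (1 + exp(-z[, (2 * H + 1):(3 * H), drop = FALSE]))
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    h_prev <- h; c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, o = o, g = g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(h = h, cache = cache, B = B, S = S, H = H, din = din)
}

#' Run one LSTM branch over a section-feature sequence
#'
#' @param model A `tdmnet_model`.
#' @param seq A `sections x d` matrix or `[B x sections x d]` array, already
#'   in the branch's permuted order.
#' @param branch Branch index.
#' @return The final hidden state (`B x lstm_units` matrix, or a vector for a
#'   single sequence).
#' @export
lstm_branch <- function(model, seq, branch = 1L) {
  stopifnot(inherits(model, "tdmnet_model"))
  single <- is.matrix(seq)
  if (single) seq <- array(seq, dim = c(1L, dim(seq)))
  out <- .lstm_forward(model$params$lstm[[branch]], seq)$h
  if (single) drop(out) else out
}

# ---- heads ----

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Linear-softmax head of one branch
#'
#' @param model A `tdmnet_model`.
#' @param representation `B x lstm_units` matrix (or a vector).
#' @param branch Branch index.
#' @return A list with `probabilities` (rows on the simplex) and `label`
#'   (argmax, in the spec's alphabet).
#' @export
head_forward <- function(model, representation, branch = 1L) {
  stopifnot(inherits(model, "tdmnet_model"))
  if (is.null(dim(representation))) representation <- matrix(representation, 1L)
  p <- model$params$head[[branch]]
  probs <- .softmax(sweep(representation %*% p$A, 2L, p$b, "+"))
  idx <- max.col(probs, ties.method = "first")
  list(probabilities = probs, label = model$spec$alphabet[idx])
}

#' Full forward pass of the temporal-difference minimizing network
#'
#' Encodes every section with the shared CNN, reorders sections per branch
#' according to the plan, runs each branch's LSTM and head, and exposes the
#' section features for the temporal-difference loss.
#'
#' @param model A `tdmnet_model`.
#' @param x A single segment tensor `[9 x 8 x 4 x 2T]` or a batch
#'   `[B x 9 x 8 x 4 x 2T]`.
#' @param plan A `branch_plan` with `n_branches` matching the model.
#' @return A list: `Pt` (`[B x 2T x d]` section features), `branches` (per
#'   branch: `probabilities`, `label`, `representation`).
#' @export
network_forward <- function(model, x, plan) {
  stopifnot(inherits(model, "tdmnet_model"), inherits(plan, "branch_plan"))
  if (plan$n_branches != model$spec$n_branches) {
    stop("plan has ", plan$n_branches, " branches; model expects ",
         model$spec$n_branches)
  }
  fw <- .forward_full(model, .as_batch5(x), plan)
  list(Pt = fw$Pt_arr, branches = fw$branches)
}

.as_batch5 <- function(x) {
  if (length(dim(x)) == 4L) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 5L) stop("x must be a 4D segment tensor or a 5D batch")
  x
}

# Shared forward used by inference and training. Returns caches when
# keep_cache = TRUE.
.forward_full <- function(model, x, plan, keep_cache = FALSE) {
  s <- model$spec
  d <- dim(x); B <- d[1L]; S <- d[5L]
  if (S != plan$two_T) stop("tensor has ", S, " sections; plan expects ", plan$two_T)
  # sections-major: [B*S, H, W, C], batch index fastest
  secs <- array(aperm(x, c(1L, 5L, 2L, 3L, 4L)), dim = c(B * S, d[2L], d[3L], d[4L]))
  cnn <- .cnn_forward(model, secs)
  Pt_arr <- array(cnn$out, dim = c(B, S, s$cnn_output_dim))
  branches <- vector("list", s$n_branches)
  lstm_caches <- vector("list", s$n_branches)
  for (k in seq_len(s$n_branches)) {
    perm <- plan$permutations[[k]]
    seqk <- Pt_arr[, perm, , drop = FALSE]
    lf <- .lstm_forward(model$params$lstm[[k]], seqk)
    hd <- head_forward(model, lf$h, branch = k)
    branches[[k]] <- list(probabilities = hd$probabilities, label = hd$label,
                          representation = lf$h)
    if (keep_cache) lstm_caches[[k]] <- lf
  }
  out <- list(Pt_arr = Pt_arr, branches = branches, B = B, S = S)
  if (keep_cache) {
    out$cnn_cache <- cnn$cache
    out$lstm_caches <- lstm_caches
  }
  out
}
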