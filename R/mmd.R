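#' Maximum mean discrepancy between two sample groups
#'
#' Empirical MMD between the rows of `X` and the rows of `Y`. With the linear
#' kernel this is the Euclidean norm of the difference of the group means,
#' the literal empirical form of the mean-embedding distance; with the RBF
#' kernel it is the square root of the biased V-statistic
#' `mean k(x,x') + mean k(y,y') - 2 mean k(x,y)` (all pairs, diagonal
#' included).
#'
#' @param X,Y Numeric matrices with one sample per row and a common number of
#'   columns.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param bandwidth RBF length scale; `NULL` (default) uses the median
#'   heuristic over the pooled pairwise distances.
#' @param squared Return MMD^2 instead of MMD.
#' @return A nonnegative scalar.
#' @examples
#' mmd(matrix(c(1, 0), 1), matrix(c(0, 0), 1))  # 1
#' @export
mmd <- function(X, Y, kernel = c("linear", "rbf"), bandwidth = NULL,
                squared = FALSE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("dimension mismatch: X has ", ncol(X), " columns, Y has ", ncol(Y))
  }
  if (nrow(X) < 1L || nrow(Y) < 1L) stop("both groups must be non-empty")
  if (kernel == "linear") {
    d2 <- sum((colMeans(X) - colMeans(Y))^2)
    return(if (squared) d2 else sqrt(d2))
  }
  bw <- if (is.null(bandwidth)) median_bandwidth(rbind(X, Y)) else bandwidth
  if (bw <= 0) stop("rbf bandwidth must be positive")
  m2 <- mean(.rbf_gram(X, X, bw)) + mean(.rbf_gram(Y, Y, bw)) -
    2 * mean(.rbf_gram(X, Y, bw))
  m2 <- max(m2, 0)
  if (squared) m2 else sqrt(m2)
}

#' Median-heuristic RBF bandwidth
#'
#' Median of the pairwise Euclidean distances between distinct rows of `Z`.
#'
#' @param Z Numeric matrix of pooled samples.
#' @return A positive length scale (falls back to 1 when all points coincide).
#' @export
median_bandwidth <- function(Z) {
  d <- stats::dist(Z)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

.rbf_gram <- function(A, B, bw) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * bw^2))
}

#' Draw a multibranch scramble-and-split plan
#'
#' For each of `n_branches` branches, draws an independent random permutation
#' of the `two_T` section indices and splits the permuted order into two
#' groups (first `ceiling(two_T/2)` vs the rest). The plan is a pure function
#' of `(seed, two_T, n_branches)`.
#'
#' @param two_T Number of sections per segment (at least 2).
#' @param n_branches Number of branches (default 3).
#' @param seed Integer seed.
#' @return A `branch_plan`: permutations and `A`/`B` group index sets per
#'   branch.
#' @export
make_branch_plan <- function(two_T, n_branches = 3L, seed = 1L) {
  if (two_T < 2L) stop("two_T must be at least 2")
  two_T <- as.integer(two_T); n_branches <- as.integer(n_branches)
  nA <- ceiling(two_T / 2)
  .with_seed(seed, {
    perms <- lapply(seq_len(n_branches), function(k) sample.int(two_T))
    groups <- lapply(perms, function(p) {
      list(A = p[seq_len(nA)], B = p[(nA + 1L):two_T])
    })
    structure(list(n_branches = n_branches, two_T = two_T,
                   permutations = perms, groups = groups, seed = seed),
              class = "branch_plan")
  })
}

#' @export
print.branch_plan <- function(x, ...) {
  cat(sprintf("<branch_plan> %d branches over %d sections (seed %d)\n",
              x$n_branches, x$two_T, x$seed))
  for (k in seq_len(x$n_branches)) {
    cat(sprintf("  branch %d: order %s | A={%s} B={%s}\n", k,
                paste(x$permutations[[k]], collapse = ","),
                paste(x$groups[[k]]$A, collapse = ","),
                paste(x$groups[[k]]$B, collapse = ",")))
  }
  invisible(x)
}

#' Temporal-difference loss of a batch of section-feature sequences
#'
#' For every segment in the batch, sums the MMD between the two scrambled
#' section groups of each branch, then averages over the batch. Minimizing
#' this value during training expresses the prior that emotional EEG features
#' are stable within a segment.
#'
#' @param Pt_batch Either a `sections x d` matrix (a single segment) or a
#'   `batch x sections x d` array.
#' @param plan A `branch_plan` whose `two_T` matches the section count.
#' @inheritParams mmd
#' @return A nonnegative scalar.
#' @export
temporal_difference_loss <- function(Pt_batch, plan, kernel = c("linear", "rbf"),
                                     bandwidth = NULL, squared = FALSE) {
  kernel <- match.arg(kernel)
  arr <- .as_pt_array(Pt_batch, plan)
  B <- dim(arr)[1L]
  total <- 0
  for (i in seq_len(B)) {
    Pt <- matrix(arr[i, , ], dim(arr)[2L], dim(arr)[3L])
    for (k in seq_len(plan$n_branches)) {
      g <- plan$groups[[k]]
      total <- total + mmd(Pt[g$A, , drop = FALSE], Pt[g$B, , drop = FALSE],
                           kernel = kernel, bandwidth = bandwidth,
                           squared = squared)
    }
  }
  total / B
}

.as_pt_array <- function(Pt_batch, plan) {
  if (is.matrix(Pt_batch)) {
    Pt_batch <- array(Pt_batch, dim = c(1L, dim(Pt_batch)))
  }
  if (length(dim(Pt_batch)) != 3L) {
    stop("Pt_batch must be a sections x d matrix or batch x sections x d array")
  }
  if (dim(Pt_batch)[2L] != plan$two_T) {
    stop("plan expects ", plan$two_T, " sections, got ", dim(Pt_batch)[2L])
  }
  Pt_batch
}

# Loss and gradient wrt the section features. Returns list(loss, grad) with
# grad the same shape as the input array. The RBF bandwidth, when taken from
# the median heuristic, is treated as a constant (no gradient through it).
.td_loss_grad <- function(arr, plan, kernel = "linear", bandwidth = NULL,
                          squared = FALSE, eps = 1e-12) {
  B <- dim(arr)[1L]; S <- dim(arr)[2L]; d <- dim(arr)[3L]
  grad <- array(0, dim = dim(arr))
  total <- 0
  if (kernel == "linear") {
    for (k in seq_len(plan$n_branches)) {
      g <- plan$groups[[k]]
      nA <- length(g$A); nB <- length(g$B)
      # group means per batch item: B x d (colSums over the section axis)
      mA <- colSums(aperm(arr[, g$A, , drop = FALSE], c(2L, 1L, 3L)), dims = 1L) / nA
      mB <- colSums(aperm(arr[, g$B, , drop = FALSE], c(2L, 1L, 3L)), dims = 1L) / nB
      diff <- mA - mB
      nrm <- sqrt(rowSums(diff^2))
      if (squared) {
        total <- total + sum(nrm^2)
        dd <- 2 * diff
      } else {
        total <- total + sum(nrm)
        dd <- diff / pmax(nrm, eps)
        dd[nrm < eps, ] <- 0
      }
      for (s in g$A) grad[, s, ] <- grad[, s, ] + dd / nA
      for (s in g$B) grad[, s, ] <- grad[, s, ] - dd / nB
    }
  } else {
    for (i in seq_len(B)) {
      Pt <- matrix(arr[i, , ], S, d)
      for (k in seq_len(plan$n_branches)) {
        g <- plan$groups[[k]]
        res <- .rbf_mmd_grad(Pt[g$A, , drop = FALSE], Pt[g$B, , drop = FALSE],
                             bandwidth, squared, eps)
        total <- total + res$value
        grad[i, g$A, ] <- grad[i, g$A, ] + res$gX
        grad[i, g$B, ] <- grad[i, g$B, ] + res$gY
      }
    }
  }
  list(loss = total / B, grad = grad / B)
}

# Value and gradients of (squared) RBF MMD for one group pair.
.rbf_mmd_grad <- function(X, Y, bandwidth, squared, eps) {
  bw <- if (is.null(bandwidth)) median_bandwidth(rbind(X, Y)) else bandwidth
  n <- nrow(X); m <- nrow(Y)
  Kxx <- .rbf_gram(X, X, bw); Kyy <- .rbf_gram(Y, Y, bw); Kxy <- .rbf_gram(X, Y, bw)
  m2 <- max(mean(Kxx) + mean(Kyy) - 2 * mean(Kxy), 0)
  # d/dx_i of mean(Kxx): (2/n^2) sum_j Kxx[i,j] (x_j - x_i) / bw^2
  gX <- (2 / n^2) * (Kxx %*% X - rowSums(Kxx) * X) / bw^2 -
    (2 / (n * m)) * (Kxy %*% Y - rowSums(Kxy) * X) / bw^2
  gY <- (2 / m^2) * (Kyy %*% Y - rowSums(Kyy) * Y) / bw^2 -
    (2 / (n * m)) * (t(Kxy) %*% X - colSums(Kxy) * Y) / bw^2
  if (squared) {
    list(value = m2, gX = gX, gY = gY)
  } else {
    v <- sqrt(m2)
    sc <- 1 / (2 * max(v, eps))
    list(value = v, gX = gX * sc, gY = gY * sc)
  }
}
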