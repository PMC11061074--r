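# Maximum mean discrepancy: estimators, branch plans, temporal-difference
# loss and its gradients.

# Independent loop-based oracles (no vectorized algebra shared with the
# implementation).
mmd_linear_oracle <- function(X, Y) {
  d <- ncol(X)
  mx <- my <- numeric(d)
  for (i in seq_len(nrow(X))) mx <- mx + X[i, ] / nrow(X)
  for (j in seq_len(nrow(Y))) my <- my + Y[j, ] / nrow(Y)
  sqrt(sum((mx - my)^2))
}

mmd_rbf_oracle <- function(X, Y, bw) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * bw^2))
  n <- nrow(X); m <- nrow(Y)
  sxx <- syy <- sxy <- 0
  for (i in 1:n) for (j in 1:n) sxx <- sxx + k(X[i, ], X[j, ])
  for (i in 1:m) for (j in 1:m) syy <- syy + k(Y[i, ], Y[j, ])
  for (i in 1:n) for (j in 1:m) sxy <- sxy + k(X[i, ], Y[j, ])
  sqrt(max(sxx / n^2 + syy / m^2 - 2 * sxy / (n * m), 0))
}

test_that("linear-kernel MMD is the norm of the group-mean difference", {
  expect_equal(mmd(matrix(c(1, 0), 1), matrix(c(0, 0), 1)), 1.0)
  X <- matrix(rnorm(12), 4)
  expect_equal(mmd(X, X), 0)
  set.seed(10)
  for (i in 1:20) {
    X <- matrix(rnorm(3 * 5), 3); Y <- matrix(rnorm(4 * 5), 4)
    expect_equal(mmd(X, Y), mmd_linear_oracle(X, Y), tolerance = 1e-12)
  }
  expect_error(mmd(matrix(0, 1, 2), matrix(0, 1, 3)), "dimension")
})

test_that("RBF MMD matches the brute-force double-loop kernel oracle", {
  set.seed(11)
  for (i in 1:20) {
    X <- matrix(rnorm(9), 3); Y <- matrix(rnorm(9), 3)
    bw <- runif(1, 0.5, 2)
    expect_equal(mmd(X, Y, kernel = "rbf", bandwidth = bw),
                 mmd_rbf_oracle(X, Y, bw), tolerance = 1e-8)
  }
  # identical groups give zero for the rbf kernel too
  X <- matrix(rnorm(9), 3)
  expect_equal(mmd(X, X, kernel = "rbf"), 0, tolerance = 1e-8)
})

test_that("MMD is symmetric and nonnegative for both kernels", {
  set.seed(12)
  for (i in 1:10) {
    X <- matrix(rnorm(8), 2); Y <- matrix(rnorm(12), 3)
    for (k in c("linear", "rbf")) {
      v1 <- mmd(X, Y, kernel = k, bandwidth = 1)
      v2 <- mmd(Y, X, kernel = k, bandwidth = 1)
      expect_gte(v1, 0)
      expect_equal(v1, v2, tolerance = 1e-12)
    }
  }
})

test_that("branch plans are seeded bijections split into two covering groups", {
  p <- make_branch_plan(6, 3, seed = 21)
  expect_length(p$permutations, 3)
  for (k in 1:3) {
    expect_setequal(p$permutations[[k]], 1:6)
    expect_length(p$groups[[k]]$A, 3)
    expect_length(p$groups[[k]]$B, 3)
    expect_setequal(c(p$groups[[k]]$A, p$groups[[k]]$B), 1:6)
  }
  # odd section counts split ceiling/floor
  p5 <- make_branch_plan(5, 3, seed = 21)
  expect_length(p5$groups[[1]]$A, 3)
  expect_length(p5$groups[[1]]$B, 2)
  # pure function of the seed
  expect_identical(make_branch_plan(6, 3, seed = 21), p)
  expect_false(identical(make_branch_plan(6, 3, seed = 22)$permutations,
                         p$permutations))
  expect_error(make_branch_plan(1, 3, seed = 1), "at least 2")
})

test_that("temporal-difference loss is zero for stable features and additive over branches", {
  plan <- make_branch_plan(6, 3, seed = 31)
  Pt <- matrix(rep(rnorm(8), each = 6), 6)  # all sections identical
  expect_equal(temporal_difference_loss(Pt, plan), 0)
  # one branch, group means differing by (3, 4, 0, ...) -> loss 5
  plan1 <- make_branch_plan(6, 1, seed = 32)
  Pt2 <- matrix(0, 6, 8)
  Pt2[plan1$groups[[1]]$A, 1] <- 3
  Pt2[plan1$groups[[1]]$A, 2] <- 4
  expect_equal(temporal_difference_loss(Pt2, plan1), 5)
})

test_that("temporal-difference loss equals a loop-based recomputation", {
  set.seed(13)
  plan <- make_branch_plan(6, 3, seed = 33)
  arr <- array(rnorm(4 * 6 * 7), dim = c(4, 6, 7))
  for (kern in c("linear", "rbf")) {
    got <- temporal_difference_loss(arr, plan, kernel = kern, bandwidth = 1.3)
    want <- 0
    for (i in 1:4) {
      Pt <- matrix(arr[i, , ], 6, 7)
      for (k in 1:3) {
        A <- Pt[plan$groups[[k]]$A, , drop = FALSE]
        B <- Pt[plan$groups[[k]]$B, , drop = FALSE]
        want <- want + if (kern == "linear") mmd_linear_oracle(A, B)
                       else mmd_rbf_oracle(A, B, 1.3)
      }
    }
    expect_equal(got, want / 4, tolerance = 1e-8, info = kern)
  }
})

test_that("reordering vectors within a group leaves the loss unchanged", {
  set.seed(14)
  arr <- array(rnorm(2 * 6 * 5), dim = c(2, 6, 5))
  for (seed in 34:36) {
    plan <- make_branch_plan(6, 1, seed = seed)
    g <- plan$groups[[1]]
    base <- temporal_difference_loss(arr, plan)
    arr2 <- arr
    arr2[, g$A, ] <- arr[, rev(g$A), ]  # swap members within group A
    expect_equal(temporal_difference_loss(arr2, plan), base, tolerance = 1e-12)
    arr3 <- arr
    arr3[, g$B, ] <- arr[, rev(g$B), ]
    expect_equal(temporal_difference_loss(arr3, plan), base, tolerance = 1e-12)
  }
})

test_that("squared linear MMD gradient is 2 (mean(X) - mean(Y)) / n per member", {
  set.seed(15)
  plan <- make_branch_plan(6, 1, seed = 35)
  arr <- array(rnorm(1 * 6 * 4), dim = c(1, 6, 4))
  res <- tdmnet:::.td_loss_grad(arr, plan, kernel = "linear", squared = TRUE)
  Pt <- matrix(arr[1, , ], 6, 4)
  g <- plan$groups[[1]]
  diff <- colMeans(Pt[g$A, ]) - colMeans(Pt[g$B, ])
  for (s in g$A) {
    expect_equal(res$grad[1, s, ], 2 * diff / length(g$A), tolerance = 1e-12)
  }
})

test_that("temporal-difference gradients match finite differences for both kernels", {
  set.seed(16)
  plan <- make_branch_plan(4, 2, seed = 36)
  arr <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  for (kern in c("linear", "rbf")) {
    res <- tdmnet:::.td_loss_grad(arr, plan, kernel = kern, bandwidth = 1.1)
    f <- function(a) temporal_difference_loss(a, plan, kernel = kern,
                                              bandwidth = 1.1)
    eps <- 1e-6
    for (probe in 1:8) {
      i <- sample(length(arr), 1)
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      fd <- (f(a1) - f(a2)) / (2 * eps)
      expect_equal(res$grad[i], fd, tolerance = 1e-5, info = kern)
    }
  }
})

test_that("gradient descent on free vectors drives the group means together", {
  set.seed(17)
  plan <- make_branch_plan(6, 1, seed = 37)
  arr0 <- array(rnorm(1 * 6 * 4, sd = 2), dim = c(1, 6, 4))
  # squared MMD: smooth objective, descent is monotone
  arr <- arr0
  losses <- numeric(100)
  for (it in 1:100) {
    res <- tdmnet:::.td_loss_grad(arr, plan, squared = TRUE)
    losses[it] <- res$loss
    arr <- arr - 0.1 * res$grad
  }
  expect_true(all(diff(losses) <= 1e-8))
  expect_lt(losses[100], 1e-3 * losses[1])
  # plain MMD: the norm gradient has constant magnitude, so descent reaches a
  # small floor set by the step size rather than oscillating at scale
  arr <- arr0
  losses <- numeric(100)
  for (it in 1:100) {
    res <- tdmnet:::.td_loss_grad(arr, plan)
    losses[it] <- res$loss
    arr <- arr - 0.1 * res$grad
  }
  expect_lt(losses[100], 0.05 * losses[1])
})
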