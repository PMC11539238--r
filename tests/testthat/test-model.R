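test_that("encode/decode match a direct dense-product oracle", {
  set.seed(51)
  for (case in 1:5) {
    n <- sample(4:20, 1); d <- sample(3:8, 1); dp <- sample(2:6, 1)
    A <- knn_oracle(matrix(rnorm(n * 2), n, 2), 2)
    S <- sym_normalize(A)
    X <- matrix(rnorm(d * n), d, n)
    p <- init_model_params(d, dp, 1, seed = case)
    H <- encode(X, S, p)
    pre <- p$We[[1]] %*% X %*% S
    expect_equal(H, ifelse(pre > 0, pre, p$ae[1] * pre), tolerance = 1e-6)
    Xp <- decode(H, S, p)
    pre_d <- p$Wd[[1]] %*% H %*% S
    expect_equal(Xp, ifelse(pre_d > 0, pre_d, p$ad[1] * pre_d),
                 tolerance = 1e-6)
    expect_equal(dim(Xp), c(d, n))
  }
})

test_that("encoder boundary behaviour: identity weights and zero input", {
  n <- 4; d <- 3
  p <- init_model_params(d, d, 1, seed = 1)
  p$We[[1]] <- diag(d)
  X <- matrix(abs(rnorm(d * n)), d, n)
  expect_equal(encode(X, diag(n), p), X)   # PReLU is identity on >= 0
  expect_equal(encode(matrix(0, d, n), diag(n), p), matrix(0, d, n))
  expect_error(encode(X, diag(5), p), "conform")
})

test_that("multi-layer encoder stacks propagation and stays differentiable", {
  rv <- random_views(n = 8, d = 5, seed = 77)
  p <- init_model_params(5, 4, 2, seed = 2)
  H <- encode(rv$X, rv$S, p)
  expect_equal(dim(H), c(4L, 8L))
  # manual two-layer composition
  h1 <- stgcl:::prelu(p$We[[1]] %*% rv$X %*% rv$S, p$ae[1])
  h2 <- stgcl:::prelu(p$We[[2]] %*% h1 %*% rv$S, p$ae[2])
  expect_equal(H, h2)
})

test_that("readout and discriminator obey their closed forms", {
  H <- matrix(0, 4, 6)
  expect_equal(readout(H), rep(0.5, 4))
  H1 <- matrix(rnorm(12), 4, 3)
  expect_equal(readout(H1[, c(3, 1, 2)]), readout(H1))
  expect_equal(readout(H1[, 2, drop = FALSE]), plogis(H1[, 2]))

  W <- diag(4)
  h <- rnorm(4); c1 <- rnorm(4); c2 <- rnorm(4)
  expect_equal(discriminate(rep(0, 4), c1, c2, W), 0.5)
  expect_equal(discriminate(h, c1, c2, W), discriminate(h, c2, c1, W))
  big <- c(100, 0, 0, 0)
  expect_gt(discriminate(big, big, big, W), 1 - 1e-10)
})

test_that("losses hit their closed-form values and limits", {
  n <- 6; dp <- 4
  H <- matrix(rnorm(dp * n), dp, n)
  Hn <- matrix(rnorm(dp * n), dp, n)
  W0 <- matrix(0, dp, dp)  # constant-1/2 discriminator
  expect_equal(loss_local_global(H, Hn, rnorm(dp), rnorm(dp), W0), log(2),
               tolerance = 1e-9)
  expect_equal(loss_subspace(H, Hn, H, H, W0), log(2), tolerance = 1e-9)

  # perfect discrimination drives the loss towards zero
  Hp <- matrix(0, 2, 1); Hp[1, 1] <- 100
  Hneg <- -Hp
  s <- c(100, 0)
  expect_lt(loss_local_global(Hp, Hneg, s, s, diag(2)), 1e-6)

  # permutation invariance
  perm <- sample(n)
  s1 <- rnorm(dp); s2 <- rnorm(dp)
  expect_equal(loss_local_global(H[, perm], Hn[, perm], s1, s2, diag(dp)),
               loss_local_global(H, Hn, s1, s2, diag(dp)))

  # clamping keeps extreme logits finite
  expect_true(is.finite(loss_local_global(1e6 * H, 1e6 * Hn, s1, s2, diag(dp))))

  # reconstruction loss: single residual entry of 2 with n = 4 gives 1
  X <- matrix(0, 3, 4); Xp <- X; Xp[2, 3] <- 2
  expect_equal(loss_recon(X, Xp), 1.0)
  expect_equal(loss_recon(X, X), 0)
  expect_equal(loss_recon(X, 2 * Xp), 4 * loss_recon(X, Xp))  # quadratic
  expect_error(loss_recon(X, matrix(0, 2, 2)), "shape")

  expect_equal(total_loss(1, 1, 1), 3)
  expect_equal(total_loss(1, 5, 7, lambda1 = 0, lambda2 = 0), 1)
  expect_equal(total_loss(2, 3, 4, 0.5, 0.25), 2 + 1.5 + 1)
})

test_that("analytic gradients match central finite differences", {
  rv <- random_views(n = 10, d = 6, seed = 42)
  p <- init_model_params(6, 5, 1, seed = 3)
  set.seed(8)
  C <- matrix(rnorm(100, sd = 0.2), 10, 10)
  fb <- stgcl:::forward_backward(p, rv$views, C, 1, 1)
  g_an <- stgcl:::flatten_params(fb$grads)
  f <- function(v)
    stgcl:::forward_backward(stgcl:::unflatten_params(v, p), rv$views, C,
                             1, 1, grad = FALSE)$loss
  g_num <- numeric_grad(f, stgcl:::flatten_params(p))
  rel <- sqrt(sum((g_an - g_num)^2)) / sqrt(sum(g_num^2))
  expect_lt(rel, 1e-6)

  # loss components recomputed by the public functions agree with the pass
  S <- rv$views$orig$S
  H <- encode(rv$views$orig$X, S, p)
  Hn <- encode(rv$views$neg$X, rv$views$neg$S, p)
  H1 <- encode(rv$views$pos1$X, rv$views$pos1$S, p)
  H2 <- encode(rv$views$pos2$X, rv$views$pos2$S, p)
  Z <- reconstruct_views(H1, H2, C)
  expect_equal(fb$global,
               loss_local_global(H, Hn, readout(H1), readout(H2), p$Wg))
  expect_equal(fb$subspace, loss_subspace(H, Hn, Z$Z1, Z$Z2, p$Ws))
  expect_equal(fb$recon, loss_recon(rv$views$orig$X, decode(H, S, p)))
})

test_that("gradients also check out for a 2-layer model and ablated losses", {
  rv <- random_views(n = 8, d = 5, seed = 13)
  p <- init_model_params(5, 4, 2, seed = 5)
  set.seed(14)
  C <- matrix(rnorm(64, sd = 0.2), 8, 8)
  for (lam in list(c(1, 1), c(0, 1), c(1, 0))) {
    fb <- stgcl:::forward_backward(p, rv$views, C, lam[1], lam[2])
    f <- function(v)
      stgcl:::forward_backward(stgcl:::unflatten_params(v, p), rv$views, C,
                               lam[1], lam[2], grad = FALSE)$loss
    g_num <- numeric_grad(f, stgcl:::flatten_params(p))
    g_an <- stgcl:::flatten_params(fb$grads)
    expect_lt(max(abs(g_an - g_num)), 1e-6)
  }
})
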