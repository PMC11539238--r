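# Small, fast training configurations are used throughout; the full default
# schedule is exercised by the end-to-end recovery tests in
# test-acceptance.R.

small_sim <- function(seed = 1) {
  sim <- simulate_spatial_grid(rows = 8, cols = 8, n_domains = 2,
                               n_genes = 30, markers_per_domain = 4,
                               seed = seed)
  list(sim = sim, ds = preprocess_st(sim$dataset))
}

small_control <- function(max_iters = 30, refresh_every = 10, ...) {
  stgcl_control(max_iters = max_iters, refresh_every = refresh_every,
                k_spatial = 5, k_expr = 5, top_k = 5, hidden_dim = 16, ...)
}

test_that("untrained fit returns the initial embedding and empty trace", {
  s <- small_sim()
  fit <- stgcl(s$ds, morphology = s$sim$morphology,
               control = small_control(max_iters = 0, refresh_every = 1))
  expect_equal(nrow(fit$loss_trace), 0L)
  expect_equal(dim(fit$embedding), c(16L, 64L))
  # the embedding is the encoder applied to the data at initialization
  p0 <- init_model_params(nrow(s$ds$counts), 16, 1, seed = 1)
  expect_equal(fit$embedding, encode(s$ds$counts, fit$S_hat, p0))
})

test_that("training is reproducible and the loss trace is finite", {
  s <- small_sim()
  f1 <- stgcl(s$ds, morphology = s$sim$morphology, control = small_control())
  f2 <- stgcl(s$ds, morphology = s$sim$morphology, control = small_control())
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$embedding, f2$embedding)
  expect_true(all(is.finite(as.matrix(f1$loss_trace))))
  expect_equal(nrow(f1$loss_trace), 30L)
  expect_equal(f1$loss_trace$total,
               with(f1$loss_trace, global + subspace + recon))
  # different seed changes the trajectory
  f3 <- stgcl(s$ds, morphology = s$sim$morphology,
              control = small_control(seed = 2))
  expect_false(identical(f1$loss_trace, f3$loss_trace))
})

test_that("loss decreases over training on structured data", {
  s <- small_sim()
  fit <- stgcl(s$ds, morphology = s$sim$morphology,
               control = small_control(max_iters = 60, refresh_every = 20))
  expect_lt(fit$loss_trace$total[60], fit$loss_trace$total[1])
})

test_that("the subspace matrix is refreshed only at schedule boundaries", {
  # with lambda2 = lambda1 = 0 weights still move every iteration, but C is
  # recomputed only at refreshes: verify via the recon component, which only
  # changes when the network moves -- and C directly via two short runs
  s <- small_sim()
  ctl_a <- small_control(max_iters = 10, refresh_every = 10)
  ctl_b <- small_control(max_iters = 9, refresh_every = 9)
  fa <- stgcl(s$ds, morphology = s$sim$morphology, control = ctl_a)
  # first window in both runs starts from the same refresh at iteration 0,
  # so the first 9 loss entries must coincide even though schedules differ
  fb <- stgcl(s$ds, morphology = s$sim$morphology, control = ctl_b)
  expect_equal(fa$loss_trace$total[1:9], fb$loss_trace$total[1:9])
})

test_that("ablation switches modify the configuration idempotently", {
  ctl <- small_control()
  no_sub <- ablate_control(ctl, "no_subspace")
  expect_equal(no_sub$lambda1, 0)
  expect_equal(ablate_control(no_sub, "no_subspace"), no_sub)
  re <- ablate_control(ctl, "random_edge")
  expect_equal(re$edge_aug, "edge")
  expect_equal(ablate_control(re, "random_edge"), re)
  expect_error(ablate_control(ctl, "bogus"), "arg")

  # a no-subspace fit carries no C and a zero subspace loss
  s <- small_sim()
  fit <- stgcl(s$ds, morphology = s$sim$morphology,
               control = ablate_control(small_control(), "no_subspace"))
  expect_null(fit$C)
  expect_true(all(fit$loss_trace$subspace == 0))
})

test_that("fits without morphology fall back to random edge augmentation", {
  s <- small_sim()
  expect_message(
    fit <- stgcl(s$ds, control = small_control(max_iters = 5, refresh_every = 5)),
    "random edge")
  expect_s3_class(fit, "stgcl")
})

test_that("methods expose the fit's pieces coherently", {
  s <- small_sim()
  fit <- stgcl(s$ds, morphology = s$sim$morphology, control = small_control())
  expect_output(print(fit), "spatial domain model")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.stgcl")
  expect_output(print(sm), "total loss")
  expect_named(coef(fit), c("We", "ae", "Wd", "ad", "Wg", "Ws"))
  expect_equal(dim(fitted(fit)), dim(s$ds$counts))
  expect_equal(residuals(fit), s$ds$counts - fitted(fit),
               ignore_attr = TRUE)
  emb <- predict(fit)
  expect_equal(dim(emb), c(64L, 16L))
  expect_equal(rownames(emb), s$ds$spot_ids)
  cl <- predict(fit, type = "clusters", method = "gmm", k = 2)
  expect_s3_class(cl, "st_clustering")
  expect_length(cl$labels, 64)
  # loss-trace plot draws without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("C and C_star in the result reflect the final embedding", {
  s <- small_sim()
  fit <- stgcl(s$ds, morphology = s$sim$morphology, control = small_control())
  K <- gram_matrix(fit$embedding, "linear")
  C <- solve_self_expression(K, fit$S_hat, 1)
  expect_equal(fit$C, C)
  expect_equal(fit$C_star, topk_filter(C, 5)$C_star)
  expect_equal(colSums(fit$M), rep(5, 64))
})

test_that("non-finite losses abort with an iteration diagnostic", {
  set.seed(71)
  X <- matrix(abs(rnorm(5 * 12)), 5, 12)
  X[2, 3] <- NaN   # poisoned input surfaces as a diagnosed abort
  A <- knn_oracle(matrix(rnorm(24), 12, 2), 3)
  ctl <- stgcl_control(max_iters = 5, refresh_every = 5, hidden_dim = 4,
                       k_spatial = 3, k_expr = 3, top_k = 3, lambda1 = 0)
  expect_error(stgcl:::stgcl_engine(X, A, NULL, "edge", ctl),
               "non-finite loss at iteration 0")
})
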