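test_that("morphology-prior perturbation follows its algebra exhaustively", {
  # all 3-node symmetric binary triples (A, A_I, L): 2^3 edge choices each
  combos <- expand.grid(rep(list(0:1), 9))
  mk <- function(bits) {
    M <- matrix(0, 3, 3)
    M[upper.tri(M)] <- as.numeric(bits)
    M + t(M)
  }
  for (r in seq_len(nrow(combos))) {
    A <- mk(combos[r, 1:3]); AI <- mk(combos[r, 4:6]); L <- mk(combos[r, 7:9])
    out <- edge_perturb_prior(A, AI, L)
    expect_equal(out, edge_perturb_oracle(A, AI, L))
    expect_true(all(out %in% c(0, 1)))
    expect_equal(out, t(out))
    expect_equal(diag(out), rep(0, 3))
    # entries where A and A_I agree never change
    agree <- A == AI
    expect_equal(out[agree], A[agree])
  }
})

test_that("perturbation boundary cases reduce as expected", {
  set.seed(31)
  A <- knn_oracle(matrix(rnorm(20), 10, 2), 2)
  AI <- knn_oracle(matrix(rnorm(20), 10, 2), 2)
  zero <- matrix(0, 10, 10)
  ones <- 1 - diag(10)
  expect_equal(edge_perturb_prior(A, AI, zero), A)
  expect_equal(edge_perturb_prior(A, AI, ones), AI)
  # two-node worked example: flagged edge absent from the prior is dropped
  expect_equal(edge_perturb_prior(rbind(c(0, 1), c(1, 0)), matrix(0, 2, 2),
                                  rbind(c(0, 1), c(1, 0))),
               matrix(0, 2, 2))
})

test_that("sample_perturbation_mask is supported on disagreements only", {
  set.seed(32)
  A <- knn_oracle(matrix(rnorm(24), 12, 2), 2)
  AI <- knn_oracle(matrix(rnorm(24), 12, 2), 3)
  expect_equal(sample_perturbation_mask(12, A, AI, 0, seed = 1)$L,
               matrix(0, 12, 12))
  full <- sample_perturbation_mask(12, A, AI, 1, seed = 1)$L
  expect_equal(full, (A != AI) * 1)
  expect_equal(sample_perturbation_mask(12, A, A, 1, seed = 1)$L,
               matrix(0, 12, 12))
  m <- sample_perturbation_mask(12, A, AI, 0.5, seed = 9)$L
  expect_equal(m, t(m))
  expect_true(all(m[(A == AI)] == 0))
  expect_equal(m, sample_perturbation_mask(12, A, AI, 0.5, seed = 9)$L)
  expect_error(sample_perturbation_mask(12, A, AI, 1.2), "rate")
})

test_that("random_edge_perturb drops and adds edges in balance", {
  set.seed(33)
  A <- knn_oracle(matrix(rnorm(30), 15, 2), 3)
  expect_equal(random_edge_perturb(A, 0, seed = 1), A)
  out <- random_edge_perturb(A, 0.5, seed = 2)
  expect_equal(out, t(out))
  expect_equal(diag(out), rep(0, 15))
  expect_equal(sum(out), sum(A))  # balanced add/drop
  expect_equal(out, random_edge_perturb(A, 0.5, seed = 2))
  # rate 1 on the complete graph removes everything (no holes to refill)
  cg <- 1 - diag(6)
  expect_equal(random_edge_perturb(cg, 1, seed = 3), matrix(0, 6, 6))
})

test_that("attribute_mask zeroes whole gene rows at the requested rate", {
  set.seed(34)
  X <- matrix(rnorm(8 * 5), 8, 5)
  expect_equal(attribute_mask(X, 0, seed = 1), X)
  expect_equal(attribute_mask(X, 1, seed = 1), matrix(0, 8, 5))
  X4 <- matrix(1, 4, 6)
  masked <- attribute_mask(X4, 0.5, seed = 7)
  zero_rows <- rowSums(masked == 0) == 6
  expect_equal(sum(zero_rows), 2L)
  expect_equal(masked, attribute_mask(X4, 0.5, seed = 7))
})

test_that("shuffle_negative permutes spots preserving the profile multiset", {
  set.seed(35)
  X <- matrix(rnorm(6 * 9), 6, 9)
  sh <- shuffle_negative(X, seed = 4)
  expect_equal(sort(colSums(sh)), sort(colSums(X)))
  expect_equal(dim(sh), dim(X))
  expect_equal(sh, shuffle_negative(X, seed = 4))
  expect_false(identical(sh, shuffle_negative(X, seed = 5)))
  expect_equal(shuffle_negative(X[, 1, drop = FALSE], seed = 1),
               X[, 1, drop = FALSE])
})

test_that("tile_and_embed extracts per-spot patch features", {
  # constant image: every spot gets the same feature row
  img <- array(0.5, c(40, 40, 3))
  coords <- cbind(x = c(10, 20, 30), y = c(10, 20, 30))
  f <- tile_and_embed(img, coords, patch_size = 10)
  expect_true(all(abs(sweep(f$X_I, 2, f$X_I[1, ])) < 1e-12))

  # identical coordinates give identical rows
  f2 <- tile_and_embed(img, rbind(c(15, 15), c(15, 15)), patch_size = 10,
                       extractor = "random_projection", seed = 3)
  expect_equal(f2$X_I[1, ], f2$X_I[2, ])

  # two solid-colour halves: pixel_mean recovers the patch mean colours
  img2 <- array(0, c(20, 40, 1))
  img2[, 1:20, 1] <- 0.2
  img2[, 21:40, 1] <- 0.9
  f3 <- tile_and_embed(img2, rbind(c(10, 10), c(30, 10)), patch_size = 6,
                       extractor = "pixel_mean")
  expect_equal(as.numeric(f3$X_I), c(0.2, 0.9))
})

test_that("morphology_knn separates domains when features are one-hot", {
  feats <- rbind(diag(3)[rep(1, 3), ], diag(3)[rep(2, 3), ],
                 diag(3)[rep(3, 3), ])
  dom <- rep(1:3, each = 3)
  A <- morphology_knn(feats, 1)
  for (i in 1:9)
    expect_true(all(dom[A[i, ] == 1] == dom[i]))
  expect_equal(morphology_knn(feats, 8), 1 - diag(9))
  set.seed(36)
  r <- matrix(rnorm(14 * 4), 14, 4)
  expect_equal(morphology_knn(r, 3), knn_oracle(r, 3))
})
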