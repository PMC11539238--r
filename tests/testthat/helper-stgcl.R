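# Shared fixtures and independent oracles used across the suite.

# Small dataset built in code.
tiny_dataset <- function(d = 5, n = 4, seed = 11) {
  set.seed(seed)
  counts <- matrix(rpois(d * n, 5), d, n,
                   dimnames = list(paste0("g", seq_len(d)),
                                   paste0("s", seq_len(n))))
  st_dataset(counts, cbind(x = seq_len(n), y = rep(0, n)))
}

# Exhaustive O(n^2) nearest-neighbour oracle, written independently of
# knn_adjacency: explicit loops, distances from first principles, union
# symmetrization, ties to the lower index.
knn_oracle <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dists <- rep(Inf, n)
    for (j in seq_len(n))
      if (j != i) dists[j] <- sqrt(sum((points[i, ] - points[j, ])^2))
    nb <- order(dists, seq_len(n))[seq_len(k)]
    A[i, nb] <- 1
  }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (A[i, j] == 1) A[j, i] <- 1
  A
}

# Elementwise evaluation of the morphology-prior perturbation rule,
# independent of the vectorized implementation.
edge_perturb_oracle <- function(A, AI, L) {
  n <- nrow(A)
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      a <- A[i, j]; ai <- AI[i, j]; l <- L[i, j]
      out[i, j] <- a * (1 - l * (a - a * ai)) + (1 - a) * (l * (ai - a * ai))
    }
  out
}

# Plain gradient-descent minimizer of the kernel self-expression objective
# 1/2 ||Phi S C - Phi||_F^2 + beta/2 ||C||_F^2 (kernelized), fixed step
# 1/L with L the Lipschitz constant of the gradient.
gd_self_expression <- function(K, S, beta, iters = 20000) {
  n <- nrow(K)
  SK <- t(S) %*% K
  M <- SK %*% S
  L <- norm(M, "2") + beta
  C <- matrix(0, n, n)
  for (i in seq_len(iters)) C <- C - (M %*% C - SK + beta * C) / L
  C
}

selfexpr_objective <- function(C, K, S, beta) {
  SC <- S %*% C
  0.5 * (sum(diag(t(SC) %*% K %*% SC)) - 2 * sum(diag(K %*% SC)) +
           sum(diag(K))) + beta / 2 * sum(C^2)
}

# Central finite differences of a scalar function over a parameter vector.
numeric_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Four training views over a random small graph, for loss/gradient tests.
random_views <- function(n = 10, d = 6, seed = 42) {
  set.seed(seed)
  A <- knn_adjacency(matrix(rnorm(n * 2), n), 3)
  S <- sym_normalize(A)
  X <- matrix(abs(rnorm(d * n)), d, n)
  list(views = list(
    orig = list(X = X, S = S),
    pos1 = list(X = attribute_mask(X, 0.3, seed = 1), S = S),
    pos2 = list(X = X, S = sym_normalize(random_edge_perturb(A, 0.3, seed = 2))),
    neg = list(X = shuffle_negative(X, seed = 3), S = S)),
    X = X, A = A, S = S)
}
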