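# Kernel self-expression on the graph-propagated embedding: closed-form
# ridge solve, top-k filtering to co-domain neighbours, view reconstruction.

#' Gram (kernel) matrix of embedding columns
#'
#' @param H d' x n matrix whose columns are spot embeddings.
#' @param kernel `"linear"` (`K = H'H`) or `"rbf"`
#'   (`K_ij = exp(-gamma ||h_i - h_j||^2)`).
#' @param gamma RBF bandwidth; defaults to the median heuristic
#'   `1 / median(squared pairwise distance)`.
#' @return Symmetric positive semidefinite n x n matrix (RBF diagonal = 1).
#' @export
gram_matrix <- function(H, kernel = c("linear", "rbf"), gamma = NULL) {
  kernel <- match.arg(kernel)
  if (kernel == "linear") return(crossprod(H))
  D2 <- colwise_sqdist(H)
  if (is.null(gamma)) {
    med <- stats::median(D2[upper.tri(D2)])
    gamma <- if (is.na(med) || med == 0) 1 else 1 / med
  }
  exp(-gamma * D2)
}

#' Closed-form kernel self-expression
#'
#' Solves the graph-regularized self-expression problem
#' `min_C 1/2 ||Phi(H) S_hat C - Phi(H)||_F^2 + beta/2 ||C||_F^2`
#' in its kernelized form. The objective is strictly convex and its unique
#' minimizer is `C = (S_hat' K S_hat + beta I)^{-1} S_hat' K`, obtained
#' here by a symmetric positive-definite solve (Cholesky, with a small
#' diagonal jitter retry), never an explicit inverse.
#'
#' @param K n x n Gram matrix from [gram_matrix()].
#' @param S_hat normalized adjacency from [sym_normalize()].
#' @param beta ridge weight, `> 0` (default 1).
#' @return n x n self-expression coefficient matrix.
#' @export
solve_self_expression <- function(K, S_hat, beta = 1) {
  stopifnot(beta > 0)
  check_square_symmetric(K, "K", tol = 1e-6)
  n <- nrow(K)
  if (!identical(dim(S_hat), dim(K)))
    stop("K and S_hat must have the same shape", call. = FALSE)
  SK <- crossprod(S_hat, K)                      # S' K
  Gm <- SK %*% S_hat + diag(beta, n)             # S' K S + beta I
  Gm <- (Gm + t(Gm)) / 2
  R <- tryCatch(chol(Gm),
                error = function(e) chol(Gm + diag(1e-8, n)))
  backsolve(R, forwardsolve(t(R), SK))
}

# Objective value of the kernelized self-expression problem; used by the
# solver tests and exposed for diagnostics.
self_expression_objective <- function(C, K, S_hat, beta) {
  SC <- S_hat %*% C
  0.5 * (sum(diag(crossprod(SC, K %*% SC))) - 2 * sum(K * t(SC)) +
           sum(diag(K))) + beta / 2 * sum(C^2)
}

#' Top-k filtering of the self-expression matrix
#'
#' For each column j, marks the `top_k` largest-magnitude coefficients
#' (ties towards the lower row index) in a binary filter `M` and zeroes the
#' rest, yielding the co-domain neighbour matrix `C* = M * C`. The retained
#' entries of a column are read as that spot's within-domain neighbours.
#' Magnitude ranking is the default because self-expression weights of
#' same-domain spots are informative in either sign; ranking by raw value
#' is available.
#'
#' @param C n x n self-expression matrix.
#' @param top_k neighbours kept per column; `top_k >= n` keeps everything.
#' @param by `"magnitude"` (default) or `"value"` ranking.
#' @return List with `M` (binary filter) and `C_star`.
#' @export
topk_filter <- function(C, top_k, by = c("magnitude", "value")) {
  stopifnot(top_k >= 1)
  by <- match.arg(by)
  n <- nrow(C)
  M <- matrix(0, n, ncol(C))
  k <- min(top_k, n)
  score <- if (by == "magnitude") abs(C) else C
  for (j in seq_len(ncol(C)))
    M[order(score[, j], decreasing = TRUE)[seq_len(k)], j] <- 1
  list(M = M, C_star = M * C)
}

#' Subspace reconstruction of the positive views
#'
#' One-step linearization: each spot's contextual representation is the
#' self-expression combination of the view's embedding columns,
#' `Z1 = H1 C`, `Z2 = H2 C`.
#'
#' @param H1_pos,H2_pos d' x n embeddings of the two positive views.
#' @param C_used n x n coefficient matrix (`C` or the filtered `C*`).
#' @return List with `Z1` and `Z2`.
#' @export
reconstruct_views <- function(H1_pos, H2_pos, C_used) {
  if (ncol(H1_pos) != nrow(C_used) || ncol(H2_pos) != nrow(C_used))
    stop("embeddings and C_used do not conform", call. = FALSE)
  list(Z1 = H1_pos %*% C_used, Z2 = H2_pos %*% C_used)
}

#' Majority label among subspace neighbours
#'
#' Reassigns each spot to the most frequent label among its retained
#' co-domain neighbours (rows i with `C_star[i, j] != 0`). Ties and empty
#' neighbour sets keep the spot's own label. Useful for inspecting how
#' well the self-expression neighbours respect a reference partition.
#'
#' @param C_star filtered coefficient matrix from [topk_filter()] (or the
#'   binary filter `M` itself).
#' @param labels vector of n labels aligned with the spots.
#' @return Vector of n labels.
#' @export
neighbor_majority_label <- function(C_star, labels) {
  n <- ncol(C_star)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  out <- labels
  for (j in seq_len(n)) {
    nb <- which(C_star[, j] != 0)
    if (!length(nb)) next
    tab <- table(labels[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) out[j] <- top
  }
  out
}
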