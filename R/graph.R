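#' k-nearest-neighbour adjacency matrix
#'
#' Builds a binary spot-spot adjacency from Euclidean distances between the
#' rows of `points`: each point selects its `k` nearest neighbours
#' (excluding itself, ties broken towards the lower index) and the directed
#' graph is symmetrized by union, so an edge exists if either endpoint
#' selected the other.
#'
#' @param points numeric n x m matrix, one row per spot.
#' @param k number of neighbours, `1 <= k < n`.
#' @param metric distance metric; only `"euclidean"` is supported.
#' @return n x n binary symmetric matrix with zero diagonal.
#' @export
knn_adjacency <- function(points, k, metric = "euclidean") {
  points <- as.matrix(points)
  n <- nrow(points)
  metric <- match.arg(metric, "euclidean")
  if (k < 1 || k >= n)
    stop(sprintf("'k' must satisfy 1 <= k < n (k=%s, n=%d)", k, n), call. = FALSE)
  D <- as.matrix(stats::dist(points))
  diag(D) <- -Inf                     # self always sorts first, then dropped
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])              # stable: ties go to the lower index
    A[i, ord[2:(k + 1)]] <- 1
  }
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  A
}

#' Blend spatial and expression adjacencies
#'
#' Merges the spatial-neighbour graph `A_S` and the expression-neighbour
#' graph `A_E` into a single weighted adjacency
#' `A = (1 - alpha) * A_S + alpha * A_E`. With binary inputs the blend's
#' entries lie in `{0, alpha, 1 - alpha, 1}`.
#'
#' @param A_spatial,A_expr binary symmetric matrices with zero diagonal.
#' @param alpha balance in `[0, 1]`; 0 keeps only spatial edges, 1 only
#'   expression edges.
#' @param k_spatial,k_expr optional bookkeeping: the neighbour counts used
#'   to build the two graphs.
#' @return An object of class `adjacency_pair` with elements `A_spatial`,
#'   `A_expr`, `A_blend`, `alpha`, `k_spatial`, `k_expr`.
#' @export
blend_adjacency <- function(A_spatial, A_expr, alpha,
                            k_spatial = NA, k_expr = NA) {
  A_spatial <- as.matrix(A_spatial); A_expr <- as.matrix(A_expr)
  if (!identical(dim(A_spatial), dim(A_expr)))
    stop("adjacency matrices must have the same shape", call. = FALSE)
  check_binary_adjacency(A_spatial, "A_spatial")
  check_binary_adjacency(A_expr, "A_expr")
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  structure(list(A_spatial = A_spatial, A_expr = A_expr,
                 A_blend = (1 - alpha) * A_spatial + alpha * A_expr,
                 alpha = alpha, k_spatial = k_spatial, k_expr = k_expr),
            class = "adjacency_pair")
}

#' @method print adjacency_pair
#' @export
print.adjacency_pair <- function(x, ...) {
  cat(sprintf("adjacency_pair: %d spots, alpha = %g (k_S = %s, k_E = %s)\n",
              nrow(x$A_blend), x$alpha, x$k_spatial, x$k_expr))
  cat(sprintf("  edges: spatial %d, expression %d\n",
              sum(x$A_spatial) / 2, sum(x$A_expr) / 2))
  invisible(x)
}

#' Build the blended spot graph for a dataset
#'
#' Constructs the spatial kNN graph from the spot coordinates and the
#' expression kNN graph from the (preprocessed) expression profiles, then
#' blends them with [blend_adjacency()]. An optional PCA reduction of the
#' expression space can be applied before the expression kNN.
#'
#' @param ds a preprocessed [st_dataset].
#' @param k_spatial,k_expr neighbour counts for the two graphs (default 10;
#'   larger tissues warrant larger values, e.g. 50).
#' @param alpha blend weight in `[0, 1]` (default 0.5).
#' @param n_pcs if positive, number of principal components of the
#'   expression matrix used for the expression kNN (default 0 = none).
#' @return An `adjacency_pair`.
#' @export
build_adjacency <- function(ds, k_spatial = 10, k_expr = 10, alpha = 0.5,
                            n_pcs = 0) {
  stopifnot(inherits(ds, "st_dataset"))
  expr <- t(ds$counts)
  if (n_pcs > 0) {
    n_pcs <- min(n_pcs, ncol(expr) - 1, nrow(expr) - 1)
    expr <- stats::prcomp(expr, rank. = n_pcs, center = TRUE)$x
  }
  A_S <- knn_adjacency(ds$coords, k_spatial)
  A_E <- knn_adjacency(expr, k_expr)
  blend_adjacency(A_S, A_E, alpha, k_spatial = k_spatial, k_expr = k_expr)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal degree
#' matrix of `A + I` — the propagation operator of a graph convolutional
#' layer. Isolated nodes reduce to a unit self-loop.
#'
#' @param A non-negative symmetric matrix with zero diagonal.
#' @return Symmetric n x n matrix.
#' @export
sym_normalize <- function(A) {
  A <- as.matrix(A)
  check_square_symmetric(A, "A")
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat * outer(dinv, dinv)
}
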