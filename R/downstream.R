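# Clustering of the learned embedding and partition-agreement scores.

#' Cluster a spot embedding
#'
#' Two classical routes over the learned embedding: model-based Gaussian
#' mixture clustering at fixed K via `mclust` (deterministic hierarchical
#' initialization), or Louvain community detection on a kNN graph of the
#' embedding, with the resolution bisected automatically to reach a target
#' number of communities when `k` is given.
#'
#' @param embedding n x d' matrix, one row per spot.
#' @param method `"gmm"` (mclust) or `"louvain"`.
#' @param k target number of clusters. Required meaningfully for `"gmm"`
#'   (`NULL` lets mclust choose among 1-9 components); optional for
#'   `"louvain"` (`NULL` keeps the resolution given).
#' @param resolution Louvain resolution when no target `k` is given.
#' @param knn neighbours for the Louvain kNN graph (default 15).
#' @param n_pcs for `"gmm"`, number of principal components of the
#'   embedding the mixture is fitted on (default 20, the usual practice for
#'   model-based clustering of learned embeddings; 0 disables the
#'   reduction). Ignored when the embedding is already narrower.
#' @param l2_normalize L2-normalize embedding rows before the Louvain graph
#'   (default TRUE; ignored for gmm).
#' @param ref optional reference labels; when provided, ARI and NMI against
#'   them are attached to the result.
#' @param seed RNG seed for Louvain.
#' @importFrom mclust Mclust mclustBIC
#' @return Object of class `st_clustering`: list with `labels` (integer
#'   vector), `method`, `params` and, if `ref` was given, `scores`
#'   (named vector with `ari`, `nmi`).
#' @export
cluster_embedding <- function(embedding, method = c("gmm", "louvain"),
                              k = NULL, resolution = 1, knn = 15,
                              n_pcs = 20, l2_normalize = TRUE, ref = NULL,
                              seed = 1) {
  method <- match.arg(method)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite", call. = FALSE)
  if (!is.null(k) && k > n) stop("k cannot exceed the number of spots", call. = FALSE)

  if (method == "gmm") {
    E <- embedding
    if (n_pcs > 0 && ncol(E) > n_pcs)
      E <- stats::prcomp(E, rank. = min(n_pcs, n - 1))$x
    fit <- Mclust(E, G = k %||% 1:9, verbose = FALSE)
    if (is.null(fit)) stop("mclust failed to fit a mixture", call. = FALSE)
    labels <- as.integer(fit$classification)
    params <- list(k = k, model = fit$modelName, n_pcs = ncol(E))
  } else {
    E <- embedding
    if (l2_normalize) {
      nrm <- sqrt(rowSums(E^2))
      nrm[nrm == 0] <- 1
      E <- E / nrm
    }
    A <- knn_adjacency(E, min(knn, n - 1))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    run <- function(res) {
      cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = res))
      as.integer(igraph::membership(cl))
    }
    if (is.null(k)) {
      labels <- run(resolution)
      params <- list(resolution = resolution, knn = knn)
    } else {
      lo <- 0.01; hi <- 10
      best <- NULL; best_res <- NA
      for (i in 1:30) {
        mid <- (lo + hi) / 2
        lab <- run(mid)
        nk <- length(unique(lab))
        if (is.null(best) ||
            abs(nk - k) < abs(length(unique(best)) - k)) {
          best <- lab; best_res <- mid
        }
        if (nk == k) break
        if (nk < k) lo <- mid else hi <- mid
      }
      labels <- best
      params <- list(k = k, resolution = best_res, knn = knn)
    }
  }

  out <- structure(list(labels = labels, method = method, params = params),
                   class = "st_clustering")
  if (!is.null(ref)) {
    stopifnot(length(ref) == n)
    out$scores <- c(ari = ari(labels, ref), nmi = nmi(labels, ref))
  }
  out
}

#' @method print st_clustering
#' @export
print.st_clustering <- function(x, ...) {
  cat(sprintf("st_clustering (%s): %d spots in %d clusters\n",
              x$method, length(x$labels), length(unique(x$labels))))
  if (!is.null(x$scores))
    cat(sprintf("  ARI = %.4f, NMI = %.4f\n", x$scores["ari"], x$scores["nmi"]))
  invisible(x)
}

contingency <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop("'pred' and 'ref' must have the same length", call. = FALSE)
  table(factor(pred), factor(ref))
}

#' Adjusted Rand Index
#'
#' Permutation-model chance-corrected agreement between two partitions:
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param pred,ref label vectors of equal length, aligned by spot.
#' @return Numeric scalar.
#' @export
ari <- function(pred, ref) {
  tab <- contingency(pred, ref)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)   # degenerate: both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized Mutual Information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies; 1 for identical partitions (up to relabeling),
#' 0 for independent ones.
#'
#' @inheritParams ari
#' @return Numeric scalar in [0, 1].
#' @export
nmi <- function(pred, ref) {
  tab <- contingency(pred, ref)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi_) + h(pj_)) / 2
  if (denom == 0) return(if (mi == 0) 1 else 0)
  mi / denom
}
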