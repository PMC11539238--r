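#' Training configuration for [stgcl()]
#'
#' Collects every tunable of the model and its alternating optimization
#' schedule. Defaults follow the method's standard settings: Adam at
#' learning rate 0.001 for 500 iterations, with the closed-form subspace
#' solve and the augmentations refreshed every 100 iterations, a
#' single-layer GCN with a 64-dimensional embedding, 10 spatial and 10
#' expression neighbours blended with weight 0.5, and the three losses
#' weighted 1:1:1.
#'
#' @param lr Adam learning rate.
#' @param max_iters number of gradient iterations.
#' @param refresh_every iterations between subspace refreshes (also when
#'   augmentations are resampled); must not exceed `max_iters` unless
#'   `max_iters` is 0.
#' @param lambda1,lambda2 weights of the subspace and reconstruction losses.
#' @param beta ridge weight of the self-expression solve.
#' @param hidden_dim embedding dimension d'.
#' @param n_layers encoder depth (1-3; deeper risks over-smoothing).
#' @param k_spatial,k_expr,alpha blended-graph settings (see
#'   [build_adjacency()]).
#' @param mask_rate fraction of genes zeroed in the node-masked view.
#' @param edge_rate edge perturbation probability.
#' @param top_k neighbours kept per column of the self-expression matrix.
#' @param kernel `"linear"` or `"rbf"` kernel for the Gram matrix.
#' @param edge_aug `"HS_image"` (morphology-prior perturbation; falls back
#'   to `"edge"` when no morphology is available) or `"edge"` (random).
#' @param use_c_star if `TRUE` the filtered `C*` feeds the view
#'   reconstruction instead of `C`.
#' @param seed integer seed controlling initialization and augmentation.
#' @return A list of class `stgcl_control`.
#' @export
stgcl_control <- function(lr = 0.001, max_iters = 500, refresh_every = 100,
                          lambda1 = 1, lambda2 = 1, beta = 1,
                          hidden_dim = 64, n_layers = 1,
                          k_spatial = 10, k_expr = 10, alpha = 0.5,
                          mask_rate = 0.2, edge_rate = 0.2, top_k = 10,
                          kernel = c("linear", "rbf"),
                          edge_aug = c("HS_image", "edge"),
                          use_c_star = FALSE, seed = 1) {
  kernel <- match.arg(kernel)
  edge_aug <- match.arg(edge_aug)
  stopifnot(lr > 0, max_iters >= 0, refresh_every >= 1,
            lambda1 >= 0, lambda2 >= 0, beta > 0, hidden_dim >= 1,
            n_layers >= 1, n_layers <= 3, alpha >= 0, alpha <= 1,
            mask_rate >= 0, mask_rate <= 1, edge_rate >= 0, edge_rate <= 1,
            top_k >= 1)
  if (max_iters > 0 && refresh_every > max_iters)
    stop("'refresh_every' must not exceed 'max_iters'", call. = FALSE)
  structure(list(lr = lr, max_iters = max_iters, refresh_every = refresh_every,
                 lambda1 = lambda1, lambda2 = lambda2, beta = beta,
                 hidden_dim = hidden_dim, n_layers = n_layers,
                 k_spatial = k_spatial, k_expr = k_expr, alpha = alpha,
                 mask_rate = mask_rate, edge_rate = edge_rate, top_k = top_k,
                 kernel = kernel, edge_aug = edge_aug,
                 use_c_star = use_c_star, seed = seed),
            class = "stgcl_control")
}

#' Ablation switches for the training configuration
#'
#' `"no_subspace"` removes the subspace module (`lambda1 = 0`, the
#' closed-form solves are skipped); `"random_edge"` replaces the
#' morphology-prior edge augmentation with the random one. Both switches
#' are idempotent.
#'
#' @param control an [stgcl_control()] list.
#' @param switch one of `"no_subspace"`, `"random_edge"`.
#' @return The modified control list.
#' @export
ablate_control <- function(control, switch = c("no_subspace", "random_edge")) {
  switch <- match.arg(switch)
  if (switch == "no_subspace") control$lambda1 <- 0
  else control$edge_aug <- "edge"
  control
}

#' Fit the graph-contrastive spatial domain model
#'
#' Learns a low-dimensional spot embedding from a preprocessed spatial
#' transcriptomics dataset by alternating gradient training of a GCN
#' encoder/decoder with closed-form kernel self-expression solves. The
#' network is trained on four views of the spot graph — the original, a
#' gene-masked positive, an edge-perturbed positive (guided by histology
#' morphology when available) and a feature-shuffled negative — under the
#' combined local-global contrastive, local-subspace contrastive and
#' reconstruction losses. Cluster the embedding afterwards with
#' [predict.stgcl()] or [cluster_embedding()].
#'
#' @param ds a preprocessed [st_dataset] (see [preprocess_st()]).
#' @param morphology optional per-spot morphology features: a
#'   `morphology_features` object from [tile_and_embed()] or an n x m
#'   matrix. If absent and `ds$image` is set, features are extracted with
#'   the default extractor; otherwise the edge augmentation falls back to
#'   random perturbation.
#' @param control an [stgcl_control()] configuration.
#' @param adjacency optional precomputed `adjacency_pair`; by default built
#'   from the control's `k_spatial`, `k_expr`, `alpha`.
#' @param morphology_k neighbours for the morphology kNN graph (defaults to
#'   `control$k_spatial`).
#' @return An object of class `stgcl` with elements `embedding` (d' x n),
#'   `C`, `C_star`, `M`, `loss_trace` (data frame), `params`, `control`,
#'   `adjacency`, plus the training data needed by the methods.
#' @seealso [predict.stgcl()], [cluster_embedding()], [simulate_spatial_grid()]
#' @export
stgcl <- function(ds, morphology = NULL, control = stgcl_control(),
                  adjacency = NULL, morphology_k = control$k_spatial) {
  stopifnot(inherits(ds, "st_dataset"), inherits(control, "stgcl_control"))
  X <- ds$counts
  n <- ncol(X)
  if (is.null(adjacency))
    adjacency <- build_adjacency(ds, control$k_spatial, control$k_expr,
                                 control$alpha)
  if (is.null(morphology) && !is.null(ds$image))
    morphology <- tile_and_embed(ds$image, ds$coords)
  A_I <- if (!is.null(morphology)) morphology_knn(morphology, morphology_k)
  edge_aug <- control$edge_aug
  if (edge_aug == "HS_image" && is.null(A_I)) {
    message("no morphology available; using random edge augmentation")
    edge_aug <- "edge"
  }

  fit <- stgcl_engine(X, adjacency$A_blend, A_I, edge_aug, control)
  structure(c(fit,
              list(adjacency = adjacency, control = control, X = X,
                   spot_ids = ds$spot_ids, coords = ds$coords,
                   ref_labels = ds$ref_labels, call = match.call())),
            class = "stgcl")
}

# Core alternating-optimization loop on plain matrices.
stgcl_engine <- function(X, A_blend, A_I, edge_aug, control) {
  n <- ncol(X); d <- nrow(X)
  S_hat <- sym_normalize(A_blend)
  A_bin <- 1 * (A_blend > 0)               # augmentation operates on edges
  params <- init_model_params(d, control$hidden_dim, control$n_layers,
                              seed = control$seed)
  state <- adam_init(params)

  refresh <- function(params, window) {
    H0 <- encode(X, S_hat, params)
    C <- NULL; filt <- NULL
    if (control$lambda1 > 0) {
      K <- gram_matrix(H0, control$kernel)
      C <- solve_self_expression(K, S_hat, control$beta)
      filt <- topk_filter(C, control$top_k)
    }
    aug_seed <- control$seed + 7919L * window
    X1 <- attribute_mask(X, control$mask_rate, seed = aug_seed)
    A2 <- if (edge_aug == "HS_image") {
      L <- sample_perturbation_mask(n, A_bin, A_I, control$edge_rate,
                                    seed = aug_seed + 1L)
      edge_perturb_prior(A_bin, A_I, L)
    } else random_edge_perturb(A_bin, control$edge_rate, seed = aug_seed + 1L)
    Xneg <- shuffle_negative(X, seed = aug_seed + 2L)
    list(C = C, filt = filt,
         views = list(orig = list(X = X, S = S_hat),
                      pos1 = list(X = X1, S = S_hat),
                      pos2 = list(X = X, S = sym_normalize(A2)),
                      neg = list(X = Xneg, S = S_hat)))
  }

  trace <- matrix(NA_real_, control$max_iters, 4,
                  dimnames = list(NULL, c("global", "subspace", "recon", "total")))
  st <- NULL
  if (control$max_iters > 0) {
    for (it in seq_len(control$max_iters) - 1L) {
      if (it %% control$refresh_every == 0)
        st <- refresh(params, it %/% control$refresh_every)
      C_used <- if (control$use_c_star && !is.null(st$filt)) st$filt$C_star else st$C
      fb <- forward_backward(params, st$views, C_used,
                             control$lambda1, control$lambda2)
      if (!is.finite(fb$loss))
        stop(sprintf(paste0("non-finite loss at iteration %d ",
                            "(global %.4g, subspace %.4g, recon %.4g)"),
                     it, fb$global, fb$subspace, fb$recon), call. = FALSE)
      trace[it + 1L, ] <- c(fb$global, fb$subspace, fb$recon, fb$loss)
      upd <- adam_step(params, fb$grads, state, lr = control$lr)
      params <- upd$params
      state <- upd$state
    }
  }

  H <- encode(X, S_hat, params)
  C <- NULL; M <- NULL; C_star <- NULL
  if (control$lambda1 > 0) {
    K <- gram_matrix(H, control$kernel)
    C <- solve_self_expression(K, S_hat, control$beta)
    filt <- topk_filter(C, control$top_k)
    M <- filt$M; C_star <- filt$C_star
  }
  list(embedding = H, C = C, C_star = C_star, M = M,
       loss_trace = as.data.frame(cbind(iter = seq_len(control$max_iters),
                                        trace)),
       params = params, S_hat = S_hat)
}

#' @method print stgcl
#' @export
print.stgcl <- function(x, ...) {
  cat("Graph-contrastive spatial domain model\n")
  cat(sprintf("  %d genes x %d spots, embedding dim %d, %d layer(s)\n",
              nrow(x$X), ncol(x$X), x$control$hidden_dim, x$control$n_layers))
  if (nrow(x$loss_trace)) {
    cat(sprintf("  %d iterations; total loss %.4f -> %.4f\n",
                nrow(x$loss_trace), x$loss_trace$total[1],
                x$loss_trace$total[nrow(x$loss_trace)]))
  } else cat("  untrained (max_iters = 0)\n")
  invisible(x)
}

#' @method summary stgcl
#' @export
summary.stgcl <- function(object, ...) {
  tr <- object$loss_trace
  res <- list(
    n_spots = ncol(object$X), n_genes = nrow(object$X),
    hidden_dim = object$control$hidden_dim,
    iterations = nrow(tr),
    loss_initial = if (nrow(tr)) tr$total[1] else NA_real_,
    loss_final = if (nrow(tr)) tr$total[nrow(tr)] else NA_real_,
    components_final = if (nrow(tr)) unlist(tr[nrow(tr), c("global", "subspace", "recon")]),
    subspace_nonzeros = if (!is.null(object$M)) sum(object$M),
    control = object$control)
  class(res) <- "summary.stgcl"
  res
}

#' @method print summary.stgcl
#' @export
print.summary.stgcl <- function(x, ...) {
  cat(sprintf("stgcl fit: %d genes x %d spots -> %d-dim embedding\n",
              x$n_genes, x$n_spots, x$hidden_dim))
  cat(sprintf("  iterations: %d, total loss %.4f -> %.4f\n",
              x$iterations, x$loss_initial, x$loss_final))
  if (!is.null(x$components_final))
    cat(sprintf("  final components: global %.4f, subspace %.4f, recon %.4f\n",
                x$components_final[1], x$components_final[2],
                x$components_final[3]))
  if (!is.null(x$subspace_nonzeros))
    cat(sprintf("  co-domain neighbours retained: %d\n", x$subspace_nonzeros))
  invisible(x)
}

#' Extract model coefficients
#'
#' Returns the trained weights: encoder/decoder layer matrices, PReLU
#' slopes and the two discriminator bilinear forms.
#'
#' @param object an `stgcl` fit.
#' @param ... unused.
#' @export
coef.stgcl <- function(object, ...) {
  object$params[c("We", "ae", "Wd", "ad", "Wg", "Ws")]
}

#' Reconstructed expression matrix
#'
#' @param object an `stgcl` fit.
#' @param ... unused.
#' @return The decoder output `X'` (genes x spots).
#' @export
fitted.stgcl <- function(object, ...) {
  decode(object$embedding, object$S_hat, object$params)
}

#' @method residuals stgcl
#' @export
residuals.stgcl <- function(object, ...) {
  object$X - fitted(object)
}

#' Embedding or cluster labels from a fitted model
#'
#' @param object an `stgcl` fit.
#' @param type `"embedding"` returns the n x d' spot embedding;
#'   `"clusters"` clusters it with [cluster_embedding()].
#' @param method,k passed to [cluster_embedding()] for `type = "clusters"`.
#' @param ... further arguments to [cluster_embedding()].
#' @export
predict.stgcl <- function(object, type = c("embedding", "clusters"),
                          method = c("gmm", "louvain"), k = NULL, ...) {
  type <- match.arg(type)
  emb <- t(object$embedding)
  rownames(emb) <- object$spot_ids
  if (type == "embedding") return(emb)
  cluster_embedding(emb, method = method, k = k, ref = object$ref_labels, ...)
}

#' Plot the training loss trace
#'
#' @param x an `stgcl` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.stgcl <- function(x, ...) {
  tr <- x$loss_trace
  if (!nrow(tr)) {
    warning("no iterations to plot")
    return(invisible(x))
  }
  graphics::matplot(tr$iter, tr[, c("global", "subspace", "recon", "total")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("#4477AA", "#EE6677", "#228833", "black"),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", c("global", "subspace", "recon", "total"),
                   col = c("#4477AA", "#EE6677", "#228833", "black"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
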