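# GCN encoder/decoder, readout, bilinear discriminators, the three loss
# terms, and their analytic gradients. All dense base-R matrix algebra;
# gradients are verified against finite differences in the test suite.

#' Initialize model parameters
#'
#' Creates Glorot-uniform encoder/decoder weights, PReLU slopes (one
#' learnable scalar per layer, initialized at 0.25) and the two bilinear
#' discriminator matrices (one for the local-global loss, one for the
#' local-subspace loss).
#'
#' @param d input dimension (number of genes).
#' @param hidden_dim embedding dimension d' (default 64).
#' @param n_layers number of GCN layers in the encoder (1 to 3; the decoder
#'   mirrors the encoder).
#' @param seed RNG seed for the initialization.
#' @return List with `We`, `ae` (encoder weights/slopes), `Wd`, `ad`
#'   (decoder), `Wg`, `Ws` (discriminator bilinear forms), `dims`.
#' @export
init_model_params <- function(d, hidden_dim = 64, n_layers = 1, seed = 1) {
  stopifnot(n_layers >= 1, n_layers <= 3)
  dims <- c(d, rep(hidden_dim, n_layers))
  glorot <- function(nout, nin) {
    a <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nout * nin, -a, a), nout, nin)
  }
  with_seed(seed, {
    We <- lapply(seq_len(n_layers), function(l) glorot(dims[l + 1], dims[l]))
    Wd <- lapply(seq_len(n_layers), function(l)
      glorot(rev(dims)[l + 1], rev(dims)[l]))
    list(We = We, ae = rep(0.25, n_layers),
         Wd = Wd, ad = rep(0.25, n_layers),
         Wg = glorot(hidden_dim, hidden_dim),
         Ws = glorot(hidden_dim, hidden_dim),
         dims = dims)
  })
}

prelu <- function(x, a) pmax(x, 0) + a * pmin(x, 0)
prelu_grad <- function(pre, a) (pre > 0) + a * (pre <= 0)

# Multi-layer GCN pass with caches for backprop.
# Returns H plus, per layer, the pre-activations and propagated inputs.
gcn_forward <- function(X, S_hat, W, slopes) {
  L <- length(W)
  Z <- X
  pres <- vector("list", L)
  pgs <- vector("list", L)   # Z^{l-1} %*% S_hat, reused for weight grads
  for (l in seq_len(L)) {
    pgs[[l]] <- Z %*% S_hat
    pres[[l]] <- W[[l]] %*% pgs[[l]]
    Z <- prelu(pres[[l]], slopes[l])
  }
  list(H = Z, pres = pres, pgs = pgs)
}

# Backprop dL/dH through a GCN; accumulates into gW (list) and ga (vector).
gcn_backward <- function(G, cache, S_hat, W, slopes) {
  L <- length(W)
  gW <- vector("list", L)
  ga <- numeric(L)
  for (l in rev(seq_len(L))) {
    ga[l] <- sum(G * pmin(cache$pres[[l]], 0))
    dPre <- G * prelu_grad(cache$pres[[l]], slopes[l])
    gW[[l]] <- tcrossprod(dPre, cache$pgs[[l]])
    if (l > 1) G <- crossprod(W[[l]], dPre) %*% S_hat
  }
  list(gW = gW, ga = ga)
}

#' GCN encoder
#'
#' Computes the spot embedding `H = PReLU(W_e X S_hat)` (stacked for
#' multi-layer encoders), where `S_hat` is the symmetrically normalized
#' adjacency with self-loops from [sym_normalize()]. The activation is
#' applied elementwise with a learnable negative slope.
#'
#' @param X d x n gene-by-spot matrix.
#' @param S_hat n x n normalized adjacency.
#' @param params parameter list from [init_model_params()].
#' @return d' x n embedding matrix (columns are spots).
#' @export
encode <- function(X, S_hat, params) {
  if (ncol(X) != nrow(S_hat)) stop("X and S_hat shapes do not conform", call. = FALSE)
  if (ncol(params$We[[1]]) != nrow(X))
    stop("encoder weights do not match nrow(X)", call. = FALSE)
  gcn_forward(X, S_hat, params$We, params$ae)$H
}

#' GCN decoder
#'
#' Mirrors the encoder: `X' = PReLU(W_d H S_hat)`, reconstructing the
#' expression matrix from the embedding.
#'
#' @param H d' x n embedding.
#' @inheritParams encode
#' @return d x n reconstruction.
#' @export
decode <- function(H, S_hat, params) {
  if (ncol(H) != nrow(S_hat)) stop("H and S_hat shapes do not conform", call. = FALSE)
  gcn_forward(H, S_hat, params$Wd, params$ad)$H
}

#' Graph-level readout
#'
#' Collapses a view's embedding into one global summary vector:
#' the sigmoid of the per-dimension mean over spots.
#'
#' @param H_view d' x n embedding of a view.
#' @return d'-vector with entries in (0, 1).
#' @export
readout <- function(H_view) {
  stopifnot(ncol(H_view) >= 1)
  stats::plogis(rowMeans(H_view))
}

#' Bilinear discriminator
#'
#' Scores how well a spot embedding `h` matches a pair of context vectors:
#' `sigmoid((h' W c1 + h' W c2) / 2)`. With the global summaries as context
#' this drives the local-global loss; with per-spot subspace
#' reconstructions it drives the local-subspace loss.
#'
#' @param h d'-vector (one spot's embedding).
#' @param c1,c2 d'-context vectors.
#' @param W d' x d' bilinear weight matrix.
#' @return Probability in (0, 1).
#' @export
discriminate <- function(h, c1, c2, W) {
  stats::plogis(as.numeric(crossprod(h, W %*% (c1 + c2)) / 2))
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Local-global contrastive loss
#'
#' Binary cross-entropy of the bilinear discriminator: spots of the
#' original view scored against the two augmented views' global summaries
#' should look positive, spots of the shuffled (corrupted) view negative:
#' `-(1/2n) [ sum_i log D(h_i, s1, s2) + sum_j log(1 - D(h~_j, s1, s2)) ]`.
#'
#' @param H,H_neg d' x n embeddings of the original and corrupted views.
#' @param s1,s2 global summaries of the two positive views ([readout()]).
#' @param W d' x d' discriminator weights.
#' @param eps probability clamp keeping the logs finite.
#' @return Non-negative scalar.
#' @export
loss_local_global <- function(H, H_neg, s1, s2, W, eps = 1e-7) {
  n <- ncol(H)
  stopifnot(ncol(H_neg) == n)
  Wc <- W %*% ((s1 + s2) / 2)
  p <- clamp_prob(stats::plogis(as.numeric(crossprod(H, Wc))), eps)
  q <- clamp_prob(stats::plogis(as.numeric(crossprod(H_neg, Wc))), eps)
  -(sum(log(p)) + sum(log(1 - q))) / (2 * n)
}

#' Local-subspace contrastive loss
#'
#' As [loss_local_global()], but each spot is scored against its own
#' contextual vectors: the columns of the subspace-reconstructed views
#' `Z1 = H1 C`, `Z2 = H2 C` ([reconstruct_views()]).
#'
#' @inheritParams loss_local_global
#' @param Z1,Z2 d' x n reconstructed views.
#' @return Non-negative scalar.
#' @export
loss_subspace <- function(H, H_neg, Z1, Z2, W, eps = 1e-7) {
  n <- ncol(H)
  stopifnot(ncol(H_neg) == n, ncol(Z1) == n, ncol(Z2) == n)
  WZ <- W %*% ((Z1 + Z2) / 2)
  p <- clamp_prob(stats::plogis(colSums(H * WZ)), eps)
  q <- clamp_prob(stats::plogis(colSums(H_neg * WZ)), eps)
  -(sum(log(p)) + sum(log(1 - q))) / (2 * n)
}

#' Reconstruction loss
#'
#' Mean squared Frobenius error per spot: `(1/n) ||X - X'||_F^2`.
#'
#' @param X,X_prime d x n matrices.
#' @return Non-negative scalar, zero iff `X == X_prime`.
#' @export
loss_recon <- function(X, X_prime) {
  if (!identical(dim(X), dim(X_prime)))
    stop("X and X_prime must have the same shape", call. = FALSE)
  sum((X - X_prime)^2) / ncol(X)
}

#' Total training objective
#'
#' `L_total = L_global + lambda1 * L_subspace + lambda2 * L_recon`.
#' Setting `lambda1 = 0` ablates the subspace module, `lambda2 = 0` the
#' decoder.
#'
#' @param l_global,l_sub,l_recon the three loss components.
#' @param lambda1,lambda2 non-negative trade-off weights (default 1, the
#'   1:1:1 ratio).
#' @return Scalar.
#' @export
total_loss <- function(l_global, l_sub, l_recon, lambda1 = 1, lambda2 = 1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  l_global + lambda1 * l_sub + lambda2 * l_recon
}

# ---------------------------------------------------------------------------
# Full forward + analytic backward pass for one training iteration.
#
# views: list with elements orig, pos1, pos2, neg; each a list(X, S) where S
# is the view's normalized adjacency. C_used: n x n self-expression matrix
# (fixed; no gradient flows through it), or NULL when lambda1 == 0.
# Returns loss components and gradients in the same structure as params.
forward_backward <- function(params, views, C_used, lambda1 = 1, lambda2 = 1,
                             eps = 1e-7, grad = TRUE) {
  n <- ncol(views$orig$X)
  fw <- lapply(views, function(v) gcn_forward(v$X, v$S, params$We, params$ae))
  H <- fw$orig$H; Hn <- fw$neg$H; H1 <- fw$pos1$H; H2 <- fw$pos2$H

  # readout summaries of the positive views
  m1 <- rowMeans(H1); m2 <- rowMeans(H2)
  s1 <- stats::plogis(m1); s2 <- stats::plogis(m2)

  # local-global term
  sbar <- (s1 + s2) / 2
  Wgs <- params$Wg %*% sbar
  u <- as.numeric(crossprod(H, Wgs))
  v <- as.numeric(crossprod(Hn, Wgs))
  pu <- stats::plogis(u); pv <- stats::plogis(v)
  l_global <- -(sum(log(clamp_prob(pu, eps))) +
                  sum(log1p(-clamp_prob(pv, eps)))) / (2 * n)

  # local-subspace term
  if (lambda1 > 0) {
    Z1 <- H1 %*% C_used; Z2 <- H2 %*% C_used
    Zbar <- (Z1 + Z2) / 2
    WsZ <- params$Ws %*% Zbar
    us <- colSums(H * WsZ)
    vs <- colSums(Hn * WsZ)
    ps <- stats::plogis(us); qs <- stats::plogis(vs)
    l_sub <- -(sum(log(clamp_prob(ps, eps))) +
                 sum(log1p(-clamp_prob(qs, eps)))) / (2 * n)
  } else l_sub <- 0

  # reconstruction term (decoder on the original view)
  dec <- gcn_forward(H, views$orig$S, params$Wd, params$ad)
  Xp <- dec$H
  l_recon <- sum((views$orig$X - Xp)^2) / n

  out <- list(loss = l_global + lambda1 * l_sub + lambda2 * l_recon,
              global = l_global, subspace = l_sub, recon = l_recon)
  if (!grad) return(out)

  dH <- matrix(0, nrow(H), n); dHn <- matrix(0, nrow(H), n)
  dH1 <- matrix(0, nrow(H), n); dH2 <- matrix(0, nrow(H), n)

  # -- global loss gradients
  gpos <- -(1 - pu) / (2 * n)
  gneg <- pv / (2 * n)
  hsum <- H %*% gpos + Hn %*% gneg
  gWg <- tcrossprod(hsum, sbar)
  dH <- dH + tcrossprod(Wgs, gpos)
  dHn <- dHn + tcrossprod(Wgs, gneg)
  dsbar <- crossprod(params$Wg, hsum)
  dm1 <- as.numeric(dsbar) / 2 * s1 * (1 - s1)
  dm2 <- as.numeric(dsbar) / 2 * s2 * (1 - s2)
  dH1 <- dH1 + matrix(dm1 / n, nrow(H), n)
  dH2 <- dH2 + matrix(dm2 / n, nrow(H), n)

  # -- subspace loss gradients (scaled by lambda1)
  if (lambda1 > 0) {
    gs <- lambda1 * (-(1 - ps) / (2 * n))
    gq <- lambda1 * (qs / (2 * n))
    Hg <- sweep(H, 2, gs, "*") + sweep(Hn, 2, gq, "*")
    gWs <- tcrossprod(Hg, Zbar)
    dH <- dH + sweep(WsZ, 2, gs, "*")
    dHn <- dHn + sweep(WsZ, 2, gq, "*")
    dZbar <- crossprod(params$Ws, Hg)
    dZ <- (dZbar / 2) %*% t(C_used)
    dH1 <- dH1 + dZ
    dH2 <- dH2 + dZ
  } else gWs <- matrix(0, nrow(params$Ws), ncol(params$Ws))

  # -- reconstruction gradients through the decoder
  dXp <- lambda2 * 2 / n * (Xp - views$orig$X)
  bd <- gcn_backward(dXp, dec, views$orig$S, params$Wd, params$ad)
  # propagate into H through the decoder stack
  G <- dXp
  for (l in rev(seq_along(params$Wd))) {
    dPre <- G * prelu_grad(dec$pres[[l]], params$ad[l])
    G <- crossprod(params$Wd[[l]], dPre) %*% views$orig$S
  }
  dH <- dH + G

  # -- encoder gradients from all four views
  gWe <- lapply(params$We, function(w) matrix(0, nrow(w), ncol(w)))
  gae <- numeric(length(params$ae))
  dviews <- list(orig = dH, pos1 = dH1, pos2 = dH2, neg = dHn)
  for (nm in names(dviews)) {
    bk <- gcn_backward(dviews[[nm]], fw[[nm]], views[[nm]]$S,
                       params$We, params$ae)
    for (l in seq_along(gWe)) gWe[[l]] <- gWe[[l]] + bk$gW[[l]]
    gae <- gae + bk$ga
  }

  out$grads <- list(We = gWe, ae = gae, Wd = bd$gW, ad = bd$ga,
                    Wg = gWg, Ws = gWs)
  out
}

# ---------------------------------------------------------------------------
# Adam on the nested parameter list (dims entry excluded).

trainable_names <- c("We", "ae", "Wd", "ad", "Wg", "Ws")

flatten_params <- function(p)
  unlist(lapply(trainable_names, function(nm) unlist(p[[nm]], use.names = FALSE)),
         use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 1L
  take <- function(x) {
    k <- length(x)
    out <- vec[pos:(pos + k - 1L)]
    pos <<- pos + k
    if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
  }
  for (nm in trainable_names) {
    if (is.list(skeleton[[nm]])) {
      skeleton[[nm]] <- lapply(skeleton[[nm]], take)
    } else skeleton[[nm]] <- take(skeleton[[nm]])
  }
  skeleton
}

adam_init <- function(params) {
  k <- length(flatten_params(params))
  list(m = numeric(k), v = numeric(k), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  g <- flatten_params(grads)
  p <- flatten_params(params)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(params = unflatten_params(p, params), state = state)
}
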