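# Graph augmentation: positive views by gene masking and (morphology-prior
# or random) edge perturbation, negative view by feature shuffling.

#' Extract per-spot morphology features from a histology image
#'
#' Crops a square patch centred on every spot, optionally resizes it, and
#' maps it to a feature vector with the chosen extractor. Patches reaching
#' beyond the image border are zero-padded.
#'
#' @param image 2D (grayscale) or 3D (height x width x channels) numeric
#'   array; rows index y, columns x.
#' @param coords n x 2 matrix of spot pixel coordinates (x, y).
#' @param patch_size side length of the cropped patch in pixels (default 50).
#' @param resize_to side length patches are resized to before a custom
#'   extractor is applied (default 224, the usual CNN input size). The
#'   built-in extractors are resize-invariant.
#' @param extractor either a function mapping a `resize_to x resize_to x
#'   channels` array to a numeric vector (e.g. a pretrained CNN wrapper), or
#'   one of `"pixel_mean"` (per-channel mean intensity) and
#'   `"random_projection"` (seeded Gaussian projection of the raw patch to
#'   `proj_dim` dimensions). Both built-ins run fully offline.
#' @param proj_dim output dimension of the `"random_projection"` extractor.
#' @param seed seed for the random projection matrix.
#' @return Object of class `morphology_features`: list with `X_I` (n x m
#'   feature matrix) and `extractor_id`.
#' @export
tile_and_embed <- function(image, coords, patch_size = 50, resize_to = 224,
                           extractor = "pixel_mean", proj_dim = 64, seed = 1) {
  if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1L)
  stopifnot(length(dim(image)) == 3)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  nch <- dim(image)[3]
  half <- floor(patch_size / 2)

  crop <- function(cx, cy) {
    patch <- array(0, c(patch_size, patch_size, nch))
    rows <- (round(cy) - half):(round(cy) - half + patch_size - 1)
    cols <- (round(cx) - half):(round(cx) - half + patch_size - 1)
    rok <- rows >= 1 & rows <= dim(image)[1]
    cok <- cols >= 1 & cols <= dim(image)[2]
    if (!any(rok) || !any(cok))
      stop("spot patch lies entirely outside the image", call. = FALSE)
    patch[which(rok), which(cok), ] <- image[rows[rok], cols[cok], , drop = FALSE]
    patch
  }

  if (is.function(extractor)) {
    extract <- function(p) extractor(resize_nn(p, resize_to))
    extractor_id <- "custom"
  } else {
    extractor_id <- match.arg(extractor, c("pixel_mean", "random_projection"))
    if (extractor_id == "pixel_mean") {
      extract <- function(p) apply(p, 3, mean)
    } else {
      P <- with_seed(seed, matrix(stats::rnorm(proj_dim * patch_size^2 * nch),
                                  nrow = proj_dim) / sqrt(patch_size^2 * nch))
      extract <- function(p) as.numeric(P %*% as.numeric(p))
    }
  }

  feats <- t(vapply(seq_len(n),
                    function(i) extract(crop(coords[i, 1], coords[i, 2])),
                    numeric(length(extract(crop(coords[1, 1], coords[1, 2]))))))
  if (any(!is.finite(feats))) stop("non-finite morphology features", call. = FALSE)
  structure(list(X_I = feats, extractor_id = extractor_id),
            class = "morphology_features")
}

# Nearest-neighbour resize of an h x w x c array to size x size x c.
resize_nn <- function(patch, size) {
  d <- dim(patch)
  if (d[1] == size && d[2] == size) return(patch)
  ri <- pmin(pmax(round(seq(1, d[1], length.out = size)), 1), d[1])
  ci <- pmin(pmax(round(seq(1, d[2], length.out = size)), 1), d[2])
  patch[ri, ci, , drop = FALSE]
}

#' Morphology k-nearest-neighbour graph
#'
#' Builds the binary kNN graph over per-spot morphology feature rows; this
#' graph is the prior guiding [edge_perturb_prior()].
#'
#' @param feats a `morphology_features` object from [tile_and_embed()], or a
#'   plain n x m feature matrix.
#' @param k number of neighbours.
#' @return n x n binary symmetric matrix with zero diagonal.
#' @export
morphology_knn <- function(feats, k) {
  X <- if (inherits(feats, "morphology_features")) feats$X_I else as.matrix(feats)
  knn_adjacency(X, k)
}

#' Sample the random perturbation location matrix
#'
#' Flags spot pairs whose edge status may be flipped by the morphology-prior
#' perturbation. Only pairs where the expression/spatial graph `A_bin` and
#' the morphology graph `A_I` disagree can have any effect, so the mask is
#' supported on those pairs: each disagreeing pair (i < j) is flagged
#' independently with probability `rate`, symmetrically.
#'
#' @param n number of spots.
#' @param A_bin,A_I n x n binary symmetric adjacencies.
#' @param rate flag probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Object of class `perturbation_mask`: list with `L` (binary
#'   symmetric, zero diagonal), `rate`, `seed`.
#' @export
sample_perturbation_mask <- function(n, A_bin, A_I, rate, seed = 1) {
  check_binary_adjacency(A_bin, "A_bin")
  check_binary_adjacency(A_I, "A_I")
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]", call. = FALSE)
  disagree <- (A_bin != A_I) * 1
  L <- matrix(0, n, n)
  up <- which(upper.tri(disagree) & disagree == 1)
  if (length(up)) {
    flag <- with_seed(seed, stats::runif(length(up)) < rate)
    L[up[flag]] <- 1
    L <- L + t(L)
  }
  structure(list(L = L, rate = rate, seed = seed), class = "perturbation_mask")
}

#' Morphology-prior edge perturbation
#'
#' Perturbs the adjacency `A` towards the morphology graph `A_I` at the
#' locations flagged in `L`:
#' `tau_A(A) = A (1 - L (A - A A_I)) + (1 - A) (L (A_I - A A_I))`
#' (all products elementwise). The first term drops flagged edges absent
#' from the morphology graph; the second adds flagged morphology edges
#' absent from `A`. At `L = 0` the graph is unchanged; at `L = 1` it
#' becomes `A_I`.
#'
#' @param A_bin n x n binary symmetric adjacency (zero diagonal).
#' @param A_I morphology kNN graph, same shape.
#' @param L a `perturbation_mask` or a binary symmetric matrix.
#' @return Perturbed binary symmetric adjacency.
#' @export
edge_perturb_prior <- function(A_bin, A_I, L) {
  if (inherits(L, "perturbation_mask")) L <- L$L
  A_bin <- as.matrix(A_bin); A_I <- as.matrix(A_I); L <- as.matrix(L)
  if (!identical(dim(A_bin), dim(A_I)) || !identical(dim(A_bin), dim(L)))
    stop("A_bin, A_I and L must have the same shape", call. = FALSE)
  check_binary_adjacency(A_bin, "A_bin")
  check_binary_adjacency(A_I, "A_I")
  A_bin * (1 - L * (A_bin - A_bin * A_I)) +
    (1 - A_bin) * (L * (A_I - A_bin * A_I))
}

#' Random edge perturbation
#'
#' Prior-free fallback augmentation for datasets without a histology image:
#' each existing edge is dropped with probability `rate`, and the same
#' number of new edges is added uniformly at random among non-adjacent
#' pairs.
#'
#' @param A_bin n x n binary symmetric adjacency (zero diagonal).
#' @param rate drop probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Perturbed binary symmetric adjacency.
#' @export
random_edge_perturb <- function(A_bin, rate, seed = 1) {
  check_binary_adjacency(A_bin, "A_bin")
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]", call. = FALSE)
  n <- nrow(A_bin)
  up <- upper.tri(A_bin)
  edges <- which(up & A_bin == 1)
  holes <- which(up & A_bin == 0)
  with_seed(seed, {
    drop <- edges[stats::runif(length(edges)) < rate]
    add <- if (length(drop) && length(holes))
      sample(holes, min(length(drop), length(holes))) else integer()
    out <- A_bin
    out[drop] <- 0
    out[add] <- 1
    out[lower.tri(out)] <- 0
    out + t(out)
  })
}

#' Gene (attribute) masking
#'
#' Node-attribute augmentation: a uniformly sampled fraction `mask_rate` of
#' gene rows is zeroed across all spots.
#'
#' @param X gene-by-spot matrix.
#' @param mask_rate fraction of genes to zero, in `[0, 1]`.
#' @param seed RNG seed.
#' @return Matrix of the same shape with `round(mask_rate * d)` zeroed rows.
#' @export
attribute_mask <- function(X, mask_rate, seed = 1) {
  if (mask_rate < 0 || mask_rate > 1)
    stop("'mask_rate' must be in [0, 1]", call. = FALSE)
  d <- nrow(X)
  n_mask <- round(mask_rate * d)
  if (n_mask == 0) return(X)
  idx <- with_seed(seed, sample.int(d, n_mask))
  X[idx, ] <- 0
  X
}

#' Corrupted (negative) view by feature shuffling
#'
#' Permutes the spot columns of `X` uniformly at random, detaching every
#' expression profile from its graph position while preserving the multiset
#' of profiles. The negative view keeps the original adjacency.
#'
#' @param X gene-by-spot matrix.
#' @param seed RNG seed.
#' @return Column-permuted matrix.
#' @export
shuffle_negative <- function(X, seed = 1) {
  n <- ncol(X)
  if (n < 2) return(X)
  X[, with_seed(seed, sample.int(n)), drop = FALSE]
}
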