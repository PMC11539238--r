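# Synthetic data generators: a gridded tissue with contiguous expression
# domains (plus optional domain-correlated morphology), and
# union-of-linear-subspaces point sets for the self-expression solver.

#' Simulate a gridded spatial transcriptomics dataset
#'
#' Places spots on an integer grid partitioned into `n_domains` contiguous
#' domains (horizontal bands or rectangular blocks). Counts follow a
#' log-normal-like model: Gaussian in log space around a shared baseline,
#' with each domain's marker genes shifted upward by `effect_size`, then
#' exponentiated and rounded — so library-size normalization and the log
#' transform are exercised realistically. Morphology features are emitted
#' directly as `one_hot(domain) * effect_size` plus Gaussian noise,
#' standing in for image-patch embeddings.
#'
#' @param rows,cols grid dimensions (`n = rows * cols` spots).
#' @param n_domains number of domains K.
#' @param layout `"bands"` (K horizontal bands of rows, equal up to
#'   remainder) or `"blocks"` (rectangular tiles).
#' @param n_genes total number of genes.
#' @param markers_per_domain genes upregulated in each domain.
#' @param effect_size log-space mean shift of marker genes (default
#'   3 * `noise_sd`); 0 gives a null model with no domain signal.
#' @param noise_sd log-space Gaussian noise standard deviation.
#' @param baseline_log_mean shared log-space baseline expression.
#' @param morphology_dim dimension m of the morphology features (>= K).
#' @param morphology_noise_sd noise on the morphology features.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return List with `dataset` (an [st_dataset] whose `ref_labels` are the
#'   planted domains), `labels` (integer vector), and `morphology`
#'   (n x m matrix).
#' @export
simulate_spatial_grid <- function(rows = 20, cols = 30, n_domains = 3,
                                  layout = c("bands", "blocks"),
                                  n_genes = 50, markers_per_domain = 5,
                                  noise_sd = 0.5,
                                  effect_size = 3 * noise_sd,
                                  baseline_log_mean = 2,
                                  morphology_dim = 8,
                                  morphology_noise_sd = 0.1, seed = 1) {
  layout <- match.arg(layout)
  n <- rows * cols
  stopifnot(n_domains <= n, effect_size >= 0, noise_sd >= 0,
            morphology_dim >= n_domains,
            markers_per_domain * n_domains <= n_genes)
  if (layout == "bands" && n_domains > rows)
    stop("bands layout requires n_domains <= rows", call. = FALSE)

  coords <- cbind(x = rep(seq_len(cols), each = rows),
                  y = rep(seq_len(rows), times = cols))
  if (layout == "bands") {
    band_of_row <- rep(seq_len(n_domains), each = ceiling(rows / n_domains),
                       length.out = rows)
    labels <- band_of_row[coords[, "y"]]
  } else {
    tr <- ceiling(sqrt(n_domains))
    tc <- ceiling(n_domains / tr)
    ri <- pmin(ceiling(coords[, "y"] / (rows / tr)), tr)
    ci <- pmin(ceiling(coords[, "x"] / (cols / tc)), tc)
    labels <- pmin((ri - 1) * tc + ci, n_domains)
  }

  marker_of <- function(k)
    ((k - 1) * markers_per_domain + 1):(k * markers_per_domain)
  with_seed(seed, {
    logmu <- matrix(baseline_log_mean, n_genes, n)
    for (k in seq_len(n_domains))
      logmu[marker_of(k), labels == k] <- baseline_log_mean + effect_size
    counts <- round(exp(logmu + matrix(stats::rnorm(n_genes * n, sd = noise_sd),
                                       n_genes, n)))
    morph <- matrix(stats::rnorm(n * morphology_dim, sd = morphology_noise_sd),
                    n, morphology_dim)
    for (k in seq_len(n_domains))
      morph[labels == k, k] <- morph[labels == k, k] + effect_size
    ds <- st_dataset(counts, coords,
                     gene_ids = sprintf("gene_%03d", seq_len(n_genes)),
                     spot_ids = sprintf("spot_%04d", seq_len(n)),
                     ref_labels = labels)
    list(dataset = ds, labels = labels, morphology = morph)
  })
}

#' Simulate a union of linear subspaces
#'
#' Samples `n_per` points from each of `n_subspaces` random
#' `subspace_dim`-dimensional linear subspaces of the ambient space
#' (orthonormal basis times Gaussian coefficients), plus isotropic ambient
#' noise. The self-expression model assumes exactly this structure, so
#' these sets probe whether its coefficients concentrate on same-subspace
#' points.
#'
#' @param n_per points per subspace.
#' @param subspace_dim intrinsic dimension (< `ambient_dim`).
#' @param ambient_dim ambient dimension.
#' @param n_subspaces number of subspaces.
#' @param noise_sd ambient Gaussian noise level.
#' @param orthogonal if `TRUE`, carve the subspace bases out of one common
#'   orthonormal frame so distinct subspaces are mutually orthogonal
#'   (requires `n_subspaces * subspace_dim <= ambient_dim`).
#' @param seed RNG seed.
#' @return List with `points` (`ambient_dim` x `n_per * n_subspaces`
#'   matrix, points in columns) and `labels` (integer vector of subspace
#'   memberships).
#' @export
simulate_union_subspaces <- function(n_per = 20, subspace_dim = 3,
                                     ambient_dim = 20, n_subspaces = 3,
                                     noise_sd = 0.01, orthogonal = FALSE,
                                     seed = 1) {
  stopifnot(subspace_dim < ambient_dim)
  if (orthogonal && n_subspaces * subspace_dim > ambient_dim)
    stop("orthogonal subspaces need n_subspaces * subspace_dim <= ambient_dim",
         call. = FALSE)
  with_seed(seed, {
    frame <- if (orthogonal)
      qr.Q(qr(matrix(stats::rnorm(ambient_dim^2), ambient_dim)))
    pts <- lapply(seq_len(n_subspaces), function(k) {
      U <- if (orthogonal)
        frame[, ((k - 1) * subspace_dim + 1):(k * subspace_dim), drop = FALSE]
      else
        qr.Q(qr(matrix(stats::rnorm(ambient_dim * subspace_dim), ambient_dim)))
      U %*% matrix(stats::rnorm(subspace_dim * n_per), subspace_dim) +
        matrix(stats::rnorm(ambient_dim * n_per, sd = noise_sd), ambient_dim)
    })
    list(points = do.call(cbind, pts),
         labels = rep(seq_len(n_subspaces), each = n_per))
  })
}
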