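#' Remove genes by name pattern and spots by reference label
#'
#' Drops genes whose identifier matches any of the supplied patterns and
#' spots whose reference label is in `exclude_labels`. This mirrors the
#' usual in-situ panel cleanup: control probes (e.g. `Blank-*`), genes
#' recorded with non-numeric values (e.g. `Fos`), and cells annotated
#' `Ambiguous`.
#'
#' @param ds an [st_dataset].
#' @param gene_patterns character vector of rules: a pattern ending in `*`
#'   is a prefix match (`"Blank*"`), otherwise an exact match (`"Fos"`).
#' @param exclude_labels character vector of reference labels whose spots
#'   are removed (requires `ds$ref_labels`).
#' @return The filtered [st_dataset]; gene and spot order is preserved.
#' @examples
#' counts <- matrix(1, 3, 2, dimnames = list(c("Blank-1", "Fos", "Actb"), NULL))
#' ds <- st_dataset(counts, cbind(0:1, 0:1))
#' filter_features(ds, gene_patterns = c("Blank*", "Fos"))$gene_ids
#' @export
filter_features <- function(ds, gene_patterns = character(),
                            exclude_labels = character()) {
  stopifnot(inherits(ds, "st_dataset"))
  keep_genes <- rep(TRUE, length(ds$gene_ids))
  for (pat in gene_patterns) {
    if (endsWith(pat, "*")) {
      keep_genes <- keep_genes & !startsWith(ds$gene_ids, substr(pat, 1, nchar(pat) - 1))
    } else {
      keep_genes <- keep_genes & ds$gene_ids != pat
    }
  }
  if (!any(keep_genes))
    stop("all genes removed by 'gene_patterns'", call. = FALSE)
  keep_spots <- rep(TRUE, length(ds$spot_ids))
  if (length(exclude_labels)) {
    if (is.null(ds$ref_labels))
      stop("'exclude_labels' given but the dataset has no reference labels",
           call. = FALSE)
    keep_spots <- !(ds$ref_labels %in% exclude_labels)
    if (!any(keep_spots)) stop("all spots removed by 'exclude_labels'", call. = FALSE)
  }
  subset_st(ds, which(keep_genes), which(keep_spots))
}

#' Select highly variable genes
#'
#' Ranks genes by a binned normalized dispersion computed on the raw counts
#' (per-gene dispersion `var/mean`, z-scored within 20 bins of similar mean
#' expression) and keeps the `n_top` highest-ranked genes. Datasets with at
#' most `n_top` genes — targeted in-situ panels — are returned unchanged.
#'
#' @param ds an [st_dataset] with raw counts.
#' @param n_top number of genes to keep (default 3000).
#' @return The [st_dataset] restricted to the selected genes (original gene
#'   order preserved), with attribute `hvg_method = "binned_dispersion"`.
#' @export
select_hvg <- function(ds, n_top = 3000) {
  stopifnot(inherits(ds, "st_dataset"), n_top >= 1)
  d <- nrow(ds$counts)
  if (d <= n_top) {
    attr(ds, "hvg_method") <- "none (gene count <= n_top)"
    return(ds)
  }
  z <- hvg_dispersion(ds$counts)
  keep <- sort(order(-z)[seq_len(n_top)])
  out <- subset_st(ds, genes = keep)
  attr(out, "hvg_method") <- "binned_dispersion"
  out
}

# Normalized dispersion: var/mean per gene, z-scored within 20 quantile
# bins of the gene means. Ties and degenerate bins score 0.
hvg_dispersion <- function(counts, n_bins = 20) {
  mu <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(breaks) > 2)
    cut(mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(mu))
  z <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- bin == b
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  z
}

#' Library-size normalization and log transform
#'
#' Scales every spot (column) to a common total `target_sum`, then applies
#' `log(1 + x)`. Spots with zero total counts cannot be scaled; they are
#' dropped with a warning.
#'
#' @param ds an [st_dataset].
#' @param target_sum the post-scaling column total (default `1e4`).
#' @return The transformed [st_dataset] (non-negative entries).
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "st_dataset"), target_sum > 0)
  tot <- colSums(ds$counts)
  if (any(tot == 0)) {
    warning(sprintf("dropping %d spot(s) with zero total counts", sum(tot == 0)))
    ds <- subset_st(ds, spots = which(tot > 0))
    tot <- tot[tot > 0]
    if (ncol(ds$counts) == 0) stop("no spots left after dropping zero columns",
                                   call. = FALSE)
  }
  x <- sweep(ds$counts, 2, tot / target_sum, "/")
  ds$counts <- log1p(x)
  ds
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper chaining [filter_features()], [select_hvg()] and
#' [normalize_log()], the usual preparation before fitting [stgcl()].
#'
#' @inheritParams filter_features
#' @inheritParams select_hvg
#' @inheritParams normalize_log
#' @return The preprocessed [st_dataset].
#' @export
preprocess_st <- function(ds, gene_patterns = character(),
                          exclude_labels = character(), n_top = 3000,
                          target_sum = 1e4) {
  ds <- filter_features(ds, gene_patterns, exclude_labels)
  ds <- select_hvg(ds, n_top = n_top)
  normalize_log(ds, target_sum = target_sum)
}
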