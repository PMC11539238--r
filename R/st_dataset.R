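#' Construct a spatial transcriptomics dataset
#'
#' Bundles a gene-by-spot count matrix with spot coordinates and, optionally,
#' a histology image and reference domain labels. All downstream functions in
#' the package operate on this container.
#'
#' @param counts numeric gene-by-spot matrix (genes in rows, spots in
#'   columns); entries must be non-negative. Sparse `Matrix` classes are
#'   accepted and densified.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y), in pixel or array units.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   `colnames(counts)`.
#' @param image optional 2D (grayscale) or 3D (height x width x channels)
#'   numeric pixel array covering the spot coordinates.
#' @param ref_labels optional vector of reference domain labels, one per
#'   spot, used only for evaluation.
#'
#' @return An object of class `st_dataset`: a list with elements `counts`,
#'   `coords`, `gene_ids`, `spot_ids`, `image`, `ref_labels`.
#' @examples
#' counts <- matrix(rpois(20, 5), nrow = 5,
#'                  dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' coords <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' ds <- st_dataset(counts, coords)
#' ds
#' @export
st_dataset <- function(counts, coords, gene_ids = rownames(counts),
                       spot_ids = colnames(counts), image = NULL,
                       ref_labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("'counts' must be non-negative", call. = FALSE)
  d <- nrow(counts); n <- ncol(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  gene_ids <- as.character(gene_ids); spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != d) stop("'gene_ids' length must equal nrow(counts)", call. = FALSE)
  if (length(spot_ids) != n) stop("'spot_ids' length must equal ncol(counts)", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("'gene_ids' must be unique", call. = FALSE)
  if (anyDuplicated(spot_ids)) stop("'spot_ids' must be unique", call. = FALSE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != n)
    stop(sprintf("coords has %d rows but counts has %d spots", nrow(coords), n),
         call. = FALSE)
  if (ncol(coords) != 2) stop("'coords' must have two columns (x, y)", call. = FALSE)
  colnames(coords) <- c("x", "y")
  if (!is.null(ref_labels)) {
    if (length(ref_labels) != n)
      stop("'ref_labels' length must equal the number of spots", call. = FALSE)
    ref_labels <- as.character(ref_labels)
  }
  dimnames(counts) <- list(gene_ids, spot_ids)
  rownames(coords) <- spot_ids
  structure(list(counts = counts, coords = coords, gene_ids = gene_ids,
                 spot_ids = spot_ids, image = image, ref_labels = ref_labels),
            class = "st_dataset")
}

#' @method print st_dataset
#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("st_dataset: %d genes x %d spots\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  coords range: x [%.1f, %.1f], y [%.1f, %.1f]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  if (!is.null(x$image))
    cat(sprintf("  image: %s pixels\n", paste(dim(x$image), collapse = " x ")))
  if (!is.null(x$ref_labels))
    cat(sprintf("  reference labels: %d classes\n", length(unique(x$ref_labels))))
  invisible(x)
}

#' @method dim st_dataset
#' @export
dim.st_dataset <- function(x) dim(x$counts)

# Subset an st_dataset by gene and/or spot index vectors.
subset_st <- function(ds, genes = NULL, spots = NULL) {
  genes <- genes %||% seq_len(nrow(ds$counts))
  spots <- spots %||% seq_len(ncol(ds$counts))
  st_dataset(ds$counts[genes, spots, drop = FALSE],
             ds$coords[spots, , drop = FALSE],
             gene_ids = ds$gene_ids[genes], spot_ids = ds$spot_ids[spots],
             image = ds$image,
             ref_labels = if (!is.null(ds$ref_labels)) ds$ref_labels[spots])
}

#' Read a spatial transcriptomics dataset from disk
#'
#' Reads an expression matrix (Matrix Market sparse triplet with companion
#' gene/barcode TSV files, or a dense CSV with genes in rows), a spot
#' coordinate table, and optional histology image and reference labels.
#' Spots are aligned across files by identifier when identifiers are present,
#' otherwise by order.
#'
#' @param matrix_path path to a `.mtx` Matrix Market file (genes x spots) or
#'   a CSV with gene identifiers in the first column and one column per spot.
#' @param coords_path path to a CSV/TSV with columns `spot_id,x,y` (header
#'   required; a two-column `x,y` file is accepted and matched by order).
#' @param genes_path,barcodes_path for MTX input, paths to one-column files
#'   of gene and spot identifiers; default to `genes.tsv`/`barcodes.tsv`
#'   next to the matrix.
#' @param image_path optional PNG or TIFF histology image.
#' @param labels_path optional CSV with columns `spot_id,label`.
#' @return An [st_dataset].
#' @export
read_st <- function(matrix_path, coords_path, genes_path = NULL,
                    barcodes_path = NULL, image_path = NULL,
                    labels_path = NULL) {
  for (p in c(matrix_path, coords_path, image_path, labels_path,
              genes_path, barcodes_path))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("file not found: %s", p), call. = FALSE)

  ext <- tolower(tools::file_ext(matrix_path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(matrix_path))
    dir <- dirname(matrix_path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
    gene_ids <- if (file.exists(genes_path))
      utils::read.table(genes_path, header = FALSE,
                        stringsAsFactors = FALSE)[, 1] else NULL
    spot_ids <- if (file.exists(barcodes_path))
      utils::read.table(barcodes_path, header = FALSE,
                        stringsAsFactors = FALSE)[, 1] else NULL
    rownames(m) <- gene_ids; colnames(m) <- spot_ids
  } else if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("expression matrix is not numeric", call. = FALSE)
  } else {
    stop(sprintf("unsupported matrix format '.%s' (use .mtx or .csv)", ext),
         call. = FALSE)
  }

  cext <- tolower(tools::file_ext(coords_path))
  coords_tab <- utils::read.table(coords_path, header = TRUE,
                                  sep = if (cext == "tsv") "\t" else ",",
                                  stringsAsFactors = FALSE)
  if (all(c("x", "y") %in% names(coords_tab)) && "spot_id" %in% names(coords_tab)) {
    spot_id_col <- as.character(coords_tab$spot_id)
    if (!is.null(colnames(m))) {
      idx <- match(colnames(m), spot_id_col)
      if (anyNA(idx))
        stop("coords are missing entries for some spots in the matrix",
             call. = FALSE)
      coords_tab <- coords_tab[idx, , drop = FALSE]
    }
    coords <- as.matrix(coords_tab[, c("x", "y")])
  } else {
    coords <- as.matrix(coords_tab[, 1:2])
  }
  if (nrow(coords) != ncol(m))
    stop(sprintf("alignment error: %d coordinate rows for %d spots",
                 nrow(coords), ncol(m)), call. = FALSE)

  image <- if (!is.null(image_path)) read_image(image_path)
  ref_labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if ("spot_id" %in% names(lab) && !is.null(colnames(m))) {
      idx <- match(colnames(m), as.character(lab$spot_id))
      if (anyNA(idx)) stop("labels are missing entries for some spots", call. = FALSE)
      ref_labels <- as.character(lab$label[idx])
    } else {
      if (nrow(lab) != ncol(m))
        stop("alignment error between labels and matrix", call. = FALSE)
      ref_labels <- as.character(lab[[ncol(lab)]])
    }
  }
  st_dataset(m, coords, image = image, ref_labels = ref_labels)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG images requires the 'png' package", call. = FALSE)
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
}
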