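# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_square_symmetric <- function(A, name = deparse(substitute(A)), tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(A - t(A))) > tol)
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  invisible(TRUE)
}

check_binary_adjacency <- function(A, name = deparse(substitute(A))) {
  check_square_symmetric(A, name)
  if (any(A != 0 & A != 1))
    stop(sprintf("'%s' must be binary (0/1)", name), call. = FALSE)
  if (any(diag(A) != 0))
    stop(sprintf("'%s' must have a zero diagonal", name), call. = FALSE)
  invisible(TRUE)
}

# Squared Euclidean distances between columns of H (d x n) -> n x n.
colwise_sqdist <- function(H) {
  cs <- colSums(H^2)
  D2 <- outer(cs, cs, "+") - 2 * crossprod(H)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
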