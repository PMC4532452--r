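#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Matrix of pairwise *squared* distances between rows of X (nm^2).
pairdist2 <- function(X) {
  g <- tcrossprod(X)
  b <- diag(g)
  d <- outer(b, b, "+") - 2 * g
  d[d < 0] <- 0
  diag(d) <- 0
  (d + t(d)) / 2
}

## Pairwise distances in nm.
pairdist <- function(X) sqrt(pairdist2(X))

upper_vec <- function(m) m[upper.tri(m)]

check_square <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  invisible(m)
}

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  check_square(m, name)
  if (max(abs(m - t(m)), na.rm = TRUE) > tol * max(1, max(abs(m), na.rm = TRUE)))
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  invisible(m)
}

as_coords <- function(x, name = "coords") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (rows = beads)", name), call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop(sprintf("'%s' must have at least one row and one column", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  x
}
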