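## Euclidean distance matrix (EDM) algebra: EDM/Gram conversions, classical
## MDS, the kappa map between Gram matrices and squared EDMs, and structure
## comparison. The canonical unit throughout is nm; squared EDMs hold nm^2.

#' Squared Euclidean distance matrix with an observed-entry mask
#'
#' Container for an n x n matrix of squared pairwise distances (nm^2) together
#' with a logical mask marking which entries are observed. The mask is kept
#' explicit (rather than encoding missingness as 0) because 0 is a legal value
#' on the diagonal.
#'
#' @param values n x n numeric matrix of squared distances (nm^2); symmetric,
#'   zero diagonal, non-negative.
#' @param mask n x n logical matrix of observed entries; symmetric with `TRUE`
#'   diagonal. Defaults to fully observed.
#' @return An object of class `squared_edm` with elements `values` and `mask`.
#' @export
squared_edm <- function(values, mask = NULL) {
  check_symmetric(values, "values")
  n <- nrow(values)
  if (any(!is.finite(values))) stop("'values' contains non-finite entries")
  if (any(values < -1e-9 * max(1, max(abs(values)))))
    stop("'values' has negative entries; squared distances must be >= 0")
  values[values < 0] <- 0
  if (max(abs(diag(values))) > 1e-9 * max(1, max(abs(values))))
    stop("'values' must have a zero diagonal")
  diag(values) <- 0
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  if (!is.matrix(mask) || !is.logical(mask) || any(dim(mask) != n))
    stop("'mask' must be an n x n logical matrix")
  if (any(mask != t(mask))) stop("'mask' must be symmetric")
  diag(mask) <- TRUE
  structure(list(values = values, mask = mask), class = "squared_edm")
}

#' @export
print.squared_edm <- function(x, ...) {
  n <- nrow(x$values)
  np <- n * (n - 1) / 2
  obs <- sum(x$mask[upper.tri(x$mask)])
  cat(sprintf("squared EDM: %d beads, %d/%d pairs observed (%.1f%%)\n",
              n, obs, np, if (np > 0) 100 * obs / np else 100))
  invisible(x)
}

is_complete <- function(edm) all(edm$mask)

as_squared_edm <- function(x) {
  if (inherits(x, "squared_edm")) return(x)
  squared_edm(x)
}

#' Squared EDM from bead coordinates
#'
#' @param coords n x r numeric matrix of bead positions (nm).
#' @return A fully observed [squared_edm()] with `D[i,j] = ||x_i - x_j||^2`.
#' @export
edm_from_coords <- function(coords) {
  coords <- as_coords(coords)
  squared_edm(pairdist2(coords))
}

#' Gram matrix from a complete squared EDM
#'
#' Double-centers the squared EDM: `B = -1/2 J D J` with `J = I - ee'/n`. For a
#' true EDM of an r-dimensional configuration, `B` is positive semidefinite of
#' rank at most r and equals `X_c X_c'` for the centered coordinates.
#'
#' @param edm A [squared_edm()] (or plain matrix), fully observed.
#' @return n x n Gram matrix (row sums zero).
#' @export
gram_from_edm <- function(edm) {
  edm <- as_squared_edm(edm)
  if (!is_complete(edm))
    stop("squared EDM has unobserved entries; complete it first, e.g. with ",
         "shortest_path_complete() on the underlying distances")
  d <- edm$values
  rm <- rowMeans(d)
  gm <- mean(d)
  b <- -0.5 * (d - outer(rm, rep(1, nrow(d))) - outer(rep(1, nrow(d)), rm) + gm)
  (b + t(b)) / 2
}

#' Classical multidimensional scaling embedding
#'
#' Embeds a complete squared EDM in r dimensions via the top-r eigenpairs of
#' the Gram matrix: `X = V sqrt(Lambda)`. Negative eigenvalues (which arise
#' when the input is not a true EDM) are clamped to zero before the square
#' root. Eigenvector signs are fixed (largest-magnitude component positive) so
#' the output is bit-reproducible.
#'
#' @param edm A [squared_edm()] or plain squared-distance matrix, complete.
#' @param r Embedding dimension (default 3).
#' @return n x r coordinate matrix (nm), centered at the origin.
#' @export
cmds_embed <- function(edm, r = 3L) {
  edm <- as_squared_edm(edm)
  n <- nrow(edm$values)
  if (r > n) stop(sprintf("embedding dimension r = %d exceeds n = %d", r, n))
  b <- gram_from_edm(edm)
  es <- eigen(b, symmetric = TRUE)
  lam <- pmax(es$values[seq_len(r)], 0)
  v <- es$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    i0 <- which.max(abs(v[, j]))
    if (v[i0, j] < 0) v[, j] <- -v[, j]
  }
  x <- v * rep(sqrt(lam), each = n)
  x - rep(colMeans(x), each = n)
}

#' The kappa map: Gram matrix to squared EDM
#'
#' `kappa(B) = b e' + e b' - 2 B` with `b = diag(B)`. For `B = X X'` this
#' reproduces the squared pairwise distances of X.
#'
#' @param gram n x n symmetric matrix.
#' @return n x n matrix with zero diagonal.
#' @export
kappa_map <- function(gram) {
  check_symmetric(gram, "gram")
  b <- diag(gram)
  d <- outer(b, b, "+") - 2 * gram
  diag(d) <- 0
  d
}

#' Adjoint of the kappa map
#'
#' `kappa*(M) = 2 (Diag(M e) - M)`, the adjoint of [kappa_map()] with respect
#' to the Frobenius inner product.
#'
#' @param m n x n symmetric matrix.
#' @return n x n symmetric matrix.
#' @export
kappa_adjoint <- function(m) {
  check_symmetric(m, "m")
  res <- -2 * m
  diag(res) <- diag(res) + 2 * rowSums(m)
  res
}

## kappa_adjoint(M) %*% Y without forming the n x n adjoint.
kappa_adjoint_times <- function(m, y) {
  2 * (rowSums(m) * y - m %*% y)
}

#' Optimal superposition RMSD between two structures
#'
#' Minimal root-mean-square deviation over translations and orthogonal
#' transforms (Kabsch superposition). By default improper rotations
#' (reflections) are allowed, because contact data cannot resolve chirality;
#' set `allow_reflection = FALSE` to restrict to proper rotations. The
#' returned value carries an attribute `improper` recording whether the
#' optimal transform was a reflection.
#'
#' @param a,b n x r coordinate matrices (nm).
#' @param allow_reflection Allow improper rotations (default `TRUE`).
#' @return RMSD in nm (scalar, with attribute `improper`).
#' @export
superimpose_rmsd <- function(a, b, allow_reflection = TRUE) {
  a <- as_coords(a, "a"); b <- as_coords(b, "b")
  if (!all(dim(a) == dim(b))) stop("'a' and 'b' must have identical dimensions")
  n <- nrow(a)
  ac <- a - rep(colMeans(a), each = n)
  bc <- b - rep(colMeans(b), each = n)
  s <- svd(crossprod(bc, ac))              # t(bc) %*% ac = U D V'
  rot <- s$u %*% t(s$v)                    # best orthogonal map for bc -> ac
  improper <- det(rot) < 0
  if (improper && !allow_reflection) {
    d <- ncol(a)
    flip <- diag(c(rep(1, d - 1), -1))
    rot <- s$u %*% flip %*% t(s$v)
    improper <- FALSE
  }
  res <- sqrt(sum((ac - bc %*% rot)^2) / n)
  attr(res, "improper") <- improper
  res
}

#' Spearman distance dissimilarity between two structures' distance sets
#'
#' `1 - rho` where `rho` is the Spearman rank correlation between the
#' upper-triangle entries of the two matrices. Being rank-based, the result is
#' invariant to any monotone transform of either input (so squared and plain
#' distances are interchangeable); 0 means perfect monotone agreement, 2 means
#' perfectly reversed ranks.
#'
#' @param edm_a,edm_b [squared_edm()] objects or plain symmetric matrices of
#'   equal size (n >= 3).
#' @param tie_tol Relative quantization applied to each distance set before
#'   ranking (default 1e-9 of its largest value). Distance sets with exactly
#'   tied entries (e.g. fixed-step chains, where every consecutive pair is at
#'   the same separation) would otherwise have those ties broken arbitrarily
#'   by round-off in a reconstruction that is exact to machine precision,
#'   placing a spurious floor under 1 - rho; the quantum is far below any
#'   genuine structural difference.
#' @return Value in \[0, 2\].
#' @export
spearman_dissimilarity <- function(edm_a, edm_b, tie_tol = 1e-9) {
  va <- if (inherits(edm_a, "squared_edm")) edm_a$values else edm_a
  vb <- if (inherits(edm_b, "squared_edm")) edm_b$values else edm_b
  check_square(va, "edm_a"); check_square(vb, "edm_b")
  if (nrow(va) != nrow(vb)) stop("inputs must have the same size")
  if (nrow(va) < 3L) stop("n must be >= 3 for a rank correlation over pairs")
  xa <- upper_vec(va); xb <- upper_vec(vb)
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop("degenerate input: all pairwise distances identical")
  if (tie_tol > 0) {
    xa <- round(xa / (tie_tol * max(abs(xa))))
    xb <- round(xb / (tie_tol * max(abs(xb))))
  }
  1 - stats::cor(xa, xb, method = "spearman")
}
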