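## Manifold-based optimization core: the weighted square-root-distance stress
## cost, its Euclidean gradient and Hessian, and a Riemannian trust-region
## minimization over rank-r positive semidefinite Gram factorizations
## B = X X'. The search space is the quotient of the full-rank factor space
## by the orthogonal group O(r) (the cost is invariant under X -> X Q); the
## geometry used is the flat Euclidean metric on factors with horizontal-space
## projection and the retraction X + U.

## Denominator floor (nm^2) guarding divisions by kappa(XX')_ij, which
## vanishes for coincident beads (routinely the case at random init).
.KAPPA_EPS <- 1e-12

#' Problem definition for the manifold optimizer
#'
#' @param target Target squared distances (nm^2): a [squared_edm()], a
#'   completed [target_distances()] (its nm distances are squared), or a plain
#'   matrix. Unreachable (`Inf`) entries are zeroed; they must carry weight 0.
#' @param weights A [weight_matrix()] or plain non-negative symmetric matrix.
#'   Defaults to the target's observed-entry mask (1 observed / 0 missing),
#'   the plain matrix-completion setting.
#' @param r Embedding rank (default 3).
#' @param use_squared_residuals If `TRUE`, minimize the squared-distance
#'   residuals `(kappa(XX')_ij - D_ij)` instead of the default square-root
#'   (plain-distance) residuals. The square-root form is the method's default:
#'   it relaxes the penalty on long distances, which carry the least reliable
#'   information; the squared form is retained as an ablation.
#' @return Object of class `mbo_problem`.
#' @export
mbo_problem <- function(target, weights = NULL, r = 3L,
                        use_squared_residuals = FALSE) {
  mask <- NULL
  if (inherits(target, "target_distances")) {
    if (!isTRUE(target$completed))
      stop("complete the target distances first (shortest_path_complete)")
    mask <- target$mask
    d <- target$distances^2
    d[!mask] <- 0
  } else if (inherits(target, "squared_edm")) {
    mask <- target$mask
    d <- target$values
    d[!mask] <- 0
  } else {
    d <- target
    check_square(d, "target")
  }
  diag(d) <- 0
  n <- nrow(d)
  if (is.null(weights)) {
    if (is.null(mask)) mask <- matrix(TRUE, n, n)
    h <- mask * 1
    diag(h) <- 0
  } else if (inherits(weights, "weight_matrix")) {
    h <- weights$values
  } else {
    h <- weights
  }
  check_symmetric(h, "weights")
  if (any(h < 0)) stop("weights must be non-negative")
  diag(h) <- 0
  if (!all(dim(h) == n)) stop("target and weights must have the same shape")
  if (any(!is.finite(d))) stop("target has non-finite entries with nonzero weight mask")
  structure(list(D = d, sqrtD = sqrt(d), H2 = h * h, H = h, r = as.integer(r),
                 use_squared_residuals = isTRUE(use_squared_residuals)),
            class = "mbo_problem")
}

#' Optimizer configuration
#'
#' @param cost_tol Stop when the cost drops below this (default 1e-20).
#' @param gradnorm_tol Stop when the Riemannian gradient norm drops below this
#'   (default 1e-8).
#' @param max_iterations Outer trust-region iteration cap (default 1000).
#' @param max_inner Inner truncated-CG iteration cap (default
#'   `min(n * r, 250)`, set at run time).
#' @param dist_tol Practical convergence tolerance in nm: stop once every
#'   weighted distance residual `H_ij * |sqrt(kappa(XX')_ij) - sqrt(D_ij)|`
#'   falls below it. `0` (default) disables it, leaving only the cost and
#'   gradient-norm rules; the Hi-C pipeline enables it because its target
#'   distances are 60/120 nm model constructs for which sub-nanometre misfit
#'   carries no information, while convergence to the exact optimum is
#'   asymptotically slow on these ill-conditioned weighted problems.
#' @param init_scale Length scale (nm) of the random initial configuration:
#'   the mean consecutive-bead distance of the init. `NULL` (default) derives
#'   it from the mean observed target distance.
#' @param delta_max Trust-region radius cap; default `max(||X0||_F, 1)`.
#' @param seed Integer seed for the random initialization.
#' @param warm_start Precede the square-root-stress minimization with a
#'   trust-region pass on the squared-residual cost from the same random
#'   init, and refine from its solution (default `TRUE`). The square-root
#'   stress has fold-type local minima that trap a substantial fraction of
#'   purely random starts even on complete noiseless data; the squared cost
#'   is far better behaved, and continuing from its minimizer makes recovery
#'   reliable while the final answer is still a minimizer of the square-root
#'   cost. Ignored when the problem itself uses squared residuals.
#' @param verbose Print per-iteration diagnostics.
#' @return Object of class `mbo_config`.
#' @export
mbo_config <- function(cost_tol = 1e-20, gradnorm_tol = 1e-8,
                       max_iterations = 1000L, max_inner = NULL,
                       dist_tol = 0, init_scale = NULL, delta_max = NULL,
                       seed = NULL, warm_start = TRUE, verbose = FALSE) {
  stopifnot(cost_tol > 0, gradnorm_tol > 0, max_iterations >= 1, dist_tol >= 0)
  structure(list(cost_tol = cost_tol, gradnorm_tol = gradnorm_tol,
                 max_iterations = as.integer(max_iterations),
                 max_inner = max_inner, dist_tol = dist_tol,
                 init_scale = init_scale,
                 delta_max = delta_max, seed = seed,
                 warm_start = isTRUE(warm_start), verbose = verbose),
            class = "mbo_config")
}

## Largest weighted distance residual (nm) of the current iterate.
max_weighted_resid <- function(X, prob) {
  delta <- pairdist2(X)
  max(prob$H * abs(sqrt(delta) - prob$sqrtD))
}

#' Weighted stress cost
#'
#' `f(X) = 1/2 sum_ij H_ij^2 (sqrt(kappa(XX')_ij) - sqrt(D_ij))^2` (square
#' roots element-wise; the sum runs over all ordered pairs, i.e. the squared
#' Frobenius norm of the weighted residual matrix). In the squared-residual
#' ablation the residual is `kappa(XX')_ij - D_ij`.
#'
#' @param X n x r coordinate matrix.
#' @param prob An [mbo_problem()].
#' @return Non-negative scalar; zero iff all positively weighted distances
#'   match exactly.
#' @export
mbo_cost <- function(X, prob) {
  X <- as_coords(X, "X")
  if (nrow(X) != nrow(prob$D) || ncol(X) != prob$r)
    stop("X must be n x r for this problem")
  delta <- pairdist2(X)
  resid <- if (prob$use_squared_residuals) delta - prob$D
           else sqrt(delta) - prob$sqrtD
  0.5 * sum(prob$H2 * resid^2)
}

#' Euclidean gradient of the stress cost
#'
#' `grad f(X) = kappa*(H^(2) o (ee' - K)) X` with
#' `K_ij = sqrt(D_ij / kappa(XX')_ij)` off-diagonal (denominator floored at
#' 1e-12 nm^2), and `H^(2) = H o H`.
#'
#' @inheritParams mbo_cost
#' @return n x r matrix.
#' @export
mbo_egrad <- function(X, prob) {
  delta <- pairdist2(X)
  if (prob$use_squared_residuals) {
    s <- prob$H2 * (delta - prob$D)
    return(2 * kappa_adjoint_times(s, X))
  }
  del <- pmax(delta, .KAPPA_EPS)
  k <- prob$sqrtD / sqrt(del)
  diag(k) <- 0
  s <- prob$H2 * (1 - k)
  kappa_adjoint_times(s, X)
}

#' Euclidean Hessian of the stress cost in a direction
#'
#' `Hess f(X)[U] = kappa*(H^(2) o (ee' - K)) U +
#'  1/2 kappa*(H^(2) o G o kappa(XU' + UX')) X` with
#' `G_ij = sqrt(D_ij / kappa(XX')_ij^3)` off-diagonal.
#'
#' @inheritParams mbo_cost
#' @param U n x r direction matrix.
#' @return n x r matrix.
#' @export
mbo_ehess <- function(X, U, prob) {
  make_ehess_op(X, prob)(U)
}

## Hessian-vector operator at a fixed X: the X-dependent matrices (K, G, the
## residual-weight matrix S) are precomputed once and shared by every
## application, which is what the truncated-CG inner loop needs.
make_ehess_op <- function(X, prob) {
  delta <- pairdist2(X)
  if (prob$use_squared_residuals) {
    s <- prob$H2 * (delta - prob$D)
    h2 <- prob$H2
    return(function(U) {
      xu <- tcrossprod(X, U)
      bp <- 2 * diag(xu)
      kb <- outer(bp, bp, "+") - 2 * (xu + t(xu))
      diag(kb) <- 0
      2 * kappa_adjoint_times(s, U) + 2 * kappa_adjoint_times(h2 * kb, X)
    })
  }
  del <- pmax(delta, .KAPPA_EPS)
  k <- prob$sqrtD / sqrt(del)
  diag(k) <- 0
  s <- prob$H2 * (1 - k)
  h2g <- 0.5 * prob$H2 * (prob$sqrtD / del^1.5)
  diag(h2g) <- 0
  function(U) {
    xu <- tcrossprod(X, U)
    bp <- 2 * diag(xu)
    kb <- outer(bp, bp, "+") - 2 * (xu + t(xu))
    diag(kb) <- 0
    kappa_adjoint_times(s, U) + kappa_adjoint_times(h2g * kb, X)
  }
}

#' Random point on the rank-r factor manifold
#'
#' I.i.d. Gaussian coordinates scaled so the mean consecutive-bead distance is
#' approximately `init_scale` nm (for i.i.d. beads the mean pairwise and mean
#' consecutive distances coincide). Redrawn in the unlikely event of a
#' rank-deficient draw.
#'
#' @param n Number of beads.
#' @param r Rank (embedding dimension).
#' @param cfg An [mbo_config()] supplying `seed` and `init_scale`.
#' @param init_scale Overrides `cfg$init_scale` if given.
#' @return n x r coordinate matrix.
#' @export
random_init <- function(n, r = 3L, cfg = mbo_config(), init_scale = NULL) {
  scale <- init_scale %||% cfg$init_scale %||% 120
  ## E||x_i - x_{i+1}|| = sd * sqrt(2) * E[chi_3] = sd * 4 / sqrt(pi)
  sd <- scale * sqrt(pi) / 4
  with_seed(cfg$seed, {
    x <- matrix(stats::rnorm(n * r, sd = sd), n, r)
    tries <- 0
    while (n >= r && qr(x)$rank < r && tries < 100) {
      x <- matrix(stats::rnorm(n * r, sd = sd), n, r)
      tries <- tries + 1
    }
    x
  })
}

## Projection of an ambient direction U onto the horizontal space at X:
## U - X Omega, with skew-symmetric Omega solving
## (X'X) Omega + Omega (X'X) = X'U - U'X  (a small r x r Sylvester system).
horizontal_project <- function(X, U) {
  s <- crossprod(X)
  a <- crossprod(X, U) - crossprod(U, X)
  es <- eigen(s, symmetric = TRUE)
  at <- crossprod(es$vectors, a %*% es$vectors)
  den <- outer(es$values, es$values, "+")
  den[den < 1e-30] <- 1e-30
  om <- es$vectors %*% (at / den) %*% t(es$vectors)
  U - X %*% om
}

## Steihaug-Toint truncated CG for the trust-region subproblem
## min <g, eta> + 1/2 <eta, H eta>  s.t. ||eta|| <= delta,
## with H the Riemannian Hessian (horizontal projection of the Euclidean one).
tcg <- function(X, g, delta, prob, max_inner, theta = 1, kappa = 0.1) {
  ehess <- make_ehess_op(X, prob)
  hop <- function(u) horizontal_project(X, ehess(u))
  eta <- 0 * g
  heta <- eta
  r <- g
  d <- -r
  r_r <- sum(r * r)
  norm_r0 <- sqrt(r_r)
  e_e <- 0
  boundary <- FALSE
  for (j in seq_len(max_inner)) {
    hd <- hop(d)
    d_hd <- sum(d * hd)
    d_d <- sum(d * d)
    e_d <- sum(eta * d)
    if (d_hd <= 0) {
      ## negative curvature: follow d to the boundary
      tau <- (-e_d + sqrt(e_d^2 + d_d * (delta^2 - e_e))) / d_d
      eta <- eta + tau * d
      heta <- heta + tau * hd
      boundary <- TRUE
      break
    }
    alpha <- r_r / d_hd
    e_e_new <- e_e + 2 * alpha * e_d + alpha^2 * d_d
    if (e_e_new >= delta^2) {
      tau <- (-e_d + sqrt(e_d^2 + d_d * (delta^2 - e_e))) / d_d
      eta <- eta + tau * d
      heta <- heta + tau * hd
      boundary <- TRUE
      break
    }
    eta <- eta + alpha * d
    heta <- heta + alpha * hd
    e_e <- e_e_new
    r <- r + alpha * hd
    r_r_new <- sum(r * r)
    if (sqrt(r_r_new) <= norm_r0 * min(kappa, norm_r0^theta)) break
    beta <- r_r_new / r_r
    d <- -r + beta * d
    r_r <- r_r_new
  }
  list(eta = eta, heta = heta, boundary = boundary, inner = j)
}

#' Riemannian trust-region minimization of the stress cost
#'
#' Minimizes the weighted stress over the quotient manifold of rank-r Gram
#' factors (second-order trust-region method with a truncated-CG inner
#' solver). Stops when the cost or the Riemannian gradient norm drops below
#' its tolerance, or at the iteration cap (the latter yields a warning, not an
#' error). The accepted iterates are monotonically non-increasing in cost.
#' The returned coordinates are centered at the origin.
#'
#' @param prob An [mbo_problem()].
#' @param cfg An [mbo_config()].
#' @param X0 Optional n x r starting configuration; defaults to
#'   [random_init()] under `cfg$seed`.
#' @return Object of class `mbo_result`: `coords`, `final_cost`,
#'   `final_gradnorm`, `iterations`, `converged_reason`, `seed`.
#' @export
mbo_optimize <- function(prob, cfg = mbo_config(), X0 = NULL) {
  n <- nrow(prob$D)
  r <- prob$r
  if (is.null(X0)) {
    scale <- cfg$init_scale
    if (is.null(scale)) {
      obs <- prob$H > 0
      scale <- if (any(obs)) mean(prob$sqrtD[obs]) else 120
    }
    X0 <- random_init(n, r, cfg, init_scale = scale)
  }
  X <- as_coords(X0, "X0")
  iters0 <- 0L
  if (cfg$warm_start && !prob$use_squared_residuals) {
    ## continuation stage on the better-behaved squared-residual cost; only
    ## the basin matters here, so the stop rule is a relative gradient drop
    prob_sq <- prob
    prob_sq$use_squared_residuals <- TRUE
    g0 <- horizontal_project(X, mbo_egrad(X, prob_sq))
    pre <- rtr_core(prob_sq, X, cfg,
                    gradnorm_tol = max(1e-8 * sqrt(sum(g0 * g0)), 1e-30),
                    cost_tol = 1e-30,
                    max_iterations = min(cfg$max_iterations, 300L))
    X <- pre$X
    iters0 <- pre$iterations
  }
  out <- rtr_core(prob, X, cfg, gradnorm_tol = cfg$gradnorm_tol,
                  cost_tol = cfg$cost_tol,
                  max_iterations = cfg$max_iterations)
  if (out$reason == "max_iterations")
    warning("mbo_optimize: iteration cap reached before convergence")
  Xf <- out$X - rep(colMeans(out$X), each = n)
  structure(list(coords = Xf, final_cost = out$cost,
                 final_gradnorm = out$gnorm,
                 iterations = iters0 + out$iterations,
                 converged_reason = out$reason, seed = cfg$seed),
            class = "mbo_result")
}

## One Riemannian trust-region run at fixed tolerances.
rtr_core <- function(prob, X, cfg, gradnorm_tol, cost_tol, max_iterations,
                     dist_tol = cfg$dist_tol %||% 0) {
  n <- nrow(X)
  max_inner <- cfg$max_inner %||% min(n * prob$r, 250L)
  fx <- mbo_cost(X, prob)
  g <- horizontal_project(X, mbo_egrad(X, prob))
  gnorm <- sqrt(sum(g * g))
  delta_bar <- cfg$delta_max %||% max(sqrt(sum(X * X)), 1)
  delta <- delta_bar / 8
  reason <- "max_iterations"
  iters <- 0L
  stall <- 0L
  for (k in seq_len(max_iterations)) {
    if (fx < cost_tol) { reason <- "cost_tol"; break }
    if (gnorm < gradnorm_tol) { reason <- "gradnorm_tol"; break }
    if (dist_tol > 0 && !prob$use_squared_residuals &&
        max_weighted_resid(X, prob) < dist_tol) {
      reason <- "dist_tol"; break
    }
    if (delta < delta_bar * 1e-14) { reason <- "step_collapse"; break }
    if (stall >= 10L) { reason <- "stagnation"; break }
    iters <- k
    step <- tcg(X, g, delta, prob, max_inner)
    xp <- X + step$eta
    fp <- mbo_cost(xp, prob)
    mdec <- -(sum(g * step$eta) + 0.5 * sum(step$eta * step$heta))
    reg <- max(1, abs(fx)) * .Machine$double.eps * 1e3
    rho <- (fx - fp + reg) / (mdec + reg)
    if (!is.finite(rho)) rho <- -1
    if (rho < 0.25) {
      delta <- delta / 4
    } else if (rho > 0.75 && step$boundary) {
      delta <- min(2 * delta, delta_bar)
    }
    if (rho > 0.1 && fp <= fx) {
      decrease <- fx - fp
      X <- xp
      fx <- fp
      g <- horizontal_project(X, mbo_egrad(X, prob))
      gnorm <- sqrt(sum(g * g))
      stall <- if (decrease <= 1e-15 * max(fx, 1e-300)) stall + 1L else 0L
    } else if (rho >= 0.25) {
      stall <- stall + 1L   # rejected without shrinking delta: no progress
    }
    if (cfg$verbose)
      message(sprintf("iter %4d  cost %.6e  |grad| %.3e  delta %.3e  inner %d",
                      k, fx, gnorm, delta, step$inner))
  }
  list(X = X, cost = fx, gnorm = gnorm, iterations = iters, reason = reason)
}

#' @export
print.mbo_result <- function(x, ...) {
  cat(sprintf(
    "MBO result: %d beads, cost %.3e, |grad| %.3e, %d iterations (%s)\n",
    nrow(x$coords), x$final_cost, x$final_gradnorm, x$iterations,
    x$converged_reason))
  invisible(x)
}
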