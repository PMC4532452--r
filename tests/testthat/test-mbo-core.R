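## Random small instances shared by the derivative checks.
rand_instance <- function(n = 10, r = 3) {
  x <- matrix(rnorm(n * r), n, r) * 50
  d <- edm_from_coords(matrix(rnorm(n * r), n, r) * 60)
  h <- matrix(runif(n * n), n)
  h <- (h + t(h)) / 2
  diag(h) <- 0
  list(x = x, prob_sqrt = mbo_problem(d, weights = h),
       prob_sq = mbo_problem(d, weights = h, use_squared_residuals = TRUE))
}

fd_grad <- function(x, prob, h = 1e-5) {
  g <- x * 0
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    g[k] <- (mbo_cost(xp, prob) - mbo_cost(xm, prob)) / (2 * h)
  }
  g
}

test_that("cost matches an explicit double-loop evaluation", {
  set.seed(21)
  for (mode in c(FALSE, TRUE)) {
    inst <- rand_instance(8)
    prob <- if (mode) inst$prob_sq else inst$prob_sqrt
    x <- inst$x
    n <- nrow(x)
    acc <- 0
    for (i in 1:n) for (j in 1:n) {
      dij <- sum((x[i, ] - x[j, ])^2)
      rij <- if (mode) dij - prob$D[i, j] else sqrt(dij) - sqrt(prob$D[i, j])
      acc <- acc + 0.5 * prob$H[i, j]^2 * rij^2
    }
    expect_equal(mbo_cost(x, prob), acc, tolerance = 1e-12)
  }
  ## perfect fit costs zero for any weights
  chain <- fixture_chain(12)
  prob <- mbo_problem(edm_from_coords(chain))
  expect_equal(mbo_cost(chain, prob), 0)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(22)
  for (i in 1:10) {
    inst <- rand_instance()
    g <- mbo_egrad(inst$x, inst$prob_sqrt)
    ref <- fd_grad(inst$x, inst$prob_sqrt)
    expect_lt(max(abs(g - ref)) / max(abs(ref)), 1e-6)
  }
  ## stationarity at a perfect fit
  chain <- fixture_chain(15)
  prob <- mbo_problem(edm_from_coords(chain))
  g0 <- mbo_egrad(chain, prob)
  expect_lt(max(abs(g0)), 1e-9 * max(1, max(abs(chain))))
  ## zero weights give a zero gradient
  inst <- rand_instance(6)
  probz <- mbo_problem(mbo3d::edm_from_coords(matrix(rnorm(18), 6, 3)),
                       weights = matrix(0, 6, 6))
  expect_equal(mbo_egrad(inst$x[1:6, ], probz), matrix(0, 6, 3))
})

test_that("squared-residual ablation has its own consistent derivatives", {
  set.seed(23)
  for (i in 1:5) {
    inst <- rand_instance()
    g <- mbo_egrad(inst$x, inst$prob_sq)
    ref <- fd_grad(inst$x, inst$prob_sq)
    expect_lt(max(abs(g - ref)) / max(abs(ref)), 1e-6)
    u <- matrix(rnorm(30), 10, 3)
    hu <- mbo_ehess(inst$x, u, inst$prob_sq)
    h <- 1e-5
    href <- (mbo_egrad(inst$x + h * u, inst$prob_sq) -
             mbo_egrad(inst$x - h * u, inst$prob_sq)) / (2 * h)
    expect_lt(max(abs(hu - href)) / max(abs(href)), 1e-5)
  }
})

test_that("Hessian matches directional finite differences and is symmetric", {
  set.seed(24)
  for (i in 1:10) {
    inst <- rand_instance()
    u <- matrix(rnorm(30), 10, 3)
    hu <- mbo_ehess(inst$x, u, inst$prob_sqrt)
    h <- 1e-5
    href <- (mbo_egrad(inst$x + h * u, inst$prob_sqrt) -
             mbo_egrad(inst$x - h * u, inst$prob_sqrt)) / (2 * h)
    expect_lt(max(abs(hu - href)) / max(abs(href)), 1e-5)
    v <- matrix(rnorm(30), 10, 3)
    lhs <- sum(u * mbo_ehess(inst$x, v, inst$prob_sqrt))
    rhs <- sum(v * hu)
    expect_lt(abs(lhs - rhs) / max(1, abs(lhs)), 1e-8)
    expect_equal(mbo_ehess(inst$x, u * 0, inst$prob_sqrt), u * 0)
  }
})

test_that("random_init is seeded, scaled, and full rank", {
  cfg <- mbo_config(seed = 5)
  x1 <- random_init(50, 3, cfg)
  x2 <- random_init(50, 3, cfg)
  expect_identical(x1, x2)
  x3 <- random_init(50, 3, mbo_config(seed = 6))
  expect_false(identical(x1, x3))
  expect_equal(qr(x1)$rank, 3)
  ## mean consecutive distance close to the requested scale
  big <- random_init(4000, 3, mbo_config(seed = 7), init_scale = 120)
  consec <- sqrt(rowSums((big[-1, ] - big[-4000, ])^2))
  expect_equal(mean(consec), 120, tolerance = 0.05)
})

test_that("cost is invariant under rigid motion and orthogonal factor mixing", {
  set.seed(25)
  inst <- rand_instance()
  f0 <- mbo_cost(inst$x, inst$prob_sqrt)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(mbo_cost(inst$x %*% q, inst$prob_sqrt), f0, tolerance = 1e-10)
  expect_equal(mbo_cost(inst$x + rep(c(3, -7, 2), each = 10), inst$prob_sqrt),
               f0, tolerance = 1e-6)
})

test_that("optimizer exactly recovers a complete noiseless 30-bead chain", {
  chain <- generate_chain(30, seed = 1)
  prob <- mbo_problem(edm_from_coords(chain$coords))
  res <- mbo_optimize(prob, mbo_config(seed = 7))
  expect_lt(res$final_cost, 1e-20)
  expect_lt(as.numeric(superimpose_rmsd(chain$coords, res$coords)), 1e-6)
  ## recovery is seed-independent and structures agree up to rigid motion
  coords <- list()
  for (s in 1:5) {
    r2 <- mbo_optimize(prob, mbo_config(seed = s))
    expect_lt(r2$final_cost, 1e-12)
    coords[[s]] <- r2$coords
  }
  for (s in 2:5)
    expect_lt(as.numeric(superimpose_rmsd(coords[[1]], coords[[s]])), 1e-4)
})

test_that("optimizer solves the 50%-missing noiseless completion problem", {
  chain <- generate_chain(30, seed = 2)
  truth <- edm_from_coords(chain$coords)
  corr <- corrupt_edm(truth, sigma = 0, missing_fraction = 0.5, seed = 9)
  res <- mbo_optimize(mbo_problem(corr), mbo_config(seed = 10))
  rec <- edm_from_coords(res$coords)
  expect_lt(spearman_dissimilarity(truth, rec), 1e-10)
})

test_that("trust-region iterates are monotone and runs are reproducible", {
  chain <- generate_chain(25, seed = 3)
  corr <- corrupt_edm(edm_from_coords(chain$coords), 0.3, 0.4, seed = 4)
  prob <- mbo_problem(corr)
  r1 <- mbo_optimize(prob, mbo_config(seed = 11, max_iterations = 150))
  r2 <- mbo_optimize(prob, mbo_config(seed = 11, max_iterations = 150))
  expect_identical(r1$coords, r2$coords)
  ## monotonicity: with a common seed the iterate sequence is shared, so the
  ## cost after k iterations is non-increasing in k
  costs <- vapply(c(3, 6, 12, 25, 50), function(k) {
    suppressWarnings(
      mbo_optimize(prob, mbo_config(seed = 11, max_iterations = k,
                                    warm_start = FALSE))$final_cost)
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-12 * pmax(costs[-length(costs)], 1)))
  ## non-convergence within a tiny cap warns but still returns a result
  expect_warning(
    r3 <- mbo_optimize(prob, mbo_config(seed = 11, max_iterations = 2,
                                        warm_start = FALSE)),
    "iteration cap")
  expect_equal(r3$converged_reason, "max_iterations")
  expect_true(all(is.finite(r3$coords)))
})
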