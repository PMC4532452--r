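test_that("generate_chain: fixed step, seeded, smoothness controls turning", {
  ch <- generate_chain(100, step_nm = 120, smoothness = 0.7, seed = 1)
  consec <- sqrt(rowSums((ch$coords[-1, ] - ch$coords[-100, ])^2))
  expect_equal(consec, rep(120, 99), tolerance = 1e-9)
  expect_gt(min(upper_vec(pairdist(ch$coords))), 0)
  expect_identical(generate_chain(100, seed = 1)$coords,
                   generate_chain(100, seed = 1)$coords)
  expect_false(identical(generate_chain(100, seed = 1)$coords,
                         generate_chain(100, seed = 2)$coords))
  ## smoothness -> 0 approaches an uncorrelated walk: mean turn cosine ~ 0
  ch0 <- generate_chain(3000, smoothness = 0, seed = 3)
  steps <- diff(ch0$coords)
  steps <- steps / sqrt(rowSums(steps^2))
  cosines <- rowSums(steps[-1, ] * steps[-nrow(steps), ])
  expect_lt(abs(mean(cosines)), 0.05)
  ## smooth chains turn less
  ch9 <- generate_chain(3000, smoothness = 0.9, seed = 3)
  s9 <- diff(ch9$coords); s9 <- s9 / sqrt(rowSums(s9^2))
  expect_gt(mean(rowSums(s9[-1, ] * s9[-nrow(s9), ])), 0.8)
})

test_that("corrupt_edm with sigma = 0 is a pure masking operation", {
  chain <- fixture_chain(20)
  truth <- edm_from_coords(chain)
  same <- corrupt_edm(truth, sigma = 0, missing_fraction = 0, seed = 1)
  expect_identical(same$values, truth$values)
  expect_true(all(same$mask))
  half <- corrupt_edm(truth, sigma = 0, missing_fraction = 0.5, seed = 2)
  expect_identical(half$values, truth$values)   # surviving entries untouched
  expect_equal(sum(!half$mask[upper.tri(half$mask)]), floor(0.5 * 190))
  expect_true(all(diag(half$mask)))
  expect_equal(half$mask, t(half$mask))
  ## reproducible
  expect_identical(corrupt_edm(truth, 0.5, 0.3, seed = 7),
                   corrupt_edm(truth, 0.5, 0.3, seed = 7))
})

test_that("corrupt_edm noise matches the folded-normal mean", {
  ## E|1 + sigma*eps| for eps ~ N(0,1): folded normal with mu=1, sd=sigma
  sigma <- 0.5
  mu <- 1
  expected <- sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
  chain <- fixture_chain(60)
  truth <- edm_from_coords(chain)
  noisy <- corrupt_edm(truth, sigma = sigma, missing_fraction = 0, seed = 5)
  ratio <- upper_vec(noisy$values) / upper_vec(truth$values)
  expect_equal(mean(ratio), expected, tolerance = 0.02)
  ## applied symmetrically, one draw per unordered pair
  expect_equal(noisy$values, t(noisy$values))
  expect_true(all(noisy$values >= 0))
  expect_equal(diag(noisy$values), rep(0, 60))
})

test_that("sample_contacts_from_structure thresholds like a loop oracle", {
  chain <- generate_chain(20, seed = 4)
  d <- pairdist(chain$coords)
  cmap <- sample_contacts_from_structure(chain, d_c = 250)
  for (i in 1:20) for (j in 1:20) {
    expected <- if (i != j && d[i, j] < 250) 1 else 0
    expect_equal(cmap$matrix[i, j], expected)
  }
  expect_equal(n_contacts(sample_contacts_from_structure(chain,
                 d_c = 0.5 * min(upper_vec(d)))), 0)
  full <- sample_contacts_from_structure(chain, d_c = 2 * max(d))
  expect_equal(n_contacts(full), choose(20, 2))
  sub <- sample_contacts_from_structure(chain, d_c = 250,
                                        target_contacts = 10, seed = 6)
  expect_equal(n_contacts(sub), 10)
})

test_that("noise_sparsity_grid reconstructs the noiseless complete case exactly", {
  chain <- generate_chain(40, seed = 8)
  grid <- noise_sparsity_grid(chain, sigmas = 0, missing = 0,
                              methods = c("mbo", "cmds"), seeds = 1,
                              cfg = mbo_config())
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$one_minus_rho < 1e-12))
  expect_true(all(c("n", "sigma", "missing_fraction", "method", "seed",
                    "one_minus_rho", "rmsd_nm") %in% names(grid)))
})

test_that("reconstruction_limit_curve finds sane fractions", {
  ## full observation always meets the criterion; the returned fraction for a
  ## larger system is no larger than for a smaller one
  cfg <- mbo_config(max_iterations = 150)
  curve <- reconstruction_limit_curve(c(30, 70), criterion = "partial",
                                      seeds = 1:2, cfg = cfg,
                                      fraction_tol = 0.1)
  expect_equal(nrow(curve), 2)
  expect_true(all(curve$min_observed_fraction > 0 &
                  curve$min_observed_fraction <= 1))
  expect_lte(curve$min_observed_fraction[2], curve$min_observed_fraction[1])
})
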