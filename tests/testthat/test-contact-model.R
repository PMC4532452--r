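test_that("bin_contacts bins, deduplicates and filters correctly", {
  rec <- data.frame(
    chrom_a = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    pos_a   = c(10,    20,     60,     120,    170,    225,    5),
    chrom_b = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    pos_b   = c(110,   115,    170,    260,    255,    235,    80))
  ## bin size 50, length 300 -> 6 bins; pairs: (1,3)x2 dup, (2,4), (3,6)+(4,6), (5,5) self
  expect_message(
    cmap <- bin_contacts(rec, "chr1", bin_size = 50, chrom_length = 300),
    "filtered 1/7")
  expect_equal(nrow(cmap$matrix), 6)
  expect_equal(n_contacts(cmap), 4)
  expect_equal(cmap$matrix[1, 3], 1)   # duplicates collapsed
  expect_equal(cmap$matrix[5, 5], 0)   # same-bin record leaves diagonal 0
  expect_equal(cmap$matrix, t(cmap$matrix))
  bad <- data.frame(chrom_a = "chr1", pos_a = 10, chrom_b = "chr1", pos_b = 300)
  expect_error(bin_contacts(bad, "chr1", bin_size = 50, chrom_length = 300),
               "beyond")
})

test_that("build_target_distances applies the contact/backbone rules", {
  m <- matrix(0, 3, 3); m[1, 3] <- m[3, 1] <- 1
  td <- build_target_distances(contact_map(m), d_c = 60, d_n = 120)
  expect_equal(td$distances[1, 2], 120)
  expect_equal(td$distances[2, 3], 120)
  expect_equal(td$distances[1, 3], 60)
  expect_true(all(td$mask))
  ## a contact between neighbors wins over the backbone distance
  m2 <- matrix(0, 3, 3); m2[1, 2] <- m2[2, 1] <- 1
  td2 <- build_target_distances(contact_map(m2), d_c = 60, d_n = 120)
  expect_equal(td2$distances[1, 2], 60)
  ## empty map: only the n-1 backbone entries observed
  td3 <- build_target_distances(contact_map(matrix(0, 4, 4)))
  expect_equal(sum(td3$mask[upper.tri(td3$mask)]), 3)
  expect_equal(unique(td3$distances[td3$mask & upper.tri(td3$mask)]), 120)
})

test_that("shortest_path_complete fills distances and hop counts correctly", {
  td <- build_target_distances(contact_map(matrix(0, 3, 3)))
  tdc <- shortest_path_complete(td)
  expect_equal(tdc$distances[1, 3], 240)
  expect_equal(tdc$hop_counts[1, 3], 2)
  m <- matrix(0, 3, 3); m[1, 3] <- m[3, 1] <- 1
  tdc2 <- shortest_path_complete(build_target_distances(contact_map(m)))
  expect_equal(tdc2$distances[1, 3], 60)
  expect_equal(tdc2$hop_counts[1, 3], 1)
  ## completion is idempotent
  expect_identical(shortest_path_complete(tdc2), tdc2)
})

test_that("completion matches the exhaustive simple-path oracle on small graphs", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 6
    m <- matrix(0, n, n)
    idx <- which(upper.tri(m) & abs(row(m) - col(m)) > 1)
    on <- sample(idx, 2)
    m[on] <- 1
    m <- m + t(m)
    td <- build_target_distances(contact_map(m))
    tdc <- shortest_path_complete(td)
    ref <- bruteforce_paths(td$distances, td$mask)
    expect_equal(tdc$distances, ref$dist, tolerance = 1e-12)
    expect_equal(tdc$hop_counts, ref$hops)
  }
})

test_that("completion agrees with igraph and respects the backbone bound", {
  skip_if_not_installed("igraph")
  cmap <- rand_cmap(40, 30, seed = 3)
  td <- build_target_distances(cmap)
  tdc <- shortest_path_complete(td)
  edge <- td$mask & row(td$mask) != col(td$mask)
  g <- igraph::graph_from_adjacency_matrix(edge * td$distances,
                                           mode = "undirected",
                                           weighted = TRUE)
  expect_lt(max(abs(tdc$distances - igraph::distances(g))), 1e-9)
  n <- nrow(tdc$distances)
  bound <- abs(row(tdc$distances) - col(tdc$distances)) * td$d_n
  expect_true(all(tdc$distances <= bound + 1e-9))
})

test_that("disconnected components are flagged, not errors", {
  ## two beads with no backbone between them: drop the backbone by building
  ## the target distances by hand
  d <- matrix(0, 4, 4)
  mask <- matrix(FALSE, 4, 4); diag(mask) <- TRUE
  d[1, 2] <- d[2, 1] <- 60; mask[1, 2] <- mask[2, 1] <- TRUE
  d[3, 4] <- d[4, 3] <- 60; mask[3, 4] <- mask[4, 3] <- TRUE
  hops <- matrix(NA_real_, 4, 4); diag(hops) <- 0
  hops[mask & row(mask) != col(mask)] <- 1
  td <- target_distances(d, mask, hops)
  expect_message(tdc <- shortest_path_complete(td), "disconnected")
  expect_false(tdc$mask[1, 3])
  expect_equal(tdc$distances[1, 3], Inf)
  h <- build_weights(tdc, q = 1)
  expect_equal(h$values[1, 3], 0)
})

test_that("build_weights implements H_ij = n_ij^-q with the right edge cases", {
  cmap <- rand_cmap(12, 6, seed = 5)
  tdc <- shortest_path_complete(build_target_distances(cmap))
  h1 <- build_weights(tdc, q = 1)
  h2 <- build_weights(tdc, q = 2)
  h0 <- build_weights(tdc, q = 0)
  hopu <- tdc$hop_counts[upper.tri(tdc$hop_counts)]
  expect_equal(h1$values[upper.tri(h1$values)], hopu^-1)
  expect_equal(h2$values[upper.tri(h2$values)], hopu^-2)
  expect_true(all(h0$values[upper.tri(h0$values)] == 1))
  expect_true(all(diag(h1$values) == 0))
  expect_true(all(h1$values[tdc$hop_counts == 1] == 1))
  ## weights in (0,1], monotone non-increasing in hop count
  expect_true(all(h2$values[upper.tri(h2$values)] > 0))
  expect_true(all(h2$values[upper.tri(h2$values)] <= 1))
  ord <- order(hopu)
  expect_true(all(diff(h2$values[upper.tri(h2$values)][ord]) <= 1e-12))
  expect_error(build_weights(tdc, q = -1), "non-negative")
  expect_error(build_weights(build_target_distances(cmap), q = 1),
               "shortest_path_complete")
})
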