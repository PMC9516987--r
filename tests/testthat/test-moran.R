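test_that("a linear gradient on a 4-node path gives I = 1/3", {
  expect_equal(moran_i(c(1, 2, 3, 4), path_adjacency(4)), 1 / 3)
})

test_that("two mutually adjacent opposite values give I = -1", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(moran_i(c(1, -1), W), -1)
})

test_that("the vectorised statistic equals a brute-force double loop", {
  geo <- simulate_geography(21, seed = 1)
  set.seed(2)
  x <- rnorm(21)
  expect_equal(moran_i(x, geo$adjacency), moran_bruteforce(x, geo$adjacency),
               tolerance = 1e-12)
  # exhaustively at small n, random graphs, binary and row-standardized
  for (n in 3:8) {
    W <- matrix(rbinom(n * n, 1, 0.5), n, n)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- 0
    if (sum(W) == 0) W[1, 2] <- W[2, 1] <- 1
    x <- rnorm(n)
    expect_equal(moran_i(x, W), moran_bruteforce(x, W), tolerance = 1e-12)
    rs <- W / ifelse(rowSums(W) > 0, rowSums(W), 1)
    expect_equal(moran_i(x, W, row_standardize = TRUE),
                 moran_bruteforce(x, rs), tolerance = 1e-12)
  }
})

test_that("constant surfaces are rejected", {
  expect_error(moran_i(rep(2, 5), path_adjacency(5)), "constant")
})

test_that("the permutation mean of I is -1/(n-1)", {
  set.seed(3)
  W <- simulate_geography(12, seed = 3)$adjacency
  x <- rnorm(12)
  perms <- replicate(4000, moran_i(x[sample.int(12)], W))
  expect_equal(mean(perms), -1 / 11, tolerance = 0.05)
})

test_that("permutation p-values are uniform under the null", {
  W <- simulate_geography(21, seed = 4)$adjacency
  set.seed(5)
  pvals <- replicate(200, {
    moran_test(rnorm(21), W, n_permutations = 199)$p_value
  })
  # p-values live on the lattice k/200; smearing each within its bin makes
  # them continuous-uniform under the null, so KS applies without ties
  smeared <- pvals - runif(200, 0, 1 / 200)
  expect_gt(stats::ks.test(smeared, "punif")$p.value, 0.01)
})

test_that("a spatially smooth surface is detected", {
  geo <- simulate_geography(21, layout = "grid", seed = 6)
  centr <- geo$polygons |>
    dplyr::group_by(ward_id) |>
    dplyr::summarise(v = mean(x[-1]) + mean(y[-1]))
  res <- moran_test(centr$v, geo$adjacency, n_permutations = 999, seed = 7)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$I, 0)
})

test_that("seeded permutation tests are reproducible", {
  W <- simulate_geography(10, seed = 8)$adjacency
  set.seed(9)
  x <- rnorm(10)
  r1 <- moran_test(x, W, n_permutations = 499, seed = 10)
  r2 <- moran_test(x, W, n_permutations = 499, seed = 10)
  expect_identical(r1$p_value, r2$p_value)
})
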