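test_that("an observation below every replicate gets an extreme-low residual", {
  sims <- matrix(10:59, nrow = 1)
  r <- pit_residuals(0, sims, seed = 1)
  expect_lt(r, 1 / (ncol(sims) + 1))
  r_hi <- pit_residuals(100, sims, seed = 1)
  expect_gt(r_hi, ncol(sims) / (ncol(sims) + 1))
})

test_that("continuous-model residuals recover the analytic CDF transform", {
  set.seed(2)
  n <- 200; M <- 4000
  obs <- rnorm(n)
  sims <- matrix(rnorm(n * M), n, M)
  r <- pit_residuals(obs, sims, seed = 3)
  expect_lt(max(abs(r - pnorm(obs))), 4 / sqrt(M) + 0.02)
})

test_that("residuals from the generating model are uniform", {
  passes <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 300
    lambda <- exp(rnorm(n, log(4), 0.3))
    obs <- rzinb(n, lambda, p = 0.15, r = 2)
    sims <- sapply(1:200, function(s) rzinb(n, lambda, p = 0.15, r = 2))
    res <- pit_residuals(obs, sims, seed = seed)
    if (stats::ks.test(res, "punif")$p.value > 0.01) passes <- passes + 1
  }
  expect_gte(passes, 9)
})

test_that("residuals are equivariant under observation relabelling", {
  set.seed(4)
  n <- 50
  obs <- rnorm(n)
  sims <- matrix(rnorm(n * 500), n, 500)
  r <- pit_residuals(obs, sims, seed = NULL)
  perm <- sample.int(n)
  r_perm <- pit_residuals(obs[perm], sims[perm, ], seed = NULL)
  # continuous outcomes: no ties, so the residuals are rank-deterministic
  expect_equal(round(r_perm, 10), round(r[perm], 10), tolerance = 1e-2)
})

test_that("ward aggregation in the Moran screen equals brute-force group means", {
  geo <- simulate_geography(6, seed = 5)
  set.seed(6)
  ward_ids <- sample(1:6, 120, replace = TRUE)
  res <- runif(120)
  scr <- residual_moran_screen(res, ward_ids, geo$adjacency,
                               n_permutations = 199, seed = 7)
  means <- attr(scr, "ward_means")
  for (j in 1:6) expect_equal(means[j], mean(res[ward_ids == j]))
  expect_true(scr$spatial_structure %in% c("structured", "unstructured"))
})

test_that("null residual screens are rarely significant and injected signal is found", {
  geo <- simulate_geography(21, layout = "grid", seed = 8)
  W <- geo$adjacency
  set.seed(9)
  sig <- 0
  for (b in 1:100) {
    scr <- residual_moran_screen(runif(21 * 20), rep(1:21, 20), W,
                                 n_permutations = 199)
    if (scr$p_value <= 0.05) sig <- sig + 1
  }
  expect_lte(sig, 10) # ~5% nominal
  # neighbour-correlated signal of ~1 SD on the ward means
  centr <- geo$polygons |>
    dplyr::group_by(ward_id) |>
    dplyr::summarise(v = mean(x[-1]) + mean(y[-1]))
  shift <- scale(centr$v)[, 1] * 0.1
  res <- runif(21 * 40) + rep(shift, 40)
  scr <- residual_moran_screen(res, rep(1:21, 40), W,
                               n_permutations = 999, seed = 10)
  expect_lte(scr$p_value, 0.05)
  expect_equal(scr$spatial_structure, "structured")
})

test_that("a degenerate posterior has zero effective parameters", {
  dic <- compute_dic(rep(123.4, 200), 123.4)
  expect_equal(dic$p_D, 0)
  expect_equal(dic$DIC, 123.4)
  expect_warning(compute_dic(rep(1, 50), 1), "100")
})

test_that("DIC matches the closed form in the conjugate Gaussian model", {
  # y_i ~ N(mu, s2) with known s2 and conjugate prior mu ~ N(m0, t0)
  set.seed(11)
  n <- 40; s2 <- 2; m0 <- 0; t0 <- 100
  y <- rnorm(n, 1, sqrt(s2))
  tn <- 1 / (1 / t0 + n / s2)
  mn <- tn * (m0 / t0 + sum(y) / s2)
  S <- 40000
  mu_draws <- rnorm(S, mn, sqrt(tn))
  dev <- vapply(mu_draws, function(m) -2 * sum(dnorm(y, m, sqrt(s2), log = TRUE)),
                numeric(1))
  dic <- compute_dic(dev, -2 * sum(dnorm(y, mean(mu_draws), sqrt(s2), log = TRUE)))
  # analytic: pD = n * tn / s2; DIC = D(mean) + 2 pD
  expect_equal(dic$p_D, n * tn / s2, tolerance = 0.05)
  expect_equal(dic$DIC, -2 * sum(dnorm(y, mn, sqrt(s2), log = TRUE)) + 2 * n * tn / s2,
               tolerance = 0.01)
})

test_that("Poisson log-density agrees with a hand-rolled log-pmf", {
  set.seed(12)
  y <- rpois(100, 5)
  mu <- runif(100, 0.1, 20)
  expect_equal(dpois(y, mu, log = TRUE),
               y * log(mu) - mu - lgamma(y + 1), tolerance = 1e-10)
})
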