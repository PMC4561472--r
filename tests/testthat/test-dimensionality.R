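test_that("Cronbach's alpha matches its closed forms", {
  # duplicated items: perfect internal consistency
  set.seed(200)
  x <- sample(0:4, 300, replace = TRUE)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # two standardized items at r = 0.5: Spearman-Brown gives 2r/(1+r)
  z <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2),
                     empirical = TRUE)
  expect_equal(cronbach_alpha(z), 2 * 0.5 / 1.5, tolerance = 1e-10)
  # variance formula equals the standardized form on equicorrelated data
  k <- 5; rbar <- 0.4
  S <- matrix(rbar, k, k); diag(S) <- 1
  ze <- MASS::mvrnorm(400, rep(0, k), S, empirical = TRUE)
  expect_equal(cronbach_alpha(ze), k * rbar / (1 + (k - 1) * rbar),
               tolerance = 1e-3)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero variance")
})

test_that("Loevinger's H spans perfect scalability to independence", {
  # perfect Guttman ordering: every item a monotone step of one order
  set.seed(210)
  u <- runif(400)
  g <- t(sapply(u, function(p) pmin(pmax(floor(p * 13) - c(0, 2, 4, 6, 8), 0), 4)))
  colnames(g) <- paste0("item", 1:5)
  expect_equal(loevinger_h(g)$H, 1)
  # independent items: H near 0
  ind <- sapply(1:5, function(j) sample(0:4, 1e5, replace = TRUE))
  h <- loevinger_h(ind)
  expect_lt(abs(h$H), 0.02)
  expect_true(all(abs(h$H_i) < 0.05))
})

test_that("the bivariate normal CDF matches base-R integration", {
  for (rho in c(-0.9, -0.5, 0, 0.3, 0.7, 0.95)) {
    for (hk in list(c(0.5, -0.3), c(-1.2, 1.7), c(2, 2))) {
      expect_equal(fastvalid:::pbvnorm(hk[1], hk[2], rho),
                   pbvnorm_oracle(hk[1], hk[2], rho), tolerance = 1e-7)
    }
  }
})

test_that("polychoric correlations recover the generating latent rho", {
  set.seed(220)
  for (rho in c(0, 0.6)) {
    z <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    X <- cbind(a = discretize5(z[, 1]), b = discretize5(z[, 2]))
    R <- polychoric_matrix(X)
    expect_equal(R[1, 2], rho, tolerance = 0.05)
    # coarsening attenuates Pearson, not polychoric
    expect_gte(abs(R[1, 2]) + 1e-9, abs(cor(X[, 1], X[, 2])))
  }
})

test_that("parallel analysis brackets chance eigenvalues and is seeded", {
  set.seed(230)
  ind <- sapply(1:6, function(j) sample(0:4, 4000, replace = TRUE))
  pa <- parallel_analysis(ind, n_reps = 20, seed = 5, type = "pearson")
  expect_equal(mean(pa$mean), 1, tolerance = 1e-6)  # trace preserved
  expect_true(all(pa$mean > 0.9 & pa$mean < 1.1))
  pa2 <- parallel_analysis(ind, n_reps = 20, seed = 5, type = "pearson")
  expect_identical(pa$eigenvalues, pa2$eigenvalues)
  expect_error(parallel_analysis(ind, n_reps = 5), "at least 20")
})

test_that("the three-criterion verdict reproduces known configurations", {
  # a large-sample configuration: dominant first component, second just
  # under 1, chance band around 1; variance share 65.7% sits below the
  # strict 2/3 bar, so criterion b fails while a and c pass
  obs <- c(5.91, 0.85, 0.50, 0.46, 0.40, 0.32, 0.27, 0.15, 0.15)
  sim <- rep(1, 9)
  v <- unidimensionality_verdict(obs, sim, rule = "all")
  expect_true(v$criterion_a)
  expect_false(v$criterion_b)
  expect_equal(v$variance_share, 5.91 / sum(obs), tolerance = 1e-12)
  expect_true(v$criterion_c)
  expect_false(v$unidimensional)
  expect_true(unidimensionality_verdict(obs, sim,
                                        rule = "majority")$unidimensional)
  # identity correlation: no eigenvalue strictly above 1
  v0 <- unidimensionality_verdict(rep(1, 9), rep(1, 9))
  expect_false(v0$criterion_a)
  expect_false(v0$unidimensional)
})

test_that("one-factor data passes and two-factor data fails the criteria", {
  set.seed(240)
  n <- 3000
  f <- rnorm(n)
  one <- sapply(1:6, function(j) discretize5(0.8 * f + sqrt(1 - 0.64) * rnorm(n)))
  d1 <- assess_dimensionality(one, n_reps = 20, seed = 6)
  expect_true(d1$criterion_a && d1$criterion_b && d1$criterion_c)
  expect_true(d1$unidimensional)

  f2 <- rnorm(n)
  two <- cbind(
    sapply(1:3, function(j) discretize5(0.8 * f + 0.6 * rnorm(n))),
    sapply(1:3, function(j) discretize5(0.8 * f2 + 0.6 * rnorm(n))))
  d2 <- assess_dimensionality(two, n_reps = 20, seed = 7)
  expect_false(d2$criterion_a && d2$criterion_c)
  expect_false(d2$unidimensional)
})
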