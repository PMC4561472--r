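test_that("latent draws follow the mixture spec and are reproducible", {
  sp <- latent_spec(p_floor = 1, floor_mean = -6, floor_sd = 0)
  expect_equal(generate_latent(sp, 50, seed = 1), rep(-6, 50))

  th <- generate_latent(latent_spec(p_floor = 0), 1e5, seed = 2)
  expect_lt(abs(mean(th)), 0.02)

  a <- generate_latent(latent_spec(p_floor = 0.3), 1000, seed = 3)
  b <- generate_latent(latent_spec(p_floor = 0.3), 1000, seed = 3)
  expect_identical(a, b)
})

test_that("the observed all-never share matches the quadrature oracle", {
  steps <- make_steps(J = 5, seed = 10, mean = 1)
  sp <- latent_spec(p_floor = 0.47, floor_mean = -6, floor_sd = 0.25,
                    mu = 0.5, sigma = 1)
  expected <- all_never_oracle(sp, steps)
  th <- generate_latent(sp, 4e4, seed = 4)
  rm_ <- generate_responses(th, steps, seed = 5)
  observed <- summarize_responses(rm_)$floor_proportion
  mc_se <- sqrt(expected * (1 - expected) / 4e4)
  expect_lt(abs(observed - expected), 4 * mc_se)
})

test_that("responses follow the PCM category distribution", {
  # uniform case: theta = 0, all steps 0
  rm_ <- generate_responses(rep(0, 1e5), list(c(0, 0, 0, 0)), seed = 6)
  freq <- tabulate(unclass(rm_)[, 1] + 1L, 5) / 1e5
  expect_equal(freq, rep(0.2, 5), tolerance = 0.01)

  # limit: theta -> -Inf pins category 0
  rm_lo <- generate_responses(rep(-30, 500), list(c(0, 0, 0, 0)), seed = 7)
  expect_true(all(unclass(rm_lo) == 0L))

  # direct evaluation of the kernel at theta = 1, steps (-1, 0.5)
  rm_k <- generate_responses(rep(1, 1e5), list(c(-1, 0.5)), seed = 8)
  freq_k <- tabulate(unclass(rm_k)[, 1] + 1L, 3) / 1e5
  expect_equal(freq_k, c(0.0486, 0.3592, 0.5922), tolerance = 0.006)

  # bit-reproducibility under a fixed seed
  expect_identical(
    unclass(generate_responses(rnorm(100), make_steps(3), seed = 9)),
    unclass(generate_responses(rnorm(100), make_steps(3), seed = 9)))
})

test_that("DIF injection shifts only the target item for the focal group", {
  steps <- make_steps(J = 4, seed = 11)
  base <- synthetic_config(4000, steps, latent = latent_spec(),
                           groups = c(g = 0.5), seed = 21)
  with_dif <- synthetic_config(4000, steps, latent = latent_spec(),
                               dif_spec = list(item = "item2", group = "g",
                                               shift = 0.5),
                               groups = c(g = 0.5), seed = 21)
  s0 <- generate_dif_responses(base)
  s1 <- generate_dif_responses(with_dif)

  # locality: non-target items identical draw-for-draw at the same seed
  expect_identical(unclass(s0$responses)[, c("item1", "item3", "item4")],
                   unclass(s1$responses)[, c("item1", "item3", "item4")])

  # a +0.5 logit shift lowers the focal group's expected item score
  focal <- s1$covariates$g == 1
  th <- s1$theta
  exp_score <- function(d, th) {
    p <- pcm_probs(th, d)
    as.numeric(p %*% (seq_len(ncol(p)) - 1))
  }
  oracle_gap <- mean(exp_score(steps$item2 + 0.5, th[focal])) -
    mean(exp_score(steps$item2, th[focal]))
  observed_gap <- mean(unclass(s1$responses)[focal, "item2"]) -
    mean(unclass(s0$responses)[focal, "item2"])
  expect_lt(oracle_gap, 0)
  expect_equal(observed_gap, oracle_gap, tolerance = 0.05)

  # null DIF: shift 0 leaves the two groups' distributions equal in law
  null_dif <- synthetic_config(8000, steps, latent = latent_spec(),
                               dif_spec = list(item = "item2", group = "g",
                                               shift = 0),
                               groups = c(g = 0.5), seed = 22)
  sn <- generate_dif_responses(null_dif)
  tab <- table(sn$covariates$g, unclass(sn$responses)[, "item2"])
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("copula covariates hit their target rank correlations", {
  th <- generate_latent(latent_spec(p_floor = 0.3), 1e5, seed = 30)
  cv <- generate_covariates(th, validators = c(a = -0.6, b = -0.2, z = 0),
                            groups = c(g = 0.4), seed = 31)
  expect_equal(cor(th, cv$a, method = "spearman"), -0.6, tolerance = 0.02)
  expect_equal(cor(th, cv$b, method = "spearman"), -0.2, tolerance = 0.02)
  expect_lt(abs(cor(th, cv$z, method = "spearman")), 0.02)
  expect_lt(abs(cor(th, cv$g)), 0.02)      # exogenous grouping
  expect_error(generate_covariates(th, validators = c(a = -1.2)),
               "rank correlations")
})
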