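test_that("the likelihood-ratio statistic follows from the nested fits", {
  set.seed(400)
  steps <- make_steps(J = 5, seed = 401)
  th <- rnorm(1500)
  rm_ <- generate_responses(th, steps, seed = 402)
  tot <- total_score(rm_)
  g <- rbinom(1500, 1, 0.5)
  res <- fit_nested_dif_models(unclass(rm_)[, 2], tot, g)
  expect_s3_class(res, "dif_result")
  expect_equal(res$lr, -2 * (res$ll_model1 - res$ll_model2))
  expect_gte(res$lr, -1e-8)              # nesting
  expect_gte(res$ll_model2, res$ll_model1 - 1e-8)
  # two groups with identical data: no improvement possible
  x <- unclass(rm_)[, 1]
  same <- fit_nested_dif_models(c(x, x), c(tot, tot),
                                rep(0:1, each = 1500),
                                family = "generalized")
  expect_equal(same$lr, 0, tolerance = 1e-6)
  expect_equal(same$effect_size, 0, tolerance = 1e-8)
})

test_that("proportional odds testing routes families sensibly", {
  # degenerate single split: nothing to compare
  po1 <- test_proportional_odds(rep(0:1, 100), rnorm(200), rbinom(200, 1, 0.5))
  expect_equal(po1$p_value, 1)
  # split-specific slopes constructed -> decisive rejection
  set.seed(410)
  n <- 4000
  t_ <- rnorm(n); g <- rbinom(n, 1, 0.5)
  # category from two mechanisms with very different slopes
  x <- ifelse(plogis(2.5 * t_) > runif(n),
              2L + (plogis(-1 + 0.1 * t_) < runif(n)) * 1L,
              (plogis(1.5 + 2.4 * t_) < runif(n)) * 1L)
  po2 <- test_proportional_odds(x, t_, g)
  expect_lt(po2$p_value, 0.001)
  # proportional-odds data keeps the proportional family under auto routing
  zeta <- c(-1, 0, 1, 2)
  eta <- 1.2 * rnorm(n)
  cp <- sapply(zeta, function(z) plogis(z - eta))
  xp <- rowSums(runif(n) > cp)
  res <- fit_nested_dif_models(xp, eta + rnorm(n, 0, 0.5), g)
  expect_equal(res$family, "proportional")
  expect_equal(res$df, 2L)
})

test_that("verdicts separate statistical from practical significance", {
  mk <- function(p, eff) list(p_value = p, effect_size = eff)
  expect_equal(dif_verdict(mk(1e-4, 0.0018)), "statistical-only")
  expect_equal(dif_verdict(mk(0.12, 0.0)), "none")
  expect_equal(dif_verdict(mk(0.01, 0.20)), "practical")
  # boundary: p exactly at alpha is not significant
  expect_equal(dif_verdict(mk(0.05, 0.5)), "none")
})

test_that("dif_analysis produces one classified row per item and grouping", {
  steps <- make_steps(J = 4, seed = 420)
  cfg <- synthetic_config(2500, steps, latent = latent_spec(),
                          dif_spec = list(item = "item2", group = "g",
                                          shift = 0.8),
                          groups = c(g = 0.5, h = 0.3), seed = 21)
  sim <- generate_dif_responses(cfg)
  tab <- dif_analysis(sim$responses, sim$covariates, groupings = c("g", "h"))
  expect_equal(nrow(tab), 8L)
  expect_setequal(unique(tab$grouping), c("g", "h"))
  # the injected 0.8-logit DIF on item2 x g is detected
  hit <- tab[tab$item == "item2" & tab$grouping == "g", ]
  expect_lt(hit$p_value, 0.01)
  # effect sizes of trait-exogenous groupings stay far below practical cutoff
  expect_true(all(tab$effect_size_pct < 13))
  expect_true(all(tab$verdict != "practical"))
})
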