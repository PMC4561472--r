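test_that("the PCM kernel is a proper, stable probability model", {
  # hand-evaluated: numerators 1, e^2, e^2.5 at theta = 1, steps (-1, 0.5)
  expect_equal(round(as.numeric(pcm_probs(1, c(-1, 0.5))), 4),
               c(0.0486, 0.3592, 0.5922))
  # symmetry: all steps 0 at theta 0 gives the uniform distribution
  expect_equal(as.numeric(pcm_probs(0, c(0, 0, 0, 0))), rep(0.2, 5))
  # dichotomous reduction to the Rasch model
  th <- seq(-3, 3, 0.5)
  expect_equal(pcm_probs(th, 1.2)[, 2], plogis(th - 1.2))
  # normalization and positivity far into the tails
  set.seed(1)
  for (r in 1:20) {
    d <- rnorm(sample(2:6, 1), 0, 2)
    p <- pcm_probs(seq(-50, 50, length.out = 41), d)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 41), tolerance = 1e-12)
  }
})

test_that("fit_pcm recovers generating steps and ascends monotonically", {
  steps <- make_steps(seed = 101)
  set.seed(102)
  th <- rnorm(2000)
  rm_ <- generate_responses(th, steps, seed = 103)
  fit <- fit_pcm(rm_)
  expect_true(fit$converged)
  err <- unlist(fit$delta) - unlist(steps)
  expect_lt(sqrt(mean(err^2)), 0.15)
  # monotone EM ascent
  expect_true(all(diff(fit$ll_trace) > -1e-7 * abs(fit$loglik)))
  # determinism: identical input, identical fit
  fit2 <- fit_pcm(rm_)
  expect_identical(fit2$loglik, fit$loglik)
  expect_identical(fit2$delta, fit$delta)
})

test_that("dichotomized fits agree with an independent Rasch MML oracle", {
  set.seed(110)
  delta_true <- c(-1, -0.3, 0.4, 1.1)
  th <- rnorm(1500)
  steps <- lapply(delta_true, function(d) d)
  rm_ <- generate_responses(th, steps, seed = 111)
  fit <- fit_pcm(rm_, n_nodes = 201, theta_range = c(-8, 8))
  oracle <- rasch_mml_oracle(unclass(rm_))
  expect_equal(unname(unlist(fit$delta)), oracle$delta, tolerance = 0.02)
  expect_equal(fit$sigma, oracle$sigma, tolerance = 0.02)
})

test_that("EAP scores are sufficient in the total and match fine-grid integration", {
  steps <- make_steps(J = 5, seed = 120)
  set.seed(121)
  rm_ <- generate_responses(rnorm(800), steps, seed = 122)
  fit <- fit_pcm(rm_)
  ps <- person_scores(fit, rm_)
  # equal totals (complete data) -> equal EAP
  spread <- tapply(ps$eap, ps$total, function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
  # all-zero pattern has the minimum EAP
  X <- unclass(rm_)
  zero_rows <- rowSums(X) == 0
  if (any(zero_rows))
    expect_equal(min(ps$eap), unique(round(ps$eap[zero_rows], 12)))
  # EAP vs fine-grid numerical integration on 5 random patterns
  set.seed(123)
  for (i in sample(nrow(X), 5)) {
    expect_equal(ps$eap[i], eap_oracle(X[i, ], fit$delta, fit$sigma),
                 tolerance = 1e-3)
  }
})

test_that("fit statistics are near 1 under the model and flag departures", {
  steps <- make_steps(J = 6, seed = 130)
  set.seed(131)
  rm_ <- generate_responses(rnorm(3000), steps, seed = 132)
  fit <- fit_pcm(rm_)
  fs <- item_fit_statistics(fit, rm_)
  # per-item aggregate Mnsq is conservative (shrunken below 1) when the
  # trait is estimated by EAP from few items; it must still sit well
  # inside the conventional acceptance window
  expect_true(all(fs$items$infit > 0.7 & fs$items$infit < 1.3))
  expect_true(all(fs$categories$infit > 0))
  # window flags follow the stated intervals
  expect_equal(fs$categories$in_acceptable,
               fs$categories$infit >= 0.7 & fs$categories$infit <= 1.3)
  expect_equal(fs$categories$in_recommended,
               fs$categories$infit >= 0.8 & fs$categories$infit <= 1.2)
  # a deterministic, perfectly conforming response carries zero residual:
  # z = (x - E)/sqrt(W) vanishes when E equals the observed x
  p <- pcm_probs(0, c(0, 0))
  E <- sum((0:2) * p)
  expect_equal(E, 1)                    # symmetric item at theta 0
  expect_equal((1 - E)^2, 0)            # outfit contribution is exactly 0
})

test_that("Thurstonian thresholds are the 50% cumulative crossings", {
  # dichotomous reduction: threshold equals the step
  expect_equal(thurstonian_thresholds(c(1.2)), 1.2, tolerance = 1e-6)
  # symmetric steps give antisymmetric thresholds
  g <- thurstonian_thresholds(c(-0.8, 0.8))
  expect_equal(g[1], -g[2], tolerance = 1e-6)
  # defining identity and strict ordering for random items
  set.seed(140)
  for (r in 1:10) {
    d <- rnorm(4, 0.5, 1.5)
    g <- thurstonian_thresholds(d)
    expect_true(all(diff(g) > 0))
    for (k in seq_along(g)) {
      cum <- sum(pcm_probs(g[k], d)[1, (k + 1):5])
      expect_equal(cum, 0.5, tolerance = 1e-5)
    }
  }
})
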