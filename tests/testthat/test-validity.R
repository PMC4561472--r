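test_that("total scores span the floor and ceiling and honour coding", {
  sc <- fast_scale()
  raw <- as_response_matrix(
    matrix(c(4, 0, 0, 0, 0, 0, 0, 0, 0,   # raw: square meals "mostly"
             0, 4, 4, 4, 4, 4, 4, 4, 4),  # raw: worst on everything
           nrow = 2, byrow = TRUE, dimnames = list(NULL, sc$items$id)), sc)
  coded <- apply_coding(raw, sc)
  expect_equal(total_score(coded), c(0, 36))
  # missing-data policies
  X <- unclass(coded); X[1, 3] <- NA
  m <- as_response_matrix(X, coded = TRUE)
  expect_true(is.na(total_score(m)[1]))
  expect_equal(total_score(m, policy = "prorate")[1], 0)
})

test_that("binning follows empirical quartiles and fixed BMI cutoffs", {
  expect_equal(as.character(quartile_bins(1:8)),
               rep(paste0("Q", 1:4), each = 2))
  expect_error(quartile_bins(rep(3, 10)), "distinct")
  # ties at a boundary go to the lower bin, deterministically
  v <- c(1, 2, 2, 2, 3, 4, 5, 6)
  b <- quartile_bins(v)
  expect_true(all(b[v == 2] == b[v == 2][1]))
  expect_equal(as.character(bmi_bins(c(17.0, 18.5, 22, 25.0, 26.1))),
               c("undernutrition", "normal", "normal", "overweight",
                 "overweight"))
})

test_that("the trend test tracks monotone association and its null", {
  set.seed(500)
  tot <- sample(0:36, 2000, replace = TRUE)
  # perfect inverse monotone association
  tt <- trend_test(tot, -tot)
  expect_lt(tt$z, -20)
  expect_lt(tt$p_value, 1e-10)
  expect_equal(tt$direction, "negative")
  # the z statistic matches a permutation-null standardization
  v <- -tot + rnorm(2000, 0, 10)
  tt2 <- trend_test(tot, v)
  L_obs <- sum(tot * rank(v))
  set.seed(501)
  L_perm <- replicate(400, sum(tot * sample(rank(v))))
  z_perm <- (L_obs - mean(L_perm)) / sd(L_perm)
  expect_equal(tt2$z, z_perm, tolerance = abs(0.05 * z_perm))
  # spearman variant agrees in sign and scale
  tt3 <- trend_test(tot, v, method = "spearman")
  expect_equal(tt3$z, tt2$z, tolerance = abs(0.1 * tt2$z))
  expect_error(trend_test(tot, rep(1, 2000)), "constant")
})

test_that("external validity summarizes bins and directions", {
  sim <- simulate_population(fast_bangladesh_config(n = 3000, seed = 55))
  ev <- external_validity(sim$responses, sim$covariates)
  expect_setequal(names(ev), c("wealth", "wdds", "bmi"))
  for (v in ev) expect_equal(v$trend$direction, "negative")
  # mean total score decreases across wealth quartiles
  expect_true(all(diff(ev$wealth$bins$mean_score) < 0))
})

test_that("the full pipeline runs, skips gracefully and is deterministic", {
  sim <- simulate_population(fast_bangladesh_config(n = 1500, seed = 77))
  rep1 <- run_full_validation(sim$responses, sim$covariates, seed = 9)
  expect_s3_class(rep1, "validation_report")
  expect_false(rep1$any_failed)
  expect_true(all(!is.na(unlist(rep1$verdicts))))

  # no covariates: DIF and external stages skipped with a reason
  rep0 <- run_full_validation(sim$responses, covariates = NULL, seed = 9)
  expect_true(is.na(rep0$dif$ok))
  expect_match(rep0$dif$reason, "grouping")
  expect_true(is.na(rep0$external$ok))

  # identical config and seed -> byte-identical JSON report
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  rep2 <- run_full_validation(sim$responses, sim$covariates, seed = 9)
  write_validation_report(rep1, d1)
  write_validation_report(rep2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
})
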