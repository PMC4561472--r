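test_that("response files are read, label-mapped and range-checked", {
  sc <- fast_scale()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(sc$items$id, collapse = ","),
    "4,0,0,0,0,0,0,0,0",
    "never,rarely,sometimes,often,mostly,never,never,never,never",
    "NA,NA,NA,NA,NA,NA,NA,NA,NA",
    "0,1,NA,0,0,0,2,0,0"), f)
  rm_ <- read_responses(f, sc)
  expect_s3_class(rm_, "response_matrix")
  expect_false(attr(rm_, "coded"))
  expect_equal(nrow(rm_), 3L)              # all-missing row dropped
  expect_equal(attr(rm_, "n_excluded"), 1L)
  expect_equal(unclass(rm_)[1L, ], c(item1 = 4L, item2 = 0L, item3 = 0L,
                                     item4 = 0L, item5 = 0L, item6 = 0L,
                                     item7 = 0L, item8 = 0L, item9 = 0L))
  expect_equal(unname(unclass(rm_)[2L, ]), c(0L, 1L, 2L, 3L, 4L, 0L, 0L, 0L, 0L))
  expect_true(is.na(unclass(rm_)[3L, "item3"]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(sc$items$id, collapse = ","),
               "0,5,0,0,0,0,0,0,0"), bad)
  expect_error(read_responses(bad, sc), "row 1.*item2")

  unk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item1,mystery", "0,1"), unk)
  expect_error(read_responses(unk, sc), "unknown item")
})

test_that("reverse coding flips only flagged items and is guarded", {
  sc <- fast_scale()
  raw <- as_response_matrix(
    matrix(c(4, 3, 0, 0, 0, 0, 0, 0, 0,
             0, 3, 1, 2, 0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
           dimnames = list(NULL, sc$items$id)), sc)
  coded <- apply_coding(raw, sc)
  expect_true(attr(coded, "coded"))
  expect_equal(unname(unclass(coded)[, "item1"]), c(0L, 4L))  # endpoint swap
  expect_equal(unname(unclass(coded)[, "item2"]), c(3L, 3L))  # identity
  expect_error(apply_coding(coded, sc), "already")

  # involution: flipping twice returns the raw values
  attr(coded, "coded") <- FALSE
  twice <- apply_coding(coded, sc)
  expect_equal(unclass(twice)[, "item1"], unclass(raw)[, "item1"])
})

test_that("response summaries count categories and the floor correctly", {
  m <- as_response_matrix(matrix(c(0, 0, 1, 4), ncol = 1,
                                 dimnames = list(NULL, "item1")),
                          coded = TRUE)
  attr(m, "n_categories") <- 5L
  s <- summarize_responses(m)
  expect_equal(unname(s$marginals[1L, ]), c(50, 25, 0, 0, 25))
  expect_equal(s$floor_proportion, 0.5)

  z <- as_response_matrix(matrix(0L, 5, 3), coded = TRUE)
  attr(z, "n_categories") <- rep(5L, 3)
  expect_equal(summarize_responses(z)$floor_proportion, 1.0)
})

test_that("read -> code -> summarize round trip preserves respondents", {
  sc <- fast_scale()
  sim <- simulate_population(fast_bangladesh_config(n = 400L, seed = 8L))
  f <- withr::local_tempfile(fileext = ".csv")
  X <- unclass(sim$responses)
  X[, "item1"] <- 4L - X[, "item1"]       # back to raw coding
  utils::write.csv(as.data.frame(X), f, row.names = FALSE)
  back <- apply_coding(read_responses(f, sc), sc)
  expect_equal(unclass(back), unclass(sim$responses),
               ignore_attr = TRUE)
  s <- summarize_responses(back)
  expect_equal(s$n, 400L)
  sums <- rowSums(s$marginals)
  expect_equal(unname(sums), rep(100, 9), tolerance = 1e-10)
})

test_that("scale definitions round trip through YAML", {
  sc <- fast_scale()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scale_definition(sc, f)
  back <- read_scale_definition(f)
  expect_equal(back$items$id, sc$items$id)
  expect_equal(back$reverse_coded, sc$reverse_coded)
  expect_equal(back$category_labels, sc$category_labels)
  expect_equal(back$n_categories, sc$n_categories)
})
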