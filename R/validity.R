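#' Total food insecurity score
#'
#' Sum of the coded item responses (0–36 for the 9-item, 5-category FAST).
#' Missing-data policy: `"complete"` (default) leaves the score `NA` when
#' any item is missing; `"prorate"` rescales the mean of the observed items
#' to the full item count.
#'
#' @param matrix a coded `response_matrix`.
#' @param policy `"complete"` or `"prorate"`.
#' @return Numeric score per respondent.
#' @export
total_score <- function(matrix, policy = c("complete", "prorate")) {
  policy <- match.arg(policy)
  X <- unclass(matrix)
  if (!isTRUE(attr(matrix, "coded") %||% TRUE))
    stop_fv("total_score expects a coded matrix")
  if (policy == "complete") {
    out <- rowSums(X)
  } else {
    out <- rowMeans(X, na.rm = TRUE) * ncol(X)
  }
  as.numeric(out)
}

#' Empirical quartile bins
#'
#' Assigns `Q1` (lowest 25 percent) through `Q4` (highest 25 percent) by
#' the empirical quartiles; values tied with a quartile boundary go to the
#' lower bin.
#'
#' @param values numeric vector with at least 4 distinct values.
#' @return Ordered factor `Q1 < Q2 < Q3 < Q4` (NA preserved).
#' @export
quartile_bins <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 4L)
    stop_fv("quartile binning needs at least 4 distinct values")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  cut(values, breaks = c(-Inf, q, Inf), labels = paste0("Q", 1:4),
      right = TRUE, ordered_result = TRUE)
}

#' Body mass index categories
#'
#' Conventional adult cutoffs: undernutrition below 18.5, overweight above
#' 25.0 kg/m^2.
#'
#' @param bmi numeric BMI values (kg/m^2).
#' @return Ordered factor `undernutrition < normal < overweight`.
#' @export
bmi_bins <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, Inf),
      labels = c("undernutrition", "normal", "overweight"),
      right = FALSE, ordered_result = TRUE)
}

#' Nonparametric trend test of a validator across total-score groups
#'
#' Cuzick-type rank test for linear trend: respondents are grouped by
#' their (ordered) total score, the validator is ranked over the pooled
#' sample, and the statistic `L = sum(l_i * R_i)` (group score times rank)
#' is standardized by its permutation mean and tie-corrected variance. A
#' negative `z` means the validator decreases as the total score rises.
#' `method = "spearman"` gives the asymptotically equivalent
#' `z = r_s * sqrt(N - 1)` alternative.
#'
#' @param score numeric total scores (define the ordered groups; the group
#'   score is the total-score value itself).
#' @param validator numeric external validator, same length.
#' @param method `"cuzick"` (default) or `"spearman"`.
#' @return List with `z`, `p_value` (two-sided), `direction`
#'   (`"negative"`/`"positive"`), `n`, `method`.
#' @export
trend_test <- function(score, validator, method = c("cuzick", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(score) & !is.na(validator)
  s <- score[ok]; v <- validator[ok]
  n <- length(s)
  if (n < 10L) stop_fv("trend test needs at least 10 paired observations")
  if (length(unique(v)) < 2L) stop_fv("validator is constant")
  if (length(unique(s)) < 2L) stop_fv("total score is constant")
  if (method == "spearman") {
    r <- stats::cor(s, v, method = "spearman")
    z <- r * sqrt(n - 1)
  } else {
    R <- rank(v)
    l <- s
    L <- sum(l * R)
    nl <- tapply(rep(1, n), l, sum)
    lv <- as.numeric(names(nl))
    EL <- (n + 1) / 2 * sum(nl * lv)
    ties <- table(v)
    tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    VL <- (n + 1) / 12 * (n * sum(nl * lv^2) - sum(nl * lv)^2) * tie_corr
    z <- (L - EL) / sqrt(VL)
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       direction = if (z < 0) "negative" else "positive",
       n = n, method = method)
}

#' External construct validity against continuous validators
#'
#' For each validator, runs the trend test on the continuous values and
#' tabulates the mean and median total score per bin (quartiles for wealth
#' and dietary diversity, fixed BMI cutoffs for BMI).
#'
#' @param matrix a coded `response_matrix`.
#' @param covariates data frame of validators.
#' @param validators character vector of validator column names present in
#'   `covariates` (default: the intersection of
#'   `c("wealth", "wdds", "bmi")` with its columns).
#' @param score_policy see [total_score()].
#' @param method see [trend_test()].
#' @return A list per validator with the trend-test result and the bin
#'   summary table; class `external_validity`.
#' @export
external_validity <- function(matrix, covariates, validators = NULL,
                              score_policy = "complete",
                              method = "cuzick") {
  if (is.null(validators))
    validators <- intersect(c("wealth", "wdds", "bmi"), names(covariates))
  if (!length(validators)) stop_fv("no validator columns found")
  total <- total_score(matrix, policy = score_policy)
  out <- lapply(validators, function(v) {
    val <- covariates[[v]]
    if (is.null(val)) stop_fv("validator column '%s' not found", v)
    tt <- trend_test(total, val, method = method)
    bins <- if (identical(v, "bmi")) bmi_bins(val) else quartile_bins(val)
    ok <- !is.na(bins) & !is.na(total)
    tab <- data.frame(
      bin = levels(bins),
      n = as.integer(table(bins[ok])),
      mean_score = as.numeric(tapply(total[ok], bins[ok], mean)),
      median_score = as.numeric(tapply(total[ok], bins[ok], stats::median)))
    list(validator = v, trend = tt, bins = tab)
  })
  names(out) <- validators
  class(out) <- "external_validity"
  out
}

#' @export
print.external_validity <- function(x, ...) {
  cat("External construct validity (trend of validator vs total score)\n")
  for (v in x)
    cat(sprintf("  %s: z = %.2f, p = %.3g (%s trend)\n",
                v$validator, v$trend$z, v$trend$p_value, v$trend$direction))
  invisible(x)
}
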