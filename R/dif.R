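# Cumulative-split binary responses for an ordinal item: y_c = 1 if x <= c.
# Splits where y is constant are dropped symmetrically from both nested
# models (recorded), since they carry no likelihood information.
cumulative_splits <- function(x) {
  m <- max(x)
  splits <- 0:(m - 1L)
  keep <- vapply(splits, function(cc) {
    y <- x <= cc
    any(y) && !all(y)
  }, logical(1))
  list(splits = splits[keep], dropped = splits[!keep])
}

# Fit one binary logistic split; returns logLik and the linear predictor
# (without intercept) for McKelvey-Zavoina R2.
split_logit <- function(y, Xmat) {
  # quasi-separation in sparse upper splits is expected with floor-heavy
  # data and harmless for the LR comparison; keep the fit quiet
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Xmat), y, family = stats::binomial()))
  eta <- if (ncol(Xmat)) as.matrix(Xmat) %*% fit$coefficients[-1L] else
    rep(0, length(y))
  lp <- cbind(1, Xmat) %*% fit$coefficients
  ll <- -fit$deviance / 2
  list(ll = ll, eta = as.numeric(eta), rank = fit$rank,
       separated = max(abs(lp)) > 15)
}

# McKelvey-Zavoina pseudo R2 on the latent logistic scale, averaged over
# splits (each split is a cumulative-logit equation).
mz_r2 <- function(etas) {
  mean(vapply(etas, function(e) {
    v <- stats::var(e)
    v / (v + pi^2 / 3)
  }, numeric(1)))
}

#' Test the proportional odds assumption for one item
#'
#' Brant-type likelihood-ratio comparison on the stacked cumulative
#' splits: the binary indicators `x <= c` for all informative splits are
#' stacked into one binary regression with split-specific intercepts, and
#' the model sharing one slope set (total score, group, interaction)
#' across splits is tested against the model with free slopes per split
#' (equivalent to independent per-split fits). A small p routes the item
#' to the generalized (unconstrained) family. With a single split the two
#' families coincide and `p = 1` by convention; separation is flagged and
#' the item routed to the generalized family.
#'
#' @param x integer item responses (codes `0..m`).
#' @param total numeric total score.
#' @param group binary group membership (0/1).
#' @return List with `p_value`, `statistic`, `df`, and `flagged` (TRUE if
#'   the constrained fit failed).
#' @export
test_proportional_odds <- function(x, total, group) {
  ok <- !is.na(x) & !is.na(total) & !is.na(group)
  x <- x[ok]; total <- total[ok]; group <- as.numeric(group[ok])
  cs <- cumulative_splits(x)
  m <- length(cs$splits)
  if (m <= 1L)
    return(list(p_value = 1, statistic = 0, df = 0L, flagged = FALSE))
  Xmat <- cbind(total = total, group = group, tg = total * group)
  ll_gen <- sum(vapply(cs$splits, function(cc)
    split_logit(x <= cc, Xmat)$ll, numeric(1)))
  # constrained stack: one intercept per split, shared slopes
  n <- length(x)
  y_st <- unlist(lapply(cs$splits, function(cc) as.numeric(x <= cc)))
  icpt <- matrix(0, n * m, m)
  for (i in seq_len(m)) icpt[((i - 1L) * n + 1L):(i * n), i] <- 1
  X_st <- cbind(icpt, Xmat[rep(seq_len(n), m), , drop = FALSE])
  ll_prop <- tryCatch({
    fit <- suppressWarnings(
      stats::glm.fit(X_st, y_st, family = stats::binomial()))
    -fit$deviance / 2
  }, error = function(e) NA_real_)
  df <- 3L * (m - 1L)
  if (is.na(ll_prop))
    return(list(p_value = 0, statistic = NA_real_, df = df, flagged = TRUE))
  stat <- max(0, 2 * (ll_gen - ll_prop))
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, flagged = FALSE)
}

#' Nested cumulative-logit DIF models for one item
#'
#' Model 1 regresses the log odds of responding in a category or below on
#' the total food insecurity score; model 2 adds group membership and the
#' total-by-group interaction (capturing uniform and non-uniform DIF
#' jointly). Under the generalized family (used when proportional odds is
#' rejected at `po_alpha`, or always when `family = "generalized"`) each
#' model is fit as independent binary logistic regressions on the `m`
#' cumulative splits and the log-likelihoods summed; under the
#' proportional family both models are single `MASS::polr` fits. The DIF
#' statistic is `LR = -2 (LL1 - LL2)` with 2 degrees of freedom per free
#' slope set. Effect size is the pseudo-R-squared difference
#' (McKelvey-Zavoina by default; Nagelkerke available) and may be slightly
#' negative under the generalized family.
#'
#' @inheritParams test_proportional_odds
#' @param family `"auto"` (route by the proportional-odds test),
#'   `"generalized"` or `"proportional"`.
#' @param po_alpha routing level for the proportional-odds test (0.05).
#' @param r2 `"mckelvey_zavoina"` (default) or `"nagelkerke"`.
#' @param item optional item id carried into the result.
#' @param grouping optional grouping-variable name carried into the result.
#' @return An object of class `dif_result`: log-likelihoods, `lr`, `df`,
#'   `p_value`, `r2_model1`, `r2_model2`, `effect_size` (R2 difference, as
#'   a proportion), `family`, `po_p_value`, `dropped_splits`.
#' @export
fit_nested_dif_models <- function(x, total, group,
                                  family = c("auto", "generalized",
                                             "proportional"),
                                  po_alpha = 0.05,
                                  r2 = c("mckelvey_zavoina", "nagelkerke"),
                                  item = NA_character_,
                                  grouping = NA_character_) {
  family <- match.arg(family); r2 <- match.arg(r2)
  ok <- !is.na(x) & !is.na(total) & !is.na(group)
  x <- x[ok]; total <- total[ok]
  group <- as.numeric(group[ok])
  if (length(unique(group)) != 2L)
    stop_fv("group must be binary with both levels observed")
  po <- test_proportional_odds(x, total, group)
  if (family == "auto")
    family <- if (po$p_value < po_alpha || po$flagged) "generalized"
              else "proportional"
  cs <- cumulative_splits(x)
  m <- length(cs$splits)
  if (m < 1L) stop_fv("item has no informative cumulative split")
  X1 <- cbind(total = total)
  X2 <- cbind(total = total, group = group, tg = total * group)
  r2_splits <- seq_len(m)
  if (family == "generalized") {
    f1 <- lapply(cs$splits, function(cc) split_logit(x <= cc, X1))
    f2 <- lapply(cs$splits, function(cc) split_logit(x <= cc, X2))
    ll1 <- sum(vapply(f1, `[[`, numeric(1), "ll"))
    ll2 <- sum(vapply(f2, `[[`, numeric(1), "ll"))
    df <- 2L * m
    # a numerically separated split has a degenerate latent-scale variance
    # (its pseudo R2 tends to 1); exclude such splits from the R2
    # aggregation in BOTH models so the effect size stays comparable.
    # The LR statistic keeps every split: its deviance remains finite.
    stable <- !(vapply(f1, `[[`, logical(1), "separated") |
                  vapply(f2, `[[`, logical(1), "separated"))
    if (any(stable)) r2_splits <- which(stable)
    eta1 <- lapply(f1[r2_splits], `[[`, "eta")
    eta2 <- lapply(f2[r2_splits], `[[`, "eta")
  } else {
    xf <- factor(x, levels = sort(unique(x)))
    prop_fit <- tryCatch(suppressWarnings({
      m1 <- MASS::polr(xf ~ total, Hess = FALSE)
      m2 <- MASS::polr(xf ~ total + group + I(total * group), Hess = FALSE)
      list(m1 = m1, m2 = m2)
    }), error = function(e) NULL)
    if (is.null(prop_fit)) {
      # sparse categories can defeat the proportional optimizer; fall back
      # to the generalized family rather than abort the item
      return(fit_nested_dif_models(x, total, group, family = "generalized",
                                   po_alpha = po_alpha, r2 = r2,
                                   item = item, grouping = grouping))
    }
    m1 <- prop_fit$m1; m2 <- prop_fit$m2
    ll1 <- as.numeric(stats::logLik(m1)); ll2 <- as.numeric(stats::logLik(m2))
    df <- 2L
    eta1 <- list(as.numeric(X1 %*% m1$coefficients))
    eta2 <- list(as.numeric(X2 %*% m2$coefficients))
  }
  if (r2 == "mckelvey_zavoina") {
    r2_1 <- mz_r2(eta1); r2_2 <- mz_r2(eta2)
  } else {
    # Nagelkerke over the pooled split observations
    if (family == "generalized") {
      ll0 <- sum(vapply(cs$splits, function(cc)
        split_logit(x <= cc, X1[, 0, drop = FALSE])$ll, numeric(1)))
      n_obs <- length(x) * m
    } else {
      ll0 <- as.numeric(stats::logLik(MASS::polr(
        factor(x, levels = sort(unique(x))) ~ 1, Hess = FALSE)))
      n_obs <- length(x)
    }
    nag <- function(ll) (1 - exp(2 * (ll0 - ll) / n_obs)) /
      (1 - exp(2 * ll0 / n_obs))
    r2_1 <- nag(ll1); r2_2 <- nag(ll2)
  }
  lr <- -2 * (ll1 - ll2)
  structure(list(item = item, grouping = grouping,
                 ll_model1 = ll1, ll_model2 = ll2,
                 lr = lr, df = df,
                 p_value = stats::pchisq(max(lr, 0), df, lower.tail = FALSE),
                 r2_model1 = r2_1, r2_model2 = r2_2,
                 effect_size = r2_2 - r2_1, r2_type = r2,
                 family = family, po_p_value = po$p_value,
                 dropped_splits = cs$dropped,
                 r2_splits_used = length(r2_splits), n = length(x)),
            class = "dif_result")
}

#' Classify a DIF result
#'
#' `"none"` if the likelihood-ratio p-value is not below `alpha`;
#' `"statistical-only"` if it is but the pseudo-R-squared difference stays
#' below `effect_cutoff`; `"practical"` if both thresholds are crossed.
#' Large samples routinely produce statistically significant DIF of no
#' practical consequence, so the two notions are never collapsed.
#'
#' @param result a `dif_result` (or a list with `p_value` and
#'   `effect_size`).
#' @param alpha significance level (default 0.05).
#' @param effect_cutoff practical-significance cutoff on the R-squared
#'   difference (default 0.13, i.e. 13 percentage points).
#' @return Character verdict.
#' @export
dif_verdict <- function(result, alpha = 0.05, effect_cutoff = 0.13) {
  if (result$p_value >= alpha) "none"
  else if (result$effect_size < effect_cutoff) "statistical-only"
  else "practical"
}

#' DIF analysis across items and groupings
#'
#' Runs [fit_nested_dif_models()] for every item against every binary
#' grouping column, matching on the observed total score (the studied item
#' included; set `matching = "rest"` to exclude it). No multiple-testing
#' correction is applied; verdicts separate statistical from practical
#' significance.
#'
#' @param matrix a coded `response_matrix`.
#' @param covariates data frame holding the grouping columns (0/1 or
#'   two-level).
#' @param groupings character vector of grouping column names (default:
#'   every two-level column).
#' @param matching `"total"` (default) or `"rest"`.
#' @param score_policy missing-data policy for the total, see
#'   [total_score()].
#' @param ... passed to [fit_nested_dif_models()].
#' @param alpha,effect_cutoff verdict thresholds, see [dif_verdict()].
#' @return A data frame of class `dif_table`, one row per item-by-grouping
#'   combination, shaped like a DIF results table (log-likelihoods, LR
#'   statistic, p, effect size in percent, family, verdict).
#' @export
dif_analysis <- function(matrix, covariates, groupings = NULL,
                         matching = c("total", "rest"),
                         score_policy = "complete",
                         alpha = 0.05, effect_cutoff = 0.13, ...) {
  matching <- match.arg(matching)
  X <- unclass(matrix)
  if (is.null(groupings))
    groupings <- names(covariates)[vapply(covariates, function(v)
      length(unique(stats::na.omit(v))) == 2L, logical(1))]
  if (!length(groupings)) stop_fv("no binary grouping columns found")
  total_all <- total_score(matrix, policy = score_policy)
  rows <- list()
  for (g in groupings) {
    gv <- covariates[[g]]
    if (is.null(gv)) stop_fv("grouping column '%s' not found", g)
    gv <- as.integer(factor(gv)) - 1L
    for (j in seq_len(ncol(X))) {
      tot <- if (matching == "rest")
        total_all - ifelse(is.na(X[, j]), 0, X[, j]) else total_all
      res <- fit_nested_dif_models(X[, j], tot, gv,
                                   item = colnames(X)[j], grouping = g, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        item = res$item, grouping = g,
        ll_model1 = res$ll_model1, ll_model2 = res$ll_model2,
        lr = res$lr, df = res$df, p_value = res$p_value,
        effect_size_pct = 100 * res$effect_size,
        family = res$family, po_p_value = res$po_p_value,
        verdict = dif_verdict(res, alpha, effect_cutoff))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dif_table", "data.frame")
  out
}
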