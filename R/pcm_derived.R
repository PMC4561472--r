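# Recode a response matrix onto a fit's (possibly collapsed) category scale.
recode_to_fit <- function(fit, X) {
  for (j in seq_along(fit$delta)) {
    map <- fit$collapse[[j]]$map
    if (isTRUE(fit$collapse[[j]]$collapsed))
      X[, j] <- match(X[, j], map) - 1L
  }
  X
}

# n x Q matrix of posterior weights over the fit's quadrature grid.
posterior_over_grid <- function(fit, X) {
  nodes <- fit$nodes
  lw <- stats::dnorm(nodes, 0, fit$sigma, log = TRUE)
  lw <- lw - max(lw) - log(sum(exp(lw - max(lw))))
  L <- matrix(rep(lw, each = nrow(X)), nrow(X), length(nodes))
  for (j in seq_along(fit$delta)) {
    lp <- t(log(pcm_probs(nodes, fit$delta[[j]])))
    xj <- X[, j]; ok <- !is.na(xj)
    L[ok, ] <- L[ok, ] + lp[xj[ok] + 1L, , drop = FALSE]
  }
  P <- exp(L - apply(L, 1L, max))
  P / rowSums(P)
}

#' Person scores: raw totals and EAP trait estimates
#'
#' The raw total is the sum of non-missing coded responses. The latent
#' score is the expected a posteriori (EAP) estimate: the posterior mean of
#' the trait over the fit's quadrature grid, with posterior SD alongside.
#' Under the partial credit model the total score is a sufficient statistic,
#' so complete-response respondents with equal totals receive equal EAPs.
#'
#' @param fit a [fit_pcm()] result.
#' @param matrix the coded `response_matrix` to score.
#' @return A data frame with columns `total`, `eap`, `eap_sd`, `n_observed`.
#' @export
person_scores <- function(fit, matrix) {
  X <- unclass(matrix)
  keep <- rowSums(!is.na(X)) > 0L
  if (!all(keep)) stop_fv("respondents with all items missing must be excluded upstream")
  total <- rowSums(X, na.rm = TRUE)
  Xr <- recode_to_fit(fit, X)
  post <- posterior_over_grid(fit, Xr)
  eap <- as.numeric(post %*% fit$nodes)
  eap_sd <- sqrt(pmax(as.numeric(post %*% fit$nodes^2) - eap^2, 0))
  data.frame(total = total, eap = eap, eap_sd = eap_sd,
             n_observed = rowSums(!is.na(X)))
}

#' Infit and outfit mean square fit statistics
#'
#' Standardized residuals compare observed responses with the model's
#' expectation at each respondent's estimated trait: for respondent `n` and
#' item `i`, `z = (x - E)/sqrt(W)` where `E` and `W` are the model mean and
#' variance of the response. Outfit is the unweighted mean of `z^2`
#' (sensitive to outlying respondents far from the item's severity); infit
#' weights each squared residual by `W` (information), emphasizing
#' respondents near the item's severity. Both equal 1 under perfect fit.
#'
#' Item-category (step) statistics use the adjacent-category-pair
#' convention: the statistic for step `k` of an item is computed from the
#' respondents whose response falls in `{k-1, k}`, for whom the conditional
#' model is a dichotomous Rasch step `P(X = k | X in {k-1,k}) =
#' plogis(theta - delta_k)`.
#'
#' @param fit a [fit_pcm()] result.
#' @param matrix the coded `response_matrix` used for (or scored under) the
#'   fit.
#' @param windows numeric acceptance windows for flagging, widest first.
#' @return A list with `items` (per-item infit/outfit data frame) and
#'   `categories` (per item-step data frame with infit/outfit, `n`, and
#'   in-window flags for 0.7–1.3 and 0.8–1.2).
#' @export
item_fit_statistics <- function(fit, matrix,
                                windows = list(acceptable = c(0.7, 1.3),
                                               recommended = c(0.8, 1.2))) {
  X <- recode_to_fit(fit, unclass(matrix))
  ps <- person_scores(fit, matrix)
  theta <- ps$eap
  J <- length(fit$delta)
  item_stats <- data.frame(item = fit$item_ids, infit = NA_real_,
                           outfit = NA_real_)
  cat_rows <- list()
  for (j in seq_len(J)) {
    xj <- X[, j]; ok <- !is.na(xj)
    if (stats::var(xj[ok]) == 0) stop_fv("item '%s' has zero variance", fit$item_ids[j])
    p <- pcm_probs(theta[ok], fit$delta[[j]])
    cats <- 0:fit$m[j]
    E <- as.numeric(p %*% cats)
    W <- as.numeric(p %*% cats^2) - E^2
    z2 <- (xj[ok] - E)^2 / W
    item_stats$outfit[j] <- mean(z2)
    item_stats$infit[j] <- sum(W * z2) / sum(W)
    for (k in seq_len(fit$m[j])) {
      pair <- ok & (X[, j] %in% c(k - 1L, k))
      if (sum(pair) < 2L) next
      pk <- stats::plogis(theta[pair] - fit$delta[[j]][k])
      y <- as.numeric(X[pair, j] == k)
      w <- pk * (1 - pk)
      z2k <- (y - pk)^2 / w
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        item = fit$item_ids[j], step = k,
        category = fit$collapse[[j]]$map[k + 1L],
        infit = sum(w * z2k) / sum(w), outfit = mean(z2k), n = sum(pair))
    }
  }
  categories <- do.call(rbind, cat_rows)
  for (wn in names(windows)) {
    w <- windows[[wn]]
    categories[[paste0("in_", wn)]] <-
      categories$infit >= w[1L] & categories$infit <= w[2L]
  }
  list(items = item_stats, categories = categories, windows = windows)
}

#' Thurstonian thresholds (item category severities)
#'
#' The step parameters of the partial credit model locate intersections of
#' adjacent category probability curves and are not themselves ordered
#' severities. The Thurstonian threshold of category `k` is instead the
#' trait value at which the probability of responding in category `k` or
#' higher reaches 0.50; these are strictly increasing in `k` and serve as
#' interpretable item-category severities.
#'
#' @param steps a [fit_pcm()] object, a list of step vectors, or a single
#'   numeric step vector.
#' @param tol root-finding tolerance in logits (default `1e-6`).
#' @param range bracketing interval, default `c(-50, 50)`.
#' @return A list (per item) of strictly increasing threshold vectors
#'   `gamma`, one entry per category `k >= 1`; a single vector if `steps`
#'   was a single vector.
#' @export
thurstonian_thresholds <- function(steps, tol = 1e-6, range = c(-50, 50)) {
  if (inherits(steps, "pcm_fit")) steps <- steps$delta
  single <- is.numeric(steps) && !is.list(steps)
  if (single) steps <- list(steps)
  out <- lapply(steps, function(d) {
    m <- length(d)
    g <- vapply(seq_len(m), function(k) {
      f <- function(th) pcm_cum_probs(th, d)[, k] - 0.5
      if (f(range[1L]) > 0 || f(range[2L]) < 0)
        stop_fv("Thurstonian threshold not bracketed in [%g, %g]",
                range[1L], range[2L])
      stats::uniroot(f, range, tol = tol)$root
    }, numeric(1))
    if (any(diff(g) <= 0))
      stop_fv("Thurstonian thresholds are not strictly increasing")
    g
  })
  if (single) out[[1L]] else out
}
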