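#' Partial credit model category probabilities
#'
#' Evaluates the PCM response-category distribution at latent trait values
#' `theta` for an item with step parameters `delta`. Adjacent categories
#' follow a step logistic model: the log odds of category `k` versus `k - 1`
#' equal `theta - delta[k]`, so
#' \deqn{P(X = x \mid \theta) = \frac{\exp\sum_{k \le x}(\theta - \delta_k)}
#'   {\sum_{h=0}^{m} \exp\sum_{k \le h}(\theta - \delta_k)}}
#' with the empty sum equal to zero. Computation is log-sum-exp stabilized
#' and safe for `|theta|` up to at least 50. With a single step the model
#' reduces to the dichotomous Rasch model,
#' `P(X = 1) = plogis(theta - delta)`.
#'
#' @param theta numeric vector of latent trait values (logit scale).
#' @param delta numeric vector of `m` step parameters for an item with
#'   `m + 1` ordered categories.
#' @return A `length(theta)` by `m + 1` matrix of probabilities; rows sum
#'   to 1.
#' @export
pcm_probs <- function(theta, delta) {
  if (!length(delta) || any(!is.finite(delta)))
    stop_fv("`delta` must be a non-empty finite vector")
  m <- length(delta)
  # cumulative numerator exponents: x*theta - sum_{k<=x} delta_k
  cs <- c(0, cumsum(delta))
  eta <- outer(theta, 0:m) - matrix(cs, length(theta), m + 1L, byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

# Cumulative category probabilities P(X >= k), k = 1..m, at theta.
pcm_cum_probs <- function(theta, delta) {
  p <- pcm_probs(theta, delta)
  m <- length(delta)
  out <- matrix(0, length(theta), m)
  for (k in seq_len(m)) out[, k] <- rowSums(p[, (k + 1L):(m + 1L), drop = FALSE])
  out
}

# Collapse unobserved categories: map observed codes to consecutive 0..m'.
# Returns list(x = recoded vector, map = original codes retained).
collapse_categories <- function(x, n_cat, policy) {
  obs <- sort(unique(x[!is.na(x)]))
  full <- 0:(n_cat - 1L)
  if (length(obs) < 2L) stop_fv("item has fewer than 2 observed categories")
  if (length(obs) == length(full)) return(list(x = x, map = full, collapsed = FALSE))
  if (policy == "strict")
    stop_fv("unobserved categories {%s} with policy = 'strict'",
            paste(setdiff(full, obs), collapse = ","))
  list(x = match(x, obs) - 1L, map = obs, collapsed = TRUE)
}

#' Fit the partial credit model by marginal maximum likelihood
#'
#' Estimates item step parameters and the latent trait standard deviation by
#' an EM algorithm over a fixed quadrature grid, with the latent trait
#' assumed normal with mean fixed at 0 (identification) and standard
#' deviation estimated. The E-step computes each respondent's posterior over
#' the grid; the M-step re-maximizes every item's expected complete-data
#' multinomial likelihood (quasi-Newton, warm-started) and solves the
#' latent-scale update exactly by one-dimensional optimization, so the
#' marginal log-likelihood is non-decreasing across iterations.
#'
#' Missing responses contribute nothing to the likelihood (missing at
#' random over observed items). Items with unobserved categories are
#' handled per `policy`: `"collapse"` merges each unobserved category with
#' its lower neighbour (recorded in the fit), `"strict"` aborts.
#'
#' @param matrix a coded `response_matrix` (or plain matrix of codes).
#' @param n_nodes number of quadrature nodes (default 61).
#' @param theta_range grid range on the logit scale, default `c(-10, 10)`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param min_n minimum number of respondents (default 50).
#' @param policy `"collapse"` or `"strict"` for unobserved categories.
#' @return An object of class `pcm_fit`: list with `delta` (list of step
#'   vectors per item), `sigma`, `loglik`, `ll_trace`, `nodes`, `weights`,
#'   `converged`, `n_iter`, `n_used`, `collapse` (category maps).
#' @export
fit_pcm <- function(matrix, n_nodes = 61L, theta_range = c(-10, 10),
                    max_iter = 500L, tol = 1e-6, min_n = 50L,
                    policy = c("collapse", "strict")) {
  policy <- match.arg(policy)
  X <- unclass(matrix)
  if (!is.matrix(X)) stop_fv("`matrix` must be a response matrix")
  keep <- rowSums(!is.na(X)) > 0L
  X <- X[keep, , drop = FALSE]
  n <- nrow(X); J <- ncol(X)
  if (n < min_n) stop_fv("need at least %d respondents, got %d", min_n, n)
  nc <- attr(matrix, "n_categories") %||%
    (apply(X, 2L, max, na.rm = TRUE) + 1L)

  collapse <- vector("list", J)
  for (j in seq_len(J)) {
    cc <- collapse_categories(X[, j], nc[j], policy)
    X[, j] <- cc$x
    collapse[[j]] <- cc
  }
  m <- vapply(seq_len(J), function(j) length(collapse[[j]]$map) - 1L,
              integer(1))

  nodes <- seq(theta_range[1L], theta_range[2L], length.out = n_nodes)
  sigma <- 1
  # init steps from adjacent-category log count ratios (0.5 smoothing)
  delta <- lapply(seq_len(J), function(j) {
    cnt <- tabulate(X[, j] + 1L, nbins = m[j] + 1L) + 0.5
    log(cnt[-length(cnt)] / cnt[-1L])
  })

  # expected complete-data log-likelihood for one item given counts R (Q x m+1)
  item_obj <- function(d, R) {
    lp <- log(pcm_probs(nodes, d))
    -sum(R * lp)
  }
  item_grad <- function(d, R) {
    cum <- pcm_cum_probs(nodes, d)            # Q x m : P(X >= k)
    Nq <- rowSums(R)
    mk <- length(d)
    Rcum <- sapply(seq_len(mk), function(k)
      rowSums(R[, (k + 1L):(mk + 1L), drop = FALSE]))
    if (is.null(dim(Rcum))) Rcum <- matrix(Rcum, nrow = 1L)
    # d(-Q)/d delta_k = sum_q (Rcum_qk - Nq * Pcum_qk)
    colSums(Rcum - Nq * cum)
  }

  loglik_parts <- function(delta) {
    # n x Q log conditional likelihood given theta_q
    L <- matrix(0, n, n_nodes)
    for (j in seq_len(J)) {
      lp <- t(log(pcm_probs(nodes, delta[[j]])))  # (m+1) x Q
      xj <- X[, j]
      ok <- !is.na(xj)
      L[ok, ] <- L[ok, ] + lp[xj[ok] + 1L, , drop = FALSE]
    }
    L
  }

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lw <- stats::dnorm(nodes, 0, sigma, log = TRUE)
    lw <- lw - logsumexp_rows(matrix(lw, 1L))[1L]
    LP <- sweep(loglik_parts(delta), 2L, lw, `+`)
    rowmax <- apply(LP, 1L, max)
    P <- exp(LP - rowmax)
    rs <- rowSums(P)
    ll <- sum(rowmax + log(rs))
    ll_trace <- c(ll_trace, ll)
    post <- P / rs

    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    # M-step: item steps
    for (j in seq_len(J)) {
      xj <- X[, j]; ok <- !is.na(xj)
      # expected counts: Q x (m+1)
      R <- crossprod(post[ok, , drop = FALSE], outer(xj[ok], 0:m[j], `==`) * 1)
      opt <- stats::optim(delta[[j]], fn = item_obj, gr = item_grad, R = R,
                          method = "BFGS",
                          control = list(maxit = 30L, reltol = 1e-10))
      delta[[j]] <- opt$par
    }
    # M-step: latent scale (exact 1-D maximization of the discretized term)
    rq <- colSums(post)
    f <- function(s) {
      lw <- stats::dnorm(nodes, 0, s, log = TRUE)
      lw <- lw - max(lw) - log(sum(exp(lw - max(lw))))
      sum(rq * lw)
    }
    sigma <- stats::optimize(f, c(0.05, 10), maximum = TRUE,
                             tol = 1e-7)$maximum
  }
  if (!converged)
    warning(sprintf("fit_pcm: EM did not converge in %d iterations (last rel change %.2e)",
                    max_iter,
                    abs(diff(utils::tail(ll_trace, 2))) / abs(ll_old)))

  names(delta) <- colnames(X) %||% paste0("item", seq_len(J))
  structure(list(delta = delta, sigma = sigma, loglik = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, nodes = nodes,
                 n_nodes = n_nodes, theta_range = theta_range,
                 converged = converged, n_iter = length(ll_trace),
                 n_used = n, m = m, collapse = collapse,
                 item_ids = names(delta)),
            class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf("Partial credit model fit (MML-EM): %d respondents, %d items\n",
              x$n_used, length(x$delta)))
  cat(sprintf("  log-likelihood %.2f after %d iterations (%s), latent SD %.3f\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged", x$sigma))
  for (j in seq_along(x$delta))
    cat(sprintf("  %s: %s\n", x$item_ids[j],
                paste(sprintf("%.3f", x$delta[[j]]), collapse = ", ")))
  invisible(x)
}
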