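# Shared fixtures and independent oracles used across the test files.

# A reproducible set of realistic step parameters (J items, m steps each).
make_steps <- function(J = 9L, m = 4L, seed = 42L, mean = 0.5, sd = 1) {
  set.seed(seed)
  steps <- replicate(J, sort(stats::rnorm(m, mean, sd)), simplify = FALSE)
  names(steps) <- paste0("item", seq_len(J))
  steps
}

# Independent dichotomous-Rasch MML oracle: directly maximizes the marginal
# likelihood over item difficulties and the latent SD by numerical
# optimization on a fine fixed grid (no EM, no shared code path with
# fit_pcm beyond the logistic kernel written out explicitly).
rasch_mml_oracle <- function(X, n_grid = 201L, range = c(-8, 8)) {
  J <- ncol(X)
  grid <- seq(range[1L], range[2L], length.out = n_grid)
  negll <- function(par) {
    delta <- par[seq_len(J)]
    sigma <- exp(par[J + 1L])
    w <- stats::dnorm(grid, 0, sigma)
    w <- w / sum(w)
    ll <- 0
    p1 <- stats::plogis(outer(grid, delta, `-`))   # Q x J
    for (i in seq_len(nrow(X))) {
      li <- rep(1, n_grid)
      for (j in seq_len(J))
        li <- li * ifelse(rep(X[i, j] == 1L, n_grid), p1[, j], 1 - p1[, j])
      ll <- ll + log(sum(w * li))
    }
    -ll
  }
  init <- c(rep(0, J), 0)
  fit <- stats::optim(init, negll, method = "BFGS",
                      control = list(maxit = 300L, reltol = 1e-10))
  list(delta = fit$par[seq_len(J)], sigma = exp(fit$par[J + 1L]))
}

# Fine-grid numerical-integration oracle for the EAP of one response
# pattern under given steps and latent SD.
eap_oracle <- function(pattern, steps, sigma, n_grid = 4001L,
                       range = c(-12, 12)) {
  grid <- seq(range[1L], range[2L], length.out = n_grid)
  w <- stats::dnorm(grid, 0, sigma)
  for (j in seq_along(steps)) {
    if (is.na(pattern[j])) next
    w <- w * pcm_probs(grid, steps[[j]])[, pattern[j] + 1L]
  }
  sum(grid * w) / sum(w)
}

# Quadrature oracle for the expected all-zero ("all never") share under a
# latent mixture and a set of item steps.
all_never_oracle <- function(spec, steps) {
  f <- function(th) {
    p0 <- rep(1, length(th))
    for (d in steps) p0 <- p0 * pcm_probs(th, d)[, 1L]
    fl <- if (spec$floor_sd > 0)
      stats::dnorm(th, spec$floor_mean, spec$floor_sd) else 0
    dens <- spec$p_floor * fl +
      (1 - spec$p_floor) * stats::dnorm(th, spec$mu, spec$sigma)
    p0 * dens
  }
  stats::integrate(f, -30, 30, rel.tol = 1e-9)$value
}

# Single-pair bivariate normal CDF by one-dimensional base-R integration,
# independent of the package's Gauss-Legendre implementation.
pbvnorm_oracle <- function(h, k, rho) {
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2)),
    -Inf, h, rel.tol = 1e-10)$value
}

# Discretize correlated standard normals into 5 ordinal categories.
discretize5 <- function(z, cuts = stats::qnorm(c(0.2, 0.4, 0.6, 0.8))) {
  findInterval(z, cuts)
}
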