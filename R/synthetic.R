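#' Specify a zero-inflated latent trait distribution
#'
#' The latent food-insecurity trait is modeled as a two-component mixture:
#' a "food-secure floor" component (a narrow normal far down the logit
#' scale, producing the large mass of households that report no insecurity
#' experience at all) and an "at-risk" normal component. Zero inflation
#' lives in the latent distribution, not in the response mechanism, so the
#' partial credit model remains the true item model conditional on the
#' trait.
#'
#' @param p_floor mixture weight of the floor component, in `[0, 1]`.
#' @param floor_mean,floor_sd location and spread of the floor component
#'   (logits); `floor_sd = 0` gives a point mass.
#' @param mu,sigma mean and SD of the at-risk normal component (logits),
#'   `sigma > 0`.
#' @return An object of class `latent_spec`.
#' @export
latent_spec <- function(p_floor = 0, floor_mean = -6, floor_sd = 0.25,
                        mu = 0, sigma = 1) {
  if (p_floor < 0 || p_floor > 1) stop_fv("p_floor must be in [0, 1]")
  if (sigma <= 0) stop_fv("sigma must be positive")
  if (floor_sd < 0) stop_fv("floor_sd must be non-negative")
  structure(list(p_floor = p_floor, floor_mean = floor_mean,
                 floor_sd = floor_sd, mu = mu, sigma = sigma),
            class = "latent_spec")
}

# Mixture density of a latent_spec (floor_sd = 0 handled by callers that
# integrate; used by the calibration utilities).
latent_density <- function(spec, theta) {
  fl <- if (spec$floor_sd > 0)
    stats::dnorm(theta, spec$floor_mean, spec$floor_sd) else 0
  spec$p_floor * fl + (1 - spec$p_floor) * stats::dnorm(theta, spec$mu, spec$sigma)
}

#' Draw latent trait values
#'
#' @param spec a [latent_spec()].
#' @param n number of respondents.
#' @param seed optional integer seed; with a seed fixed the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric vector of `n` trait values.
#' @export
generate_latent <- function(spec, n, seed = NULL) {
  if (n < 1L) stop_fv("n must be at least 1")
  with_seed(seed, {
    is_floor <- stats::runif(n) < spec$p_floor
    th <- numeric(n)
    th[is_floor] <- stats::rnorm(sum(is_floor), spec$floor_mean, spec$floor_sd)
    th[!is_floor] <- stats::rnorm(sum(!is_floor), spec$mu, spec$sigma)
    th
  })
}

#' Generate partial-credit-model responses
#'
#' Each response is drawn from the PCM category distribution
#' [pcm_probs()] at the respondent's latent trait value.
#'
#' @param theta numeric vector of latent trait values.
#' @param steps list of step-parameter vectors, one per item (or a single
#'   vector for a one-item scale).
#' @param seed optional integer seed.
#' @param item_ids optional item names (default `item1..itemJ`).
#' @param missing_rate optional MCAR missingness proportion applied
#'   cell-wise (default 0).
#' @return A coded `response_matrix`.
#' @export
generate_responses <- function(theta, steps, seed = NULL, item_ids = NULL,
                               missing_rate = 0) {
  if (is.numeric(steps) && !is.list(steps)) steps <- list(steps)
  J <- length(steps)
  n <- length(theta)
  item_ids <- item_ids %||% paste0("item", seq_len(J))
  with_seed(seed, {
    X <- matrix(NA_integer_, n, J, dimnames = list(NULL, item_ids))
    for (j in seq_len(J)) {
      p <- pcm_probs(theta, steps[[j]])
      cp <- matrixStats_cumsum(p)
      u <- stats::runif(n)
      # inverse-CDF draw: category = number of cumulative bounds exceeded
      X[, j] <- as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
    }
    if (missing_rate > 0)
      X[matrix(stats::runif(n * J) < missing_rate, n, J)] <- NA_integer_
    new_response_matrix(X, coded = TRUE,
                        n_categories = vapply(steps, length, 1L) + 1L)
  })
}

# Row-wise cumulative sums.
matrixStats_cumsum <- function(p) t(apply(p, 1L, cumsum))

#' Full synthetic-population configuration
#'
#' Bundles everything needed to simulate a study population: sample size,
#' item step parameters, the latent distribution, optional differential
#' item functioning (DIF) injection, binary grouping variables, and target
#' rank correlations between the latent trait and continuous external
#' validators.
#'
#' @param n number of respondents.
#' @param steps list of per-item step-parameter vectors.
#' @param latent a [latent_spec()].
#' @param dif_spec optional list with `item` (item id), `group` (name of a
#'   binary group variable), `shift` (uniform DIF: logits added to every
#'   step for the focal group) and/or `slope` (non-uniform DIF: the focal
#'   group's trait is multiplied by `1 + slope` inside the target item's
#'   kernel).
#' @param groups named numeric vector of Bernoulli probabilities for binary
#'   group variables (drawn independently of the trait: exogenous).
#' @param validators named numeric vector of target Spearman correlations
#'   between each continuous validator and the latent trait.
#' @param validator_marginals optional named list of quantile functions
#'   mapping `[0,1]` to each validator's scale (default standard normal).
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n, steps, latent = latent_spec(),
                             dif_spec = NULL, groups = NULL,
                             validators = NULL, validator_marginals = NULL,
                             seed = 1L) {
  if (n < 1L) stop_fv("n must be at least 1")
  if (is.numeric(steps) && !is.list(steps)) steps <- list(steps)
  if (is.null(names(steps))) names(steps) <- paste0("item", seq_along(steps))
  if (!is.null(validators) && any(abs(validators) >= 1))
    stop_fv("validator rank correlations must lie in (-1, 1)")
  if (!is.null(dif_spec)) {
    if (!dif_spec$item %in% names(steps))
      stop_fv("DIF item '%s' is not in the scale", dif_spec$item)
    if (is.null(groups) || !(dif_spec$group %in% names(groups)))
      stop_fv("DIF group '%s' has no membership probability", dif_spec$group)
  }
  structure(list(n = n, steps = steps, latent = latent, dif_spec = dif_spec,
                 groups = groups, validators = validators,
                 validator_marginals = validator_marginals, seed = seed),
            class = "synthetic_config")
}

#' Generate covariates tied to a latent trait by a Gaussian copula
#'
#' Continuous validators are built as monotone transforms of normals
#' correlated with the normal scores of `theta`, so the realized Spearman
#' correlation matches the target at large `n` (the Pearson correlation of
#' the underlying normals is `2 sin(pi * rho_s / 6)`). Binary group
#' variables are drawn independently of the trait (exogenous by
#' construction).
#'
#' @param theta latent trait vector.
#' @param validators named numeric vector of target Spearman correlations
#'   in `(-1, 1)`.
#' @param groups named numeric vector of Bernoulli probabilities.
#' @param marginals optional named list of quantile functions for the
#'   validators (default `qnorm`).
#' @param seed optional integer seed.
#' @return Data frame with a `respondent` column, one 0/1 column per group
#'   and one numeric column per validator.
#' @export
generate_covariates <- function(theta, validators = NULL, groups = NULL,
                                marginals = NULL, seed = NULL) {
  n <- length(theta)
  if (!is.null(validators) && any(abs(validators) >= 1))
    stop_fv("target rank correlations must lie in (-1, 1)")
  with_seed(seed, {
    out <- data.frame(respondent = as.character(seq_len(n)))
    for (g in names(groups))
      out[[g]] <- as.integer(stats::runif(n) < groups[[g]])
    if (length(validators)) {
      z_theta <- stats::qnorm((rank(theta, ties.method = "average") - 0.5) / n)
      for (v in names(validators)) {
        r <- 2 * sin(pi * validators[[v]] / 6)
        z <- r * z_theta + sqrt(1 - r^2) * stats::rnorm(n)
        q <- if (!is.null(marginals[[v]])) marginals[[v]] else stats::qnorm
        out[[v]] <- q(stats::pnorm(z))
      }
    }
    out
  })
}

#' Generate a population with injected differential item functioning
#'
#' Draws the latent trait, assigns exogenous group memberships, and
#' generates PCM responses in which the focal group (membership = 1) of the
#' DIF target item answers under shifted step parameters (uniform DIF:
#' every step moved by `shift` logits, so the focal group endorses the item
#' less readily at equal trait when `shift > 0`) and/or a trait-by-group
#' interaction (non-uniform DIF via the `slope` multiplier). All other
#' items are identical across groups.
#'
#' @param config a [synthetic_config()] with `dif_spec` present (a null
#'   `dif_spec` generates DIF-free data).
#' @return List with `responses` (coded `response_matrix`), `covariates`
#'   (data frame) and `theta` (latent draw).
#' @export
generate_dif_responses <- function(config) {
  with_seed(config$seed, {
    theta <- generate_latent(config$latent, config$n)
    cov <- generate_covariates(theta, validators = config$validators,
                               groups = config$groups,
                               marginals = config$validator_marginals)
    X <- unclass(generate_responses(theta, config$steps,
                                    item_ids = names(config$steps)))
    ds <- config$dif_spec
    if (!is.null(ds)) {
      focal <- cov[[ds$group]] == 1L
      d <- config$steps[[ds$item]] + (ds$shift %||% 0)
      th_f <- theta[focal] * (1 + (ds$slope %||% 0))
      p <- pcm_probs(th_f, d)
      cp <- matrixStats_cumsum(p)
      u <- stats::runif(sum(focal))
      X[focal, ds$item] <- as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
    }
    rm_out <- new_response_matrix(X, coded = TRUE,
                                  n_categories = vapply(config$steps, length, 1L) + 1L)
    list(responses = rm_out, covariates = cov, theta = theta)
  })
}

#' Simulate a complete synthetic study population
#'
#' Convenience wrapper running [generate_latent()], [generate_responses()]
#' (with DIF injection if configured) and [generate_covariates()] from one
#' seeded configuration.
#'
#' @param config a [synthetic_config()].
#' @return List with `responses`, `covariates`, `theta` and `truth` (the
#'   generating parameters, for recovery checks).
#' @export
simulate_population <- function(config) {
  sim <- generate_dif_responses(config)
  sim$truth <- list(steps = config$steps, latent = unclass(config$latent),
                    dif_spec = config$dif_spec,
                    validators = as.list(config$validators %||% list()),
                    groups = as.list(config$groups %||% list()),
                    seed = config$seed)
  sim
}
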