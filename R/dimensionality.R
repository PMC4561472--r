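#' Cronbach's alpha
#'
#' Internal-consistency coefficient on the raw coded item scores (complete
#' cases): `alpha = J/(J-1) * (1 - sum(var_i) / var(total))`.
#'
#' @param matrix a `response_matrix` or numeric matrix.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(matrix) {
  X <- stats::na.omit(unclass(matrix))
  J <- ncol(X)
  if (J < 2L) stop_fv("Cronbach's alpha needs at least 2 items")
  vt <- stats::var(rowSums(X))
  if (vt == 0) stop_fv("total score has zero variance")
  J / (J - 1) * (1 - sum(apply(X, 2L, stats::var)) / vt)
}

# Maximum covariance of two ordinal variables given their marginals:
# expectation under the comonotone (sorted-marginals) coupling.
max_covariance <- function(px, py, xv = seq_along(px) - 1,
                           yv = seq_along(py) - 1) {
  i <- 1L; j <- 1L
  pi_ <- px[1L]; qj <- py[1L]
  Exy <- 0
  while (i <= length(px) && j <= length(py)) {
    mass <- min(pi_, qj)
    Exy <- Exy + mass * xv[i] * yv[j]
    pi_ <- pi_ - mass; qj <- qj - mass
    if (pi_ <= 1e-12) { i <- i + 1L; if (i <= length(px)) pi_ <- px[i] }
    if (qj <= 1e-12) { j <- j + 1L; if (j <= length(py)) qj <- py[j] }
  }
  Exy - sum(px * xv) * sum(py * yv)
}

#' Loevinger's scalability coefficient H for polytomous items
#'
#' Mokken-style homogeneity: the ratio of observed inter-item covariances
#' to their maxima attainable given the item marginals (the comonotone
#' coupling). `H = 1` for perfect Guttman-ordered data, `H ~ 0` for
#' independent items; `H >= 0.4` is the conventional scalability cutoff.
#' Computed on complete cases; constant items are excluded with a warning.
#'
#' @param matrix a `response_matrix` or integer matrix.
#' @return A list with scale-level `H`, per-item `H_i` and the pairwise
#'   `H_ij` matrix.
#' @export
loevinger_h <- function(matrix) {
  X <- stats::na.omit(unclass(matrix))
  keep <- apply(X, 2L, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning("constant items excluded from H: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  J <- ncol(X)
  if (J < 2L) stop_fv("Loevinger's H needs at least 2 non-constant items")
  n <- nrow(X)
  obs <- stats::cov(X) * (n - 1) / n   # population covariances
  mx <- matrix(0, J, J, dimnames = dimnames(obs))
  for (i in seq_len(J - 1L)) for (j in (i + 1L):J) {
    px <- tabulate(X[, i] + 1L, nbins = max(X[, i]) + 1L) / n
    py <- tabulate(X[, j] + 1L, nbins = max(X[, j]) + 1L) / n
    mx[i, j] <- mx[j, i] <- max_covariance(px, py)
  }
  Hij <- obs / mx; diag(Hij) <- NA_real_
  ut <- upper.tri(obs)
  H <- sum(obs[ut]) / sum(mx[ut])
  Hi <- vapply(seq_len(J), function(i)
    sum(obs[i, -i]) / sum(mx[i, -i]), numeric(1))
  names(Hi) <- colnames(X)
  list(H = H, H_i = Hi, H_ij = Hij)
}

#' Parallel analysis for ordinal items
#'
#' Simulates `n_reps` datasets of independent items whose category
#' frequencies match the observed marginals, computes the eigenvalues of
#' each replicate's correlation matrix (same correlation type as the
#' observed analysis), and summarizes them per component. Observed
#' eigenvalues exceeding the chance band indicate real structure.
#'
#' @param matrix a coded `response_matrix`.
#' @param n_reps number of replicates, at least 20 (default 20).
#' @param seed integer seed (replicates are reproducible).
#' @param type correlation type, `"polychoric"` (default) or `"pearson"`.
#' @return List with per-component `mean`, `min`, `max`, the replicate
#'   `eigenvalues` matrix, and the settings used.
#' @export
parallel_analysis <- function(matrix, n_reps = 20L, seed = 1L,
                              type = c("polychoric", "pearson")) {
  type <- match.arg(type)
  if (n_reps < 20L) stop_fv("parallel analysis needs at least 20 replicates")
  X <- unclass(matrix)
  n <- nrow(X); J <- ncol(X)
  margs <- lapply(seq_len(J), function(j) {
    v <- X[!is.na(X[, j]), j]
    tabulate(v + 1L, nbins = max(v) + 1L) / length(v)
  })
  ev <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      S <- vapply(margs, function(p)
        sample.int(length(p), n, replace = TRUE, prob = p) - 1L,
        integer(n))
      R <- if (type == "polychoric") polychoric_matrix(S) else stats::cor(S)
      sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
           decreasing = TRUE)
    }, numeric(J)))
  })
  list(mean = colMeans(ev), min = apply(ev, 2L, min),
       max = apply(ev, 2L, max), eigenvalues = ev,
       n_reps = n_reps, seed = seed, type = type)
}

#' Three-criterion unidimensionality verdict
#'
#' Given observed eigenvalues and a parallel-analysis summary, evaluates:
#' (a) only the first component has an observed eigenvalue above 1;
#' (b) the first component explains more than 2/3 of total variance;
#' (c) the observed eigenvalue exceeds the simulated (chance) eigenvalue
#' for the first component only. Each criterion is always reported; the
#' overall verdict combines them per `rule` (`"all"` requires all three,
#' `"majority"` at least two — criterion (b) is a strict 2/3 bar that
#' large real scales can miss narrowly, so the rule is configurable).
#'
#' @param observed numeric vector of observed eigenvalues, sorted
#'   descending.
#' @param simulated parallel-analysis summary (list with `mean`) or a
#'   numeric vector of simulated mean eigenvalues.
#' @param rule `"all"` or `"majority"`.
#' @return List with `criterion_a`, `criterion_b`, `criterion_c`,
#'   `variance_share`, and logical `unidimensional`.
#' @export
unidimensionality_verdict <- function(observed, simulated,
                                      rule = c("all", "majority")) {
  rule <- match.arg(rule)
  sim_mean <- if (is.list(simulated)) simulated$mean else simulated
  J <- length(observed)
  a <- observed[1L] > 1 && all(observed[-1L] <= 1)
  share <- observed[1L] / sum(observed)
  b <- share > 2 / 3
  above <- observed > sim_mean
  c_ <- above[1L] && !any(above[-1L])
  n_pass <- sum(a, b, c_)
  list(criterion_a = a, criterion_b = b, criterion_c = c_,
       variance_share = share,
       unidimensional = if (rule == "all") n_pass == 3L else n_pass >= 2L,
       rule = rule)
}

#' Full dimensionality assessment
#'
#' Computes Cronbach's alpha, Loevinger's H, the eigenvalues of the
#' polychoric (or Pearson) correlation matrix, a parallel analysis, and
#' the three-criterion unidimensionality verdict.
#'
#' @inheritParams parallel_analysis
#' @param rule verdict rule, see [unidimensionality_verdict()].
#' @param alpha_cutoff,h_cutoff conventional acceptability cutoffs
#'   (defaults 0.7 and 0.4).
#' @return An object of class `dimensionality_report`.
#' @export
assess_dimensionality <- function(matrix, n_reps = 20L, seed = 1L,
                                  type = c("polychoric", "pearson"),
                                  rule = c("all", "majority"),
                                  alpha_cutoff = 0.7, h_cutoff = 0.4) {
  type <- match.arg(type); rule <- match.arg(rule)
  alpha <- cronbach_alpha(matrix)
  H <- loevinger_h(matrix)
  R <- if (type == "polychoric") polychoric_matrix(matrix)
       else stats::cor(stats::na.omit(unclass(matrix)))
  observed <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                   decreasing = TRUE)
  pa <- parallel_analysis(matrix, n_reps = n_reps, seed = seed, type = type)
  verdict <- unidimensionality_verdict(observed, pa, rule = rule)
  structure(list(alpha = alpha, alpha_acceptable = alpha >= alpha_cutoff,
                 H = H$H, H_acceptable = H$H >= h_cutoff,
                 H_i = H$H_i, H_ij = H$H_ij,
                 correlation = R, observed_eigenvalues = observed,
                 variance_share = verdict$variance_share,
                 parallel = pa[c("mean", "min", "max", "n_reps", "seed",
                                 "type")],
                 criterion_a = verdict$criterion_a,
                 criterion_b = verdict$criterion_b,
                 criterion_c = verdict$criterion_c,
                 unidimensional = verdict$unidimensional, rule = rule),
            class = "dimensionality_report")
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat("Dimensionality assessment\n")
  cat(sprintf("  Cronbach's alpha: %.3f (%s)\n", x$alpha,
              if (x$alpha_acceptable) "acceptable" else "below cutoff"))
  cat(sprintf("  Loevinger's H:    %.3f (%s)\n", x$H,
              if (x$H_acceptable) "acceptable" else "below cutoff"))
  cat(sprintf("  Observed eigenvalues: %s\n",
              paste(sprintf("%.2f", x$observed_eigenvalues), collapse = ", ")))
  cat(sprintf("  First-component variance share: %.1f%%\n",
              100 * x$variance_share))
  cat(sprintf("  Parallel analysis (%s, %d reps): simulated means %s\n",
              x$parallel$type, x$parallel$n_reps,
              paste(sprintf("%.2f", x$parallel$mean), collapse = ", ")))
  cat(sprintf("  Criteria: a=%s b=%s c=%s -> %s (rule: %s)\n",
              x$criterion_a, x$criterion_b, x$criterion_c,
              if (x$unidimensional) "unidimensional" else "not unidimensional",
              x$rule))
  invisible(x)
}
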