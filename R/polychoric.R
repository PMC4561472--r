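# Bivariate standard normal CDF, vectorized over (h, k) with common rho.
# Drezner-Wesolowsky identity: Phi2(h,k,rho) = Phi(h)Phi(k) +
#   (1/2pi) * int_0^rho exp(-(h^2 - 2 t h k + k^2)/(2(1-t^2)))/sqrt(1-t^2) dt,
# integrated by 32-node Gauss-Legendre. Accurate to ~1e-7 for |rho| <= 0.999.
pbvnorm <- function(h, k, rho) {
  rho <- max(min(rho, 0.9995), -0.9995)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  gl <- gauss_legendre_32()
  t_nodes <- 0.5 * rho * (gl$x + 1)          # map [-1,1] -> [0, rho]
  w <- 0.5 * abs(rho) * gl$w * sign(rho)
  hk <- h * k
  h2k2 <- h^2 + k^2
  acc <- 0
  for (i in seq_along(t_nodes)) {
    t <- t_nodes[i]
    acc <- acc + w[i] * exp(-(h2k2 - 2 * t * hk) / (2 * (1 - t^2))) /
      sqrt(1 - t^2)
  }
  base + acc / (2 * pi)
}

gauss_legendre_32 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # Golub-Welsch via the symmetric tridiagonal Jacobi matrix
      n <- 32L
      b <- (1:(n - 1)) / sqrt(4 * (1:(n - 1))^2 - 1)
      Jm <- diag(0, n)
      Jm[cbind(1:(n - 1), 2:n)] <- b
      Jm[cbind(2:n, 1:(n - 1))] <- b
      e <- eigen(Jm, symmetric = TRUE)
      cache <<- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
    }
    cache
  }
})

# Rectangle probabilities of a discretized bivariate normal with thresholds
# tau1, tau2 (finite interior cutpoints) and correlation rho.
binorm_cell_probs <- function(tau1, tau2, rho) {
  a <- c(-Inf, tau1, Inf)
  b <- c(-Inf, tau2, Inf)
  K1 <- length(a) - 1L; K2 <- length(b) - 1L
  # Phi2 on the grid of upper corners; +/-Inf collapse to marginals
  F2 <- function(x, y) {
    if (x == -Inf || y == -Inf) return(0)
    if (x == Inf && y == Inf) return(1)
    if (x == Inf) return(stats::pnorm(y))
    if (y == Inf) return(stats::pnorm(x))
    pbvnorm(x, y, rho)
  }
  G <- matrix(0, K1 + 1L, K2 + 1L)
  for (i in seq_len(K1 + 1L)) for (j in seq_len(K2 + 1L))
    G[i, j] <- F2(a[i], b[j])
  P <- G[-1L, -1L, drop = FALSE] - G[-nrow(G), -1L, drop = FALSE] -
    G[-1L, -ncol(G), drop = FALSE] + G[-nrow(G), -ncol(G), drop = FALSE]
  pmax(P, 1e-12)
}

# Two-step polychoric correlation for one pair: thresholds from the
# marginals, rho by maximizing the contingency-table likelihood.
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  cum_thresholds <- function(p) {
    cp <- cumsum(p / sum(p))
    cp <- cp[-length(cp)]                      # interior cutpoints only
    stats::qnorm(pmin(pmax(cp, 1e-12), 1 - 1e-12))
  }
  tau1 <- cum_thresholds(rowSums(tab))
  tau2 <- cum_thresholds(colSums(tab))
  nll <- function(r) -sum(tab * log(binorm_cell_probs(tau1, tau2, r)))
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-6)
  opt$minimum
}

#' Polychoric correlation matrix of ordinal items
#'
#' Pairwise two-step polychoric estimates: category thresholds are read off
#' the inverse-normal marginal frequencies of each item, and each pairwise
#' latent correlation maximizes the bivariate-normal likelihood of the
#' observed contingency table. Pairwise deletion handles missing values.
#' If the assembled matrix is not positive semi-definite it is repaired by
#' clipping eigenvalues at `1e-6` and rescaling to unit diagonal (recorded
#' in attribute `psd_repaired`).
#'
#' @param matrix a `response_matrix` or integer matrix of ordinal codes.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(matrix) {
  X <- unclass(matrix)
  J <- ncol(X)
  R <- diag(1, J)
  dimnames(R) <- list(colnames(X), colnames(X))
  for (i in seq_len(J - 1L)) for (j in (i + 1L):J) {
    r <- tryCatch(polychoric_pair(X[, i], X[, j]), error = function(e)
      stop_fv("polychoric estimation failed for pair (%s, %s): %s",
              colnames(X)[i] %||% i, colnames(X)[j] %||% j,
              conditionMessage(e)))
    R[i, j] <- R[j, i] <- r
  }
  ev <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  if (any(ev$values < 0)) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    repaired <- TRUE
  }
  attr(R, "psd_repaired") <- repaired
  R
}
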