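# Calibration of the "fast_bangladesh" synthetic preset.
#
# The preset must reproduce, at n = 12,000, the published FAST marginal
# response distributions (coded scale, percent per category) and the 46.7%
# share of households answering "never" to all nine items. The published
# tables give marginals, not generating parameters, so the generating step
# parameters are solved for here: given a candidate latent mixture, each
# item's four step parameters are fitted to its five-category marginal by
# quadrature; the floor weight of the latent mixture is then solved so the
# implied all-never share hits 0.467. The resulting constants are frozen
# into R/preset_fast.R.
#
# Run from the package root:  Rscript tools/calibrate_preset.R

for (f in list.files("R", full.names = TRUE)) source(f)

targets <- fast_reference_marginals() / 100

floor_mean <- -6; floor_sd <- 0.25
mu <- -0.3; sigma <- 1.4

grid <- seq(-12, 8, length.out = 401)

marg_for <- function(delta, w) colSums(w * pcm_probs(grid, delta))

fit_item <- function(target, w) {
  obj <- function(d) sum((marg_for(d, w) - target)^2)
  init <- log(pmax(target[-5], 1e-4) / pmax(target[-1], 1e-4))
  stats::nlminb(init, obj)$par
}

solve_preset <- function(p_floor) {
  spec <- latent_spec(p_floor, floor_mean, floor_sd, mu, sigma)
  dens <- latent_density(spec, grid)
  w <- dens / sum(dens)
  steps <- apply(targets, 1L, fit_item, w = w, simplify = FALSE)
  p0 <- vapply(steps, function(d) pcm_probs(grid, d)[, 1L], numeric(length(grid)))
  all_never <- sum(w * apply(p0, 1L, prod))
  list(steps = steps, all_never = all_never, weights = w)
}

root <- stats::uniroot(function(p) solve_preset(p)$all_never - 0.467,
                       c(0.05, 0.46), tol = 1e-5)
p_floor <- root$root
sol <- solve_preset(p_floor)

cat(sprintf("p_floor = %.4f, all-never = %.4f\n", p_floor, sol$all_never))
fit <- t(vapply(sol$steps, function(d) marg_for(d, sol$weights), numeric(5)))
cat("max abs marginal deviation (pct points):",
    round(100 * max(abs(fit - targets)), 3), "\n")

cat("\nsteps matrix for R/preset_fast.R:\n")
m <- round(t(vapply(sol$steps, identity, numeric(4))), 4)
for (i in seq_len(nrow(m)))
  cat(sprintf("    c(%s)%s\n", paste(sprintf("%.4f", m[i, ]), collapse = ", "),
              if (i < nrow(m)) "," else ""))
cat(sprintf("p_floor: %.4f\n", p_floor))
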