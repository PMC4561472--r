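---
title: "Validating polytomous food insecurity scales with fastvalid"
author: "fastvalid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating polytomous food insecurity scales with fastvalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastvalid)
```

## The measurement problem

Household food insecurity has no direct physical gauge. Experience-based
Likert instruments such as the 9-item Food Access Survey Tool (FAST) ask a
respondent how often, over a recall window, the household lived through
progressively harsher coping experiences — worrying about food, eating
less-preferred grains, skipping meals, buying rice in small frequent
amounts, taking food on credit — each answered on a 5-point frequency
scale (never / rarely / sometimes / often / mostly, coded 0–4). The
working hypothesis is that these experiences are ordered expressions of a
single underlying severity continuum, so that a simple summed score can
rank households by food insecurity. That hypothesis is exactly what a
validation analysis has to earn, and `fastvalid` implements the full
chain of evidence: item response model fit, unidimensionality,
monotonicity, measurement invariance, interpretable item-category
severities, and external construct validity.

## The partial credit model

The core engine is the partial credit model (PCM), the polytomous
extension of the Rasch model. For a household with latent severity
$\theta$ (logit scale) and an item with step parameters
$\delta_1, \dots, \delta_m$, adjacent response categories follow a step
logistic model, giving

$$P(X = x \mid \theta) \;=\;
  \frac{\exp \sum_{k \le x} (\theta - \delta_k)}
       {\sum_{h=0}^{m} \exp \sum_{k \le h} (\theta - \delta_k)},$$

with the empty sum equal to zero. Two properties motivate this choice
over more heavily parameterized ordinal models: the raw total score is a
sufficient statistic for $\theta$, which is what licenses summed-score
rankings in the field, and with a single step the model collapses to the
dichotomous Rasch model. `pcm_probs()` evaluates this kernel with
log-sum-exp stabilization and is exercised in the tests out to
$|\theta| = 50$.

### Estimation

`fit_pcm()` estimates the steps by marginal maximum likelihood: the
latent trait is integrated out over a normal distribution with mean fixed
at zero (identification) and standard deviation estimated. The EM
algorithm works on a fixed quadrature grid — 61 equally spaced nodes on
$[-10, 10]$ by default — with the normal weights renormalized on the
grid. We deliberately use a fixed grid rather than one rescaled by the
current $\sigma$ estimate: with a moving grid the E- and M-steps optimize
different discretized models from one iteration to the next and the
monotone-ascent guarantee of EM is lost, whereas on a fixed grid every
M-step (quasi-Newton for each item's steps, exact one-dimensional search
for $\sigma$) provably never decreases the marginal log-likelihood. The
test suite asserts this ascent on every fitted trace. Convergence is
declared when the relative log-likelihood change drops below $10^{-6}$
(cap: 500 iterations). Missing responses simply drop out of the
likelihood (missing at random given $\theta$); an item category never
observed in the data is inestimable and is merged with its lower
neighbour under the default `policy = "collapse"` (recorded in the fit),
or aborts under `policy = "strict"`.

At the simulation sizes used throughout the tests (n = 2000, 9 items,
5 categories) a fit takes on the order of a second and recovers
generating steps with RMSE well under 0.15 logits and negligible bias.

### Person scores and fit statistics

`person_scores()` returns raw totals and EAP (posterior mean) trait
estimates; under the PCM, complete-response households with equal totals
receive identical EAPs, and the tests verify this sufficiency property to
numerical precision against a fine-grid integration oracle.

`item_fit_statistics()` computes infit and outfit mean squares from
standardized residuals $z = (x - E)/\sqrt{W}$ at the EAP estimates.
Outfit is the plain mean of $z^2$; infit weights by the model variance
$W$, concentrating on households near the item's severity, which is why
food-security practice favours it. Because the published convention
reports fit *per item category*, the package attributes a statistic to
each step $k$ using the adjacent-category-pair convention: households
answering in $\{k-1, k\}$ face a conditional dichotomous Rasch step
$P(X = k \mid X \in \{k-1,k\}) = \mathrm{logis}(\theta - \delta_k)$, and
the step's Mnsq is computed from those conditional residuals. This
convention is a documented package choice — the reference analyses plot
per-category infit without defining the residual grouping — and it is the
quantity the null-calibration test gates on: with data simulated from the
fitted model at n = 5000, at least 90% of the 36 item-category infits lie
in $[0.9, 1.1]$. The per-item *aggregate* Mnsq is also reported but is
known to sit conservatively below 1 when $\theta$ is estimated by EAP
from few items (shrinkage correlates the residual with the estimate);
flagging decisions should use the category-level statistics and the
conventional windows, 0.7–1.3 (acceptable) and 0.8–1.2 (recommended).

### Item category severity

Step parameters locate intersections of adjacent category curves and need
not be ordered, so they are poor severity summaries.
`thurstonian_thresholds()` instead solves
$P(X \ge k \mid \gamma_k) = 0.5$ by bracketed root finding (tolerance
$10^{-6}$ logits on $[-50, 50]$); these thresholds are strictly
increasing in $k$ by construction of the cumulative curves and order
item-categories along the severity continuum.

## Assumption checks

**Unidimensionality** (`assess_dimensionality()`) combines Cronbach's
$\alpha$ (cutoff 0.7) on the raw coded scores, Loevinger's $H$ (cutoff
0.4) computed as the ratio of observed inter-item covariances to their
maxima under the comonotone coupling of the marginals, and a principal
component analysis of the polychoric correlation matrix with parallel
analysis. Polychoric correlations use the standard two-step pairwise
estimator — thresholds from inverse-normal marginals, then the latent
correlation by maximizing the bivariate-normal contingency likelihood
(the bivariate normal CDF is evaluated by 32-node Gauss–Legendre
quadrature of the Drezner–Wesolowsky identity, accurate to about
$10^{-7}$, and tested against an independent integration oracle).
Parallel analysis resamples each item independently from its observed
marginals (chance-only correlation), 20 replicates by default, same
correlation type as the observed analysis. Three criteria are evaluated:
(a) only the first observed eigenvalue exceeds 1; (b) the first component
explains more than 2/3 of total variance; (c) observed exceeds simulated
for the first component only. Criterion (b) is a strict bar that real
scales can miss narrowly (a first component at 65.7% fails it by one
point), so the overall verdict rule is configurable (`"all"`, the
default, or `"majority"`); each criterion is always reported separately
so a marginal (b) is surfaced rather than silently absorbed. On raw-score
alpha versus polychoric-based ordinal alpha, the package defaults to raw
scores and exposes the choice.

**Monotonicity** (`check_monotonicity()`) is the Mokken-style manifest
check: for each item, $P(X \ge k)$ must be non-decreasing in the rest
score. Respondents are partitioned into rest-score groups of at least
`minsize` members (ties never split); for every ordered group pair and
category, a comparison is *active* when both proportions are strictly
inside $(0,1)$, a *violation* when the lower group's proportion exceeds
the higher group's, and *significant* under a one-sided unpooled
two-proportion z-test at $\alpha = 0.05$. The bundled sweep uses
`minsize` of N/10 (the recommended level for large samples) plus the
stricter N/50 and N/500; shrinking `minsize` raises the number of groups
and active comparisons — and with them the share of sampling-error
violations in the sparse upper tail, which is why significant violations
at N/10 are the headline figure. The z-test variant is a package choice;
the classical implementations of this check use related normal
approximations without a single canonical form.

**Measurement invariance** (`dif_analysis()`) tests each item for
differential item functioning across binary, trait-exogenous groupings
(literacy, age band, land ownership, household size in the bundled
preset) with nested cumulative-logit models: model 1 regresses the
cumulative log odds on the total score; model 2 adds group and
total-by-group interaction, capturing uniform and non-uniform DIF
jointly. Proportional odds is tested first (a Brant-type LR on the
stacked splits with shared versus free slopes); items that reject it are
fit in the generalized family — independent binary logistic fits per
cumulative split with summed log-likelihoods, df = 2 per split — and the
rest in the proportional family via `MASS::polr`, df = 2. The matching
variable is the full total score (a rest-score option exists but is off
by default). Effect size is the pseudo-$R^2$ difference between the
models, McKelvey–Zavoina by default (Nagelkerke optional): practical
significance requires a difference of at least 13 percentage points,
while statistical significance alone is expected — and innocuous — at
large n. One numerical guard matters with floor-heavy data: a sparse top
split can separate numerically, which drives its latent-scale variance
(hence its MZ $R^2$) to 1; such splits are excluded from the $R^2$
aggregation in both models symmetrically (the LR keeps every split, its
deviance being finite). No multiple-testing correction is applied, by
design: verdicts separate "statistical-only" from "practical" instead.

**External validity** (`external_validity()`) tests the direction of
association between the total score and continuous validators — wealth
index, women's dietary diversity score (WDDS), body mass index — with a
Cuzick-type nonparametric trend test (group scores are the total-score
values, the validator is ranked, the statistic is standardized with tie
correction; a Spearman-based z is available as an alternative, and the
two agree closely on these data). Wealth and WDDS are additionally
summarized over empirical quartiles, BMI over the fixed cutoffs 18.5 and
25 kg/m².

## The synthetic population

Because the original trial data are not deposited, the package ships a
calibrated generator. Zero inflation is modeled in the *latent*
distribution, not the response mechanism: the trait is a two-component
mixture of a narrow "food-secure floor" component (mean −6 logits,
SD 0.25) and an at-risk normal component (mean −0.3, SD 1.4), so the PCM
remains the true item model conditional on $\theta$ and parameter
recovery stays well defined. The `fast_bangladesh` preset's step
parameters were solved (see `tools/calibrate_preset.R`) so that the
implied marginal category frequencies match the reference marginal
distribution of the Bangladesh sample the instrument was validated in,
and the floor weight (0.2189) was solved so that 46.7% of simulated
households report "never" on all nine items. At n = 12,000 a simulated
population reproduces every item's "never" share within half a
percentage point and the all-never share within Monte Carlo error.

Covariates are tied to the trait by a Gaussian copula: validators are
monotone transforms of normals correlated with the normal scores of
$\theta$ (Pearson $2\sin(\pi\rho_s/6)$ for a Spearman target $\rho_s$),
so realized rank correlations match their targets within ±0.02 at large
n. The preset targets $-0.5$ (wealth), $-0.2$ (WDDS) and $-0.1$ (BMI)
are assumptions, chosen once to reproduce the *ordering* of the
published associations (wealth strongest, BMI weakest); the reference
study reports trend statistics, not correlations. Binary groupings are
drawn independently of the trait (exogenous) with realistic prevalences.
DIF injection shifts all steps of one item by a constant for the focal
group (uniform DIF) and/or scales the focal group's trait inside that
item's kernel (non-uniform DIF).

What the generator does *not* emulate: informative missingness (only
MCAR is available), household clustering and survey design, local
dependence among items, and any misfit of the PCM itself. Passing tests
on synthetic data therefore demonstrate that the pipeline's statistics
do what they claim under the model and the calibrated marginals — not
that any real dataset satisfies the model.

## Numerical and design choices

- Quadrature: 61 nodes on $[-10, 10]$, wide enough to cover the preset's
  floor at −6 with an estimated latent SD around 1.7.
- EM convergence: relative log-likelihood change $< 10^{-6}$, maximum
  500 iterations; step updates warm-started BFGS with analytic
  gradients.
- Root finding (thresholds): `uniroot` at $10^{-6}$ logits.
- Polychoric: pairwise deletion, PSD repair by eigenvalue clipping at
  $10^{-6}$ with rescaling to unit diagonal (flagged on the result).
- Ties: quartile boundaries assign ties to the lower bin; rest-score
  groups never split tied values.
- Determinism: every stochastic entry point takes a seed and restores
  the caller's RNG state; identical seeds give byte-identical JSON
  reports.
- Test problem sizes (n = 2000–12,000, 20 replicates for recovery and
  monotonicity, 500 for the DIF null) were chosen as the smallest sizes
  at which the asymptotic approximations under test are expected to
  hold cleanly.

## Known limitations

- Estimation is MML-EM with a normal latent assumption only; CML and JML
  are out of scope, as are 2PL, graded-response and generalized partial
  credit models.
- The latent mixture of the preset violates the fitting model's normal
  assumption by design; fitted step parameters on preset data are
  therefore quasi-parameters (the fit remains useful for fit statistics
  and scoring, and the validation verdicts are unaffected).
- Local independence is not tested — consistent with standard practice
  in this literature, it is assumed and indirectly supported by fit
  statistics.
- The DIF stage tests binary groupings only, without purification or
  anchor selection.

## A worked run

```{r, eval = FALSE}
sim <- simulate_population(fast_bangladesh_config(n = 12000, seed = 1))
report <- run_full_validation(sim$responses, sim$covariates, seed = 2)
print(report)
write_validation_report(report, "report")
```

The report object carries every stage (summary, PCM fit, fit statistics,
thresholds, dimensionality, monotonicity, DIF, external validity) plus a
machine-readable verdict block; stages lacking inputs are skipped with a
recorded reason rather than failing the run.
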