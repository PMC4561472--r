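# fastvalid

Psychometric validation of polytomous Likert-type food insecurity scales,
built around the 9-item **Food Access Survey Tool (FAST)** used to measure
household food insecurity in rural Bangladesh.

Experience-based scales ask households how often (never / rarely /
sometimes / often / mostly, coded 0–4) they lived through coping
experiences of increasing harshness — worrying about food, eating
less-preferred grains, skipping meals, taking food on credit. Before a
simple summed score over such items can be trusted to rank households by
food insecurity, the scale must earn it: the items must fit a Rasch-family
model, measure one dimension, be monotone in the trait, behave identically
across demographic subgroups, and correlate the right way with external
indicators. `fastvalid` implements that entire chain of evidence.

## The model

The core is the **partial credit model** (PCM), the polytomous Rasch
model. For a household at latent severity θ (logit scale) and an item with
step parameters δ₁…δₘ:

    P(X = x | θ) = exp( Σ_{k≤x} (θ − δ_k) ) / Σ_{h=0}^{m} exp( Σ_{k≤h} (θ − δ_k) )

Estimation is marginal maximum likelihood (EM over a normal latent trait,
mean fixed at 0, SD estimated). Around the fit, the package provides:

- **Fit statistics** — infit/outfit mean squares per item and per item
  category (adjacent-pair convention), with the conventional 0.7–1.3 and
  0.8–1.2 windows.
- **Item category severity** — Thurstonian thresholds γ_k solving
  P(X ≥ k | γ_k) = 0.5, strictly increasing in k.
- **Unidimensionality** — Cronbach's α, Loevinger's H (comonotone-coupling
  maximum covariances), PCA of the polychoric correlation matrix with
  parallel analysis and a three-criterion verdict.
- **Monotonicity** — Mokken-style manifest check of P(X ≥ k) over
  rest-score groups at minsize N/10, N/50, N/500, with active comparisons,
  violations, and one-sided z-test significance.
- **Measurement invariance (DIF)** — nested cumulative-logit models
  (total score vs total + group + interaction), proportional-odds routing,
  likelihood-ratio tests and pseudo-R² effect sizes with a 13-point
  practical-significance bar.
- **External validity** — Cuzick-type nonparametric trend tests of the
  total score against wealth, dietary diversity and BMI.
- **A calibrated synthetic population** — `fast_bangladesh_config()`
  reproduces the reference sample's marginal response distributions and
  its 46.7% all-"never" share at n = 12,000, with copula-linked
  validators and optional DIF injection, so the whole pipeline is testable
  without the original trial data.

## Worked example

```r
library(fastvalid)

sim <- simulate_population(fast_bangladesh_config(n = 12000, seed = 1))
report <- run_full_validation(sim$responses, sim$covariates, seed = 2)
print(report)
```

```
== Scale validation report ==
Respondents: 12000 (floor share 47.0%)
Partial credit model fit (MML-EM): 12000 respondents, 9 items
  log-likelihood -56102.08 after 69 iterations (converged), latent SD 1.682
  item1: 2.909, 1.897, 3.680, 3.054
  ...
Verdicts:
  fit_acceptable             TRUE
  unidimensional             TRUE
  alpha_acceptable           TRUE
  h_acceptable               TRUE
  monotone                   TRUE
  dif_practical              FALSE
  dif_statistical            TRUE
  external_negative_trends   TRUE
```

Reading the output: 47.0% of simulated households report no insecurity
experience at all (the scale's floor). On this population Cronbach's α is
0.874 and Loevinger's H is 0.614, the first polychoric principal component
carries 72.8% of the variance (eigenvalues 6.55, 0.39, 0.34, …) and only
it beats the parallel-analysis chance band — the scale is unidimensional
by all three criteria. No significant monotonicity violations occur at
minsize N/10. Several item-by-grouping DIF tests are statistically
significant (expected at n = 12,000) but every effect size stays far below
the 13-point practical bar. The trend tests give z = −43.4 (wealth),
−19.1 (dietary diversity) and −8.7 (BMI): more food-insecure households
are poorer, eat less diversely, and have thinner women — the expected
external-validity pattern. Item-category severities are interpretable:
"purchase rice often" becomes likely already at mild severity
(γ_rarely = 0.53 logits) while "have to eat other grains" requires far
harsher conditions (γ_rarely = 2.98).

`write_validation_report(report, "report/")` writes `report.json`,
`report.txt` and CSV tables (marginals, fit statistics, eigenvalues,
monotonicity, DIF, trends); identical seeds give byte-identical JSON.

A thin CLI over the same functions lives at `inst/cli/fastvalid.R`
(`simulate`, `fit`, `validate` subcommands).

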