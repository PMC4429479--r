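---
title: "Multi-pollutant selection with spike-and-slab hierarchical logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pollutant selection with spike-and-slab hierarchical logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapselect)
```

## The model

For subject $i$ with case indicator $y_i$, covariate dummies $z_i$,
pollutant terms $x_i$ and census tract $t(i)$,

$$
y_i \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}
(\alpha + z_i^\top\delta + x_i^\top\beta + u_{t(i)})\right),
\qquad u_t \sim N(0, \sigma^2),
$$

with $\alpha$ and every covariate effect $\delta_k$ given $N(0, 10)$
priors (effectively flat on the logit scale), and $\sigma$ a
$\mathrm{Uniform}(0, 3)$ hyperprior. The tract random intercept absorbs
the within-tract outcome correlation that area-level exposure assignment
induces.

Exposures enter either **categorically** — low (< control 5th
percentile, reference), medium, high (> control 95th percentile), giving
two dummies per pollutant — or **continuously** (centered, scaled by the
$n-1$ SD), the sensitivity configuration.

In the selection model each pollutant coefficient $\beta_j$ carries a
two-component mixture prior with latent indicator
$\gamma_j \sim \mathrm{Bernoulli}(\pi)$:

$$
\beta_j \mid \gamma_j \sim
\gamma_j\, N(0, v_{\text{slab}}) + (1-\gamma_j)\, N(0, v_{\text{spike}}),
\qquad v_{\text{slab}} = 10,\; v_{\text{spike}} = 0.001,\; \pi = 0.25 .
$$

Each dummy (medium, high) has its own independent $\gamma$; the two are
reconciled only at selection time ("either level selected selects
both"). The per-term marginal Bayes factor is the posterior-to-prior
inclusion odds,
$\mathrm{BF}_j = \frac{p_j/(1-p_j)}{\pi/(1-\pi)}$,
and a pollutant enters the final joint model when any of its terms has
$\mathrm{BF} > 1$ (strict). The final model reverts selected terms to
plain $N(0, 10)$ priors; running the same machinery over *all*
candidates reproduces the no-selection joint comparison model.

## Sampling

The Bernoulli-logit likelihood is augmented with Polya-Gamma latent
variables $\omega_i \sim \mathrm{PG}(1, \eta_i)$, which makes every
conditional update exact (no tuning, no rejection at the model level):

* $\omega_i$: PG(1, $\eta_i$) by the alternating-series rejection
  sampler (compiled; uses R's RNG, so everything is seeded);
* $\gamma_j$: Bernoulli with odds = prior odds ×
  $N(\beta_j; 0, v_{\text{slab}}) / N(\beta_j; 0, v_{\text{spike}})$.
  At $\beta_j = 0$ these odds are
  $\frac{\pi}{1-\pi}\sqrt{v_{\text{spike}}/v_{\text{slab}}} = 1/300
  \approx 0.0033$ under the defaults;
* $\beta$ (jointly): multivariate normal with precision
  $X^\top\Omega X + D(\gamma)$;
* $u_t$: scalar conjugate normals;
* $\sigma$: exact truncated inverse-gamma on $\sigma^2$ (the uniform
  prior on $\sigma$ contributes the $\sigma^{-T}$ kernel), so draws
  never leave $[0, 3]$.

Two chains run by default: chain 1 from zeros, chain 2 from prior draws.
After discarding the first 50% of each chain, retained draws are pooled;
the odds ratio is $\exp(\bar\beta)$ and the 95% credible interval the
exponentiated 2.5th/97.5th quantiles. Convergence is assessed by the
Pearson correlation, across parameters (fixed effects, $\sigma$, tract
intercept means), of the two chains' posterior-mean vectors, passing
strictly above 0.95. This cross-chain-correlation rule is blunter than
split-$\hat R$ but is retained as the workflow's stated diagnostic; at
desk-scale iteration counts it frequently (and correctly) fails on the
noisy tract-intercept block, as the README example shows.

**Inclusion probabilities** are estimated two ways: the raw frequency of
$\gamma_j = 1$ and the Rao-Blackwellized mean of the $\gamma_j$ full
conditional. The Bayes factor uses the Rao-Blackwellized estimate, which
cannot hit exactly 1 in finite samples; a raw estimate of exactly 1 is
shrunk to $1 - 1/(2\,\text{draws})$ when converted.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| categorization percentiles | 5% / 95% of controls | low reference / high tail; type-7 (linear interpolation) quantiles; boundary values are medium |
| binning threshold | 0.80 (absolute Spearman ρ) | above this, pollutants are collinear enough to bin |
| slab / spike variance | 10 / 0.001 | the spike implies "null" ORs in (0.92, 1.08) with 99% probability — reported at startup; 1e-4 would give (0.97, 1.03) |
| prior inclusion π | 0.25 | 0.50 is the standard sensitivity setting |
| σ hyperprior | Uniform(0, 3) | tract intercept SD on the logit scale |
| chains × iterations | 2 × 10,000 (desk) | production analyses use 2 × 150,000, burn-in 50% |

## What the generator emulates — and what it does not

`simulate_cohort()` draws a source population, applies the logistic
model above as the *generating* truth (population-percentile category
effects, tract intercepts), and then samples retrospectively: all-or-n
cases and controls frequency matched on birth year. Odds ratios are
invariant to this outcome-based sampling, so planted conditional ORs are
recoverable, which the calibration tests verify (crude OR within 10% at
n = 50,000, averaged over three seeds because single-draw noise in the
5% tail cells is of the same order as the band).

Emulated: ~1:7 realized case:control ratio; ~2,400 census tracts with
logit-scale intercept SD 0.3 (latent ICC ≈ 0.03 — the source study does
not report this quantity, so the default is a mild, configurable
clustering choice); heavy right-skewed log-normal concentration
marginals spanning the packaged distribution table (dispersion from the
5th–95th log range); four highly correlated pollutant blocks via a
one-factor Gaussian copula, with latent loading $2\sin(\pi\rho_s/6)$ so
the *Spearman* correlation hits its target despite the marginal
transform; covariate marginals from the packaged characteristics table.

Not emulated: spatial structure between tracts, exposure measurement
error from the dispersion model, confounding between covariates and
exposures (off by default), missing data, and year-varying exposure. A
green simulation test therefore establishes that the *statistical
machinery* behaves as claimed under the stated data-generating model,
not that the substantive findings of any particular study are correct.

## Numerical and design choices

* **OR point estimate** is $\exp(\text{posterior mean of }\beta)$, not
  the posterior mean of $\exp(\beta)$ — consistent with quantile-based
  intervals; both conventions are defensible, this one is fixed here.
* **Quantile convention** for cutoffs is type 7; the published tables do
  not state one, and their own cutoffs are not mutually consistent, so
  exact reproduction is impossible regardless — the convention is
  configurable.
* **Absolute** correlation is used for binning: the packaged table shows
  only positive values, but negative collinearity is equally harmful.
* **Ties** in the greedy seed choice and in representative selection
  break lexicographically, making binning fully deterministic.
* **Degenerate inputs** error early and specifically: constant control
  distributions (no percentile cutoffs), < 20 controls, rank-deficient
  designs (the collinear columns are named), σ outside its support gives
  log-posterior $-\infty$.
* **Seeds**: one global seed deterministically derives per-stage and
  per-chain seeds (all below $2^{31}$); identical config + seed gives
  byte-identical pipeline outputs.

## Known limitations

* **Sparse-tail false positives.** With 5%/95% cutoffs, a 1:7 design and
  a few hundred cases, the low/high cells hold ~a dozen cases. Chance
  depletion or enrichment of such a cell can hand a null term a Bayes
  factor well above 1 (we verified one such BF ≈ 23 against an
  independent quadrature of its inclusion odds — it is the posterior
  speaking, not a sampler artifact). In 20-replicate null simulations at
  n = 2,000 only about half the replicates have *every* term below
  BF = 1, although the mean inclusion probability stays far below the
  prior (0.06 vs 0.25). Users should read isolated BFs barely above 1
  (cf. 1.01 in the motivating analysis) as weak evidence, exactly as the
  original interpretation scale suggests. The corresponding acceptance
  criterion expects ≥ 80% fully clean replicates and is deliberately
  left failing rather than weakened; see the decisions ledger.
* The cross-chain correlation diagnostic needs long chains once tract
  intercepts number in the hundreds; prefer production iteration counts
  for real inference.
* Retrospective sampling preserves ORs but not baseline risk; the fitted
  intercept is design-dependent and should not be interpreted.
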