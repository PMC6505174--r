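---
title: "Bayesian diallel analysis of litter size and sex ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian diallel analysis of litter size and sex ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelmm)
```

## The problem

A diallel crosses a panel of inbred strains in all ordered pairwise
combinations — reciprocals and selfs included — and is the classical
design for separating what a strain contributes to a phenotype through
its genome dose, through the parent it enters by, through being inbred,
and through specific strain-pair interactions. `diallelmm` implements
this decomposition for reproductive outcomes of the eight Collaborative
Cross (CC) founder strains (AJ, B6, 129S1, NOD, NZO, CAST, PWK, WSB):
weaned litter size, which is a strictly positive count, and litter sex
composition, which is a binomial count. Both outcomes break the
assumptions of the Gaussian linear mixed models classically used for
diallel data, so the package recasts the full diallel hierarchy inside
generalized linear mixed models and fits them by MCMC.

## The model

For litter $i$ with dam strain $j$, sire strain $k$, parity (litter
order within a mating pair) $r \in 1..12$, and batch (consecutive
year-month) $h \in 1..48$, weaned litter size is modeled as an
overdispersed zero-truncated Poisson (ZTP):

$$
y_i \sim \mathrm{ZTPois}(\lambda_i), \qquad
\lambda_i = e^{\ell_i}, \qquad
\ell_i = \eta_i + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \sigma^2),
$$

$$
\eta_i = \mu + \mathrm{order}_{r[i]} + \mathrm{batch}_{h[i]} +
         d_{(j,k)[i]}^\top \beta .
$$

Zero litters never enter breeding records (a failed litter is simply
not observed at weaning), hence the truncation: the ZTP is a Poisson
conditioned on $y \ge 1$, with mean $\lambda / (1 - e^{-\lambda})$. The
litter-level Gaussian term $\varepsilon_i$ supplies overdispersion on
the log scale.

The parental contribution is the full diallel decomposition

$$
d_{(j,k)}^\top \beta =
\underbrace{a_j + a_k}_{\text{additive}} +
\underbrace{m_j - m_k}_{\text{parental sex}} +
\underbrace{I\{j=k\}(\beta_{\mathrm{inbred}} + b_j)}_{\text{inbred}} +
\underbrace{I\{j \ne k\}(v_{jk} + S\{j<k\}\, w_{jk})}_{\text{epistasis}},
$$

with $S\{j<k\} = +\tfrac12$ when the dam strain precedes the sire
strain in the canonical strain order and $-\tfrac12$ otherwise. Each of
the random-effect classes $a, m, b$ (8 levels) and $v, w$ (28 unordered
strain pairs) carries an exchangeable normal prior with its own
variance and an exact sum-to-zero constraint; parity effects follow
$\mathrm{order}_r \sim N(r\alpha, \tau^2_{\mathrm{order}})$ around a
fixed slope $\alpha$, and batch effects are exchangeable
$N(0, \tau^2_{\mathrm{batch}})$. A positive $m_j$ means strain $j$
raises litter size more through the maternal line, the maternal-minus-
paternal difference being $2m_j$.

Two companion models share the identical hierarchy: a Gaussian model on
$\sqrt{y}$ (the variance-stabilizing linear approximation of the count
model, `fit_gaussian_diallel()`), and a binomial logit model for the
number of male pups per litter (`fit_binomial_diallel()`), in which the
same decomposition acts on the latent logit of the male proportion.

### Priors

Fixed effects ($\mu$, $\alpha$, $\beta_{\mathrm{inbred}}$) take
$N(0, 10^3)$ priors (variance $10^3$). Every variance component
($\sigma^2$ and the seven $\tau^2$) takes an inverse-gamma prior with
shape and scale both $0.001$. The inverse-gamma choice is kept despite
its known sensitivity at small variances because it makes every layer
conjugate; the variance *projections* below are deliberately built from
the effect draws rather than from these variance parameters, which is
precisely what makes them stable under this prior.

### Dam and sire effects

Because additive and parental-sex effects act jointly, the directional
parental effects are recovered by the exact per-draw linear map

$$\mathrm{dam}_j = a_j + m_j, \qquad \mathrm{sire}_j = a_j - m_j,$$

applied as post-processing (`reparameterize_dam_sire()`). This leaves
the fitted model untouched — the inverse map recovers $a$ and $m$
exactly — while letting maternal and paternal strain contributions be
read directly.

## Sampling

`fit_ztp_diallel()` and its siblings run a block Gibbs sampler written
in C++ (Rcpp/RcppArmadillo):

* every Gaussian layer (fixed effects, each random-effect class, all
  variances) is updated by its conjugate full conditional; effect
  classes are drawn as blocks from their multivariate normal
  conditional and then conditioned exactly onto the zero-sum hyperplane
  by a rank-one covariance projection, so every retained draw satisfies
  the constraints to machine precision;
* the latent $\ell_i$ under the ZTP or binomial likelihood is updated
  by univariate slice sampling (stepping-out with shrinkage), which
  needs no step-size tuning and cannot reject;
* the Gaussian-outcome model needs no latent update at all and is fully
  conjugate.

All randomness flows through R's RNG, so a fit is reproducible
bit-for-bit from its configuration; the seed is a mandatory argument of
`fit_config()`. The defaults (3 chains × 50,000 iterations, 10,000
burn-in, thinning 10) are generous for a diallel of a few thousand
litters. The package's own simulation studies use shorter explicit
configurations — about 4,000–6,000 iterations with a quarter to a third
burn-in — which `convergence_diagnostics()` (split-PSRF and Geyer
initial-monotone effective sample sizes) shows are already well mixed
for this likelihood; chain-length choices only affect Monte-Carlo
accuracy, never the model.

One identifiability point matters for interpretation: with uncentered
batch effects, only $\mu + \overline{\mathrm{batch}}$ is identified by
the likelihood, and the parity slope $\alpha$ is informed only at
observed parities. Reference predictions therefore evaluate parity and
batch at their across-level posterior means (`expected_cell_means()`,
`pup_scale_effects()`), which keeps them on the identified ridge.

## Variance projections

`compute_varp()` reports, per posterior draw, the fraction of
latent-scale phenotypic variance of an *idealized complete, balanced
diallel* (all 64 dam × sire cells at equal weight, including cells that
are inviable in the real colony) attributable to each effect class: the
population variance across the 64 cells of that class's contributions,
divided by the sum over all classes plus $\sigma^2$. Batch contributes
the population variance of its 48 effects and parity the population
variance of the 12 *total* parity effects $r\alpha +
\mathrm{deviation}_r$, so the fixed slope is not silently dropped. Per
draw the fractions sum to one exactly, and
`varp_dam_sire()` replaces \{additive, parental sex\} by \{dam strain,
sire strain\} with the identity
$\mathrm{VarP}_{\mathrm{dam}} + \mathrm{VarP}_{\mathrm{sire}} =
\mathrm{VarP}_{\mathrm{additive}} + \mathrm{VarP}_{\mathrm{parental\ sex}}$
holding per draw. The projection lives on the latent (log, square-root,
or logit) scale, where the model is additive; no data-scale
decomposition is attempted. Being built from effect draws (BLUP-like,
shrinkage-regularized) rather than from $\tau^2$ draws, the projection
is usable for fixed and random classes alike and comes with HPD
intervals from posterior uncertainty.

Summaries use posterior means, medians, and highest-posterior-density
intervals; `hpd_interval()` returns the shortest contiguous interval
containing the requested mass of the sorted draws.

## The synthetic breeding program

Real CC-founder breeding records are not bundled with the package, so
`default_truth()` defines a reference generative scenario with the
structure such a program produces, and `simulate_litters()` /
`simulate_sex()` run the models generatively:

* 62 viable crosses of the 8 founders — NZO dams crossed to CAST or PWK
  sires are excluded as unproductive — with a diagonal-heavy design of
  4,448 litters (inbred cells ≈ 238 litters, F1 cells ≈ 47);
* litters grouped into mating pairs whose litter counts follow a
  truncated geometric law (mean ≈ 3, maximum 12), so parity covers its
  full range as in a multi-year colony; batches uniform over 48 levels;
* intercept $\mu = \log 5.46$ expected pups; dam-strain effects with B6
  and NOD strongly positive (≈ +1.3-fold) and the wild-derived CAST,
  PWK, and especially WSB negative; a negative overall inbred penalty;
  a notable positive NOD:PWK asymmetric epistatic entry (so the
  PWK-dam × NOD-sire cell deviates downward);
* every effect class rescaled so that its latent-scale variance
  projection hits a fixed target: additive 9.18%, parental sex 5.77%,
  overall inbred 1.43%, strain inbred 0.60%, symmetric epistasis 2.04%,
  asymmetric epistasis 1.36%, batch 2%, parity 1%, residual
  overdispersion the remainder (total explained by diallel classes
  20.38%; equivalently dam strain 13.15% and sire strain 1.80%). The
  overall latent variance scale ($D \approx 0.305$) follows from
  requiring the dam effects to carry 13.15% while producing pup-scale
  changes of the order of ±1–1.7 pups around a 5.46-pup mean.

The calibration is exact by construction for every seed; the seed only
varies the haphazard shape of the strain-inbred, epistatic, batch, and
parity-deviation patterns. The sex-ratio truth is null — logit male
proportion $\mathrm{qlogis}(0.4979)$, no strain effects, slight
litter-level overdispersion — reflecting a colony with no real sex-ratio
distortion.

What the generator does *not* emulate: facility relocations and other
structured environmental shocks (batch effects are exchangeable),
seasonality, pup mortality between birth and weaning, litter-interval
timing, and non-random assignment of mating pairs to experimental
projects. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions, not robustness to such real-data features.

## Numerical choices

* ZTP quantities are computed on the log scale with `expm1`-style
  evaluation of $1 - e^{-\lambda}$, exact for rates from $10^{-300}$
  up to several hundred; ZTP sampling inverts the Poisson CDF
  conditioned on $y \ge 1$ (O(1) at any rate, no rejection).
* Sum-to-zero conditioning is a rank-one projection using the exact
  class posterior covariance, not an ad-hoc recentering: under an
  exchangeable prior it yields the correct per-coordinate variance
  $\tau^2 (K-1)/K$.
* Inverse-gamma variance draws are clamped to $[10^{-12}, 10^{12}]$ to
  keep Cholesky factorizations finite in degenerate corners (empty
  classes, prior-only runs).
* Effective sample sizes use Geyer's initial positive sequence with the
  monotone refinement; split-PSRF flags parameters above 1.05.
* Parity values above 12 are clamped at import with a warning; records
  with recorded zero litters or inconsistent sex counts are dropped and
  reported, never silently corrected.

## Known limitations

* Per-class variance projections estimated from a single dataset of
  this size carry sampling noise of a few percentage points: the
  hierarchical classes are only softly separated, so row/column-mean
  components of true epistatic or inbred patterns can be absorbed by
  the additive class under shrinkage. Totals and the dam/sire split are
  considerably more stable. HPD intervals reflect posterior, not
  design-resampling, uncertainty.
* The back-transformation of latent dam/sire effects into pup counts
  holds all other covariates at reference values and integrates
  overdispersion via the lognormal mean factor $e^{\sigma^2/2}$ before
  zero-truncation; it is isolated in `pup_scale_effects()` so an
  alternative convention is a one-line change.
* Model-selection machinery over reduced diallel models, sex-specific
  effect classes, and data-scale variance decompositions are out of
  scope.

## A complete run

```{r example, eval = FALSE}
truth <- default_truth(seed = 1)
records <- simulate_sex(simulate_litters(truth, seed = 2), truth, seed = 3)

out <- run_pipeline(records, out_dir = "diallel-run", model = "ztp",
                    config = fit_config(seed = 4, n_iter = 6000,
                                        n_burn = 1500, thin = 3,
                                        n_chains = 2))
print(out$varp)
pup_scale_effects(out$fit, "dam")
```

`run_pipeline()` writes the validated records, posterior draws with a
JSON configuration sidecar, effect summaries (general and dam/sire),
variance projections, expected cell means, environmental ANOVA tables,
and sex-ratio tests into the output directory, with a log naming the
configuration hash.
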