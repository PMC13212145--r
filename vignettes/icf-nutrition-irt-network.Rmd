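---
title: "Methods: IRT scaling and Ising-network perturbation of ICF nutrition items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IRT scaling and Ising-network perturbation of ICF nutrition items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfnet)
```

## The measurement problem

Nutrition-associated health in cancer patients is broader than nutrient
intake: it spans body functions (taste, digestion, fatigue, emotion) and
activities and participation (walking, dressing, shopping for food), the
domains the WHO ICF codes as `b...` and `d...` items with qualifiers 0 (no
problem) to 4 (complete problem).  `icfnet` implements a two-part analysis
of such data:

1. a **measurement model** — a dichotomous item response theory (IRT) scale
   placing persons (latent trait $\theta$, "nutrition-associated health
   level") and items (difficulty $b$) on one logit scale; and
2. a **dependence model** — an Ising network over the same items in risk
   coding, whose node perturbation yields a *benefit index*: a model-based
   ranking of which impairment, if relieved, would most improve the whole
   system.

## Measurement model

Qualifiers are dichotomized with 0 mapped to 1 (unimpaired) and 1–4 to 0,
so a higher total score means better functioning.  The 4PL response
function is

$$P(X_{ij}=1\mid\theta_i) = g_j + (u_j - g_j)\,
\mathrm{logistic}\!\big(a_j(\theta_i - b_j)\big),$$

without the historical 1.7 scaling constant; 3PL ($u=1$), 2PL ($g=0$) and
1PL (common $a$) are the usual restrictions.  Estimation is marginal
maximum likelihood via Bock–Aitkin EM with *fixed quadrature*: 61 equally
spaced nodes on $[-6, 6]$ weighted by the standard-normal prior.  The
fixed standard-normal prior is an explicit assumption — with a skewed
latent distribution it induces conditional bias, which is why the
quadrature choice is surfaced as a parameter rather than hidden.
Convergence is declared when the largest absolute parameter change falls
below $10^{-5}$; the observed-data marginal log-likelihood is tracked and
tested to be non-decreasing (tolerance $10^{-8}$ for quadrature
round-off).

Numerical guards: probabilities are clamped to $[10^{-12}, 1-10^{-12}]$
before logs (items with near-step curves otherwise produce $0\cdot\infty$);
$a$ is boxed to $[0.05, 100]$ — the upper cap keeps the arithmetic finite
for items whose EM path runs toward a step function, a known estimation
artifact that we deliberately do not penalize by default; $g$ is boxed to
$[0, 0.5]$ with an *optional* weak logit-normal prior (`g_prior_sd`, off by
default); $u$ to $[0.5, 1]$.  Items answered identically by everyone are
flagged inestimable and skipped in the M step.

Persons are scored by expected a posteriori (EAP): posterior mean and SD
over the same quadrature, skipping missing responses; an empty response
pattern returns the prior.  EAP was chosen for the worked-example
reproduction because it is the default of the common IRT software in this
area and is well-defined for all response patterns; the estimator behind
the published example value is not stated in the source material, and with
parameters printed to two decimals the reproduced EAP differs from the
printed value by about 0.03 logits (our quadrature-converged value is
−0.4702).  The package reports its own computation rather than the printed
number.

**Model choice.**  Candidate 1PL–4PL fits are compared with adjacent
likelihood-ratio tests and BIC $=-2\ell + k\log n$; the selected model is
the lowest-BIC model among those passing a per-item adequacy gate (S-X²
p-values, Benjamini–Hochberg at 0.05).  S-X² uses the Lord–Wingersky
score-distribution recursion for the model-implied proportions per summed
score, with expected cells collapsed to at least 1.  INFIT/OUTFIT are
mean-square residuals integrated over each person's posterior rather than
plugged in at the EAP point estimate — the plug-in version is biased below
1 by shrinkage, the integrated version is calibrated (mean ≈ 1 under the
generating model in our null simulations).

**Nonparametric screen.**  Before parametric fitting, Mokken scalability
coefficients ($H_{ij}$, $H_i$, $H$ as covariance ratios against the
marginal-preserving maximum), greedy AISP item selection with the
published lower bound 0.42, Guttman-error person screening (Tukey upper
fence $Q_3 + 1.5\,\mathrm{IQR}$ — the source says only "extreme values",
the fence makes the rule deterministic), and rest-score monotonicity
checks with one-sided two-proportion z tests at $\alpha = 0.05$.

**Adjusted difficulty.**  `monte_carlo_difficulty()` is a parametric
bootstrap: 500 replicate datasets (the published count) of the original
size are simulated from the fitted bank and refitted; $b_{mc}$ is the mean
of the replicate difficulty estimates, averaging over full-model refits
(whether the original averaged full-model or per-item refits is unstated;
full-model refits are the stricter reading).

**Reliability.**  Cronbach's $\alpha$ classically, and the latent class
reliability coefficient (LCRC) from an unrestricted latent class model:
between-class variance of class true scores over total implied variance.
The class count is chosen by BIC over $K = 1..6$ because no $K$ is given
in the source material.

**Imputation (MILCA).**  Items with ≥ 30% missing are removed, as are
pseudo-constant items (minority category ≤ 5%, inclusive at the
boundary).  Remaining holes are imputed from a latent class model fitted
with the missing entries marginalized out of the likelihood; each hole is
drawn from the posterior predictive given the person's observed entries.
The default is a single completed dataset (the downstream stages consume
one matrix); `m_imputations > 1` is available.

**DIF/DTF.**  Expected total-score curves per group, optionally after
mean/sigma linking of the focal difficulties onto the reference metric
(no linking detail is published; mean/sigma on all items as anchors is the
simplest defensible choice).  Signed/unsigned DTF are the mean (absolute)
curve differences over the focal trait density.

## Network model and benefit index

The imputed matrix of retained items is complemented into risk coding
(1 = impaired).  Structure learning is Metropolis–Hastings over graph
space with single-edge toggles: a graph is scored by the sum over nodes of
the Laplace-approximated marginal likelihood of the node's logistic
regression on its neighbours (marginal pseudo-likelihood), with
independent N(0, 2²) coefficient priors and a uniform prior over graphs.
The published analysis used a birth–death-style sampler for the same
estimand (edge posteriors and the maximum-posterior graph); the MH kernel
is simpler and its node-wise scores cache efficiently.  Defaults: 50,000
iterations, 10% burn-in.  Edges with posterior inclusion probability
strictly above 0.5 are retained; Ising parameters on the retained graph
are maximum pseudo-likelihood (per-node logistic regressions,
interactions symmetrized by averaging; ridge fallback with penalty 0.1
under separation; closed-form marginal logits for isolated nodes).

The *benefit index* of node $i$ deactivates that node — lowers its
threshold $\tau_i$ by $2\,\mathrm{sd}(\tau)$, the SD taken across the
fitted node thresholds (the published "two standard deviations" does not
name the SD's population; an absolute shift is available as an
alternative) — and measures the drop in the expected system score
$\sum_j P(x_j = 1)$, by exact $2^p$ enumeration up to 20 nodes and Gibbs
sampling (compiled single-chain sampler, systematic updates, 1000-sweep
burn-in, thinning 10) beyond.  Indices are normalized so the maximum is
exactly 1.  Significance uses the 84%-CI overlap rule: percentile
intervals of per-batch mean scores from independent simulation batches
(default 50 batches × 2000 draws); whether the published CIs resample
data or simulation batches is unstated — batch CIs are the
implementation, a person-level bootstrap being a straightforward
extension.

Per person, items split into a *functional challenge zone* (difficulty
above $\theta$) and *competency zone* (at or below $\theta$; the tie goes
to competency, a measure-zero case).  The adjusted difficulty $b_{mc}$ is
the default comparator.  Intervention targets are the impaired items,
ranked significant-benefit first, then ascending difficulty, ties by item
id; items outside the largest connected component are flagged low
leverage because their deactivation cannot propagate.

## Synthetic cohorts

`generate_cohort()` emulates the study conditions the analysis assumes:
300 patients, $\theta \sim N(0,1)$, responses from the packaged 43-item
3PL bank, covariate marginals matching the published cohort (43% female,
62% under 70 years, 64% operated, 47% malnourished — the published
malnutrition row is internally inconsistent across sex columns, so only
the marginal is emulated), injectable MCAR missingness below the 30%
removal threshold, and three surrogate criterion scores that are linear
transforms of standardized $\theta$ plus N(0, 1) noise (increasing for
the MNA-like score, decreasing for the PG-SGA- and NRS-like scores,
giving validity correlations near ±0.7).  The generator does **not**
emulate real instrument content, cancer-type strata, polytomous
qualifiers, or non-normal trait distributions — so passing tests show the
pipeline's statistical machinery is correct under its own assumptions,
not that those assumptions hold in any clinic.  An optional group shift of
$b$ can inject DIF; no published value constrains its size, so it defaults
to off.

## Problem sizes and tolerances in the test suite

Simulation-based tests use the smallest sizes at which the tested
property is clearly identified: parameter recovery at $n = 1000$
(RMSE$(b) < 0.25$), selection consistency at $n = 2000$ over 20
replicates, Ising total-variation agreement at 50,000 draws on 5 nodes,
planted chain recovery at $n = 2000$ with thresholds centred so node
prevalences sit near one half (the most informative regime for edge
detection), Monte-Carlo difficulty with 15–30 replicates.  The pipeline
smoke test reduces iteration counts (3000 structure-search iterations,
400-draw benefit batches) — these are test sizes, the function defaults
remain the analysis-scale ones quoted above.

## Known limitations

- The fixed standard-normal prior biases person and item estimates when
  the latent distribution is skewed; an empirical-histogram prior is not
  implemented.
- The benefit index is a model-derived potential, not an observed
  intervention effect; nothing here validates it longitudinally.
- Polytomous (graded) models, IIO statistics, mixed graphical models and
  regularized (eLasso) estimation are out of scope; eLasso-style fits
  would only ever be a cross-check, not the estimator.
- Exact enumeration is capped at 20 nodes; larger systems rely on Gibbs
  Monte Carlo with its reported batch-means standard errors.
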