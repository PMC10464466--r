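---
title: "Bifactor modeling and integrative analysis of sensory reactivity items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifactor modeling and integrative analysis of sensory reactivity items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensebifactor)
```

## The measurement problem

Caregiver questionnaires about sensory reactivity in autistic children
come in incompatible versions: the Sensory Profile family scores *lower*
numbers for more frequent behaviours, the Sensory Experiences
Questionnaire the opposite; analogous questions recur across versions;
different studies administer different instruments to different children.
The substantive questions sit one level up: which modality-by-pattern
subconstructs (Auditory HYPER, Tactile SEEK, ...) are measurable scales at
all; whether a supra-modal total score per response pattern (HYPER, HYPO,
SEEK) is interpretable on top of the modality scores; and how the
resulting constructs relate to clinical and demographic characteristics
across studies. This package implements that pipeline end to end, with a
synthetic-data generator in place of the restricted multi-site data.

## Harmonization

An `item_bank` declares, per raw item, its instrument, modality, response
pattern, reverse flag and homolog group. `harmonize()` maps reversed
responses x to K + 1 − x (an involution; K = 5 throughout), then collapses
each homolog group to one column. When a child answered homologous items
on two instruments, the instrument earliest in a configurable precedence
order wins; the default prefers the newest instrument version
(SEQ-3.0, SEQ-2.1, SP2, SSP2, SP1, SSP1). The category count is fixed by
the bank rather than inferred, so empty categories stay representable, and
missingness is an explicit `NA`, never a category.

## The graded response model engine

The generative model for item $i$ is linear on a latent response scale:
$y_i = \lambda_{G,i}\theta_G + \lambda_{s,i}\theta_s + e_i$ with
orthogonal standard-normal traits and uniqueness variance $1 - h_i^2$;
observed categories cut $y_i$ at $K-1$ increasing thresholds. Under the
probit link this is exactly a (bifactor) graded response model with
slopes $a = \lambda/\sqrt{1-h^2}$, which keeps the index formulas below
linear in the standardized loadings — the reason probit is the internal
link (logit input is rescaled by 1.702).

Estimation choices, all defaults of `fit_grm()`:

- **Quadrature**: 21 Gauss–Hermite-type nodes per dimension (Golub–Welsch
  on the standard normal). Bifactor likelihoods use dimension reduction —
  the general dimension crossed with one specific dimension per subscale
  block — so cost is $O(Q^2 \cdot \text{items})$ rather than
  $Q^{1+S}$; `tests` verify equality with naive full-dimensional
  quadrature to $10^{-4}$ on a toy model.
- **EM**: the E-step puts posterior weights on the grid; the M-step solves
  each item's expected ordinal regression by BFGS with analytic gradients,
  thresholds kept increasing via a log-increment parametrization. A GEM
  guard never accepts an uphill move, so the marginal log-likelihood is
  non-decreasing by construction (asserted every cycle). Stopping: change
  < 1e-5 (tests use 1e-4 on large problems), max 500 cycles.
- **Identification**: factor variances fixed at 1, all factors orthogonal.
- **Degenerate inputs**: categories never observed are collapsed into the
  adjacent category with a recorded remapping; an item with a single
  observed category is rejected rather than silently diverging; scales
  with fewer than three items are refused.
- **Scoring**: EAP means and SDs from the quadrature posterior; marginal
  reliability $\rho_{xx} = \mathrm{Var(EAP)}/(\mathrm{Var(EAP)} +
  \overline{\mathrm{Var}_{post}})$. Plausible values are drawn from the
  discrete grid posterior with uniform jitter of half the local node
  spacing — a deterministic, seedable approximation chosen over MCMC for
  reproducibility; with 21 nodes the grid is dense relative to posterior
  SDs (~0.3+), so the discretization is negligible for the downstream
  regressions.

## Limited-information fit and the adequacy gates

`limited_info_chisq()` sums Pearson-type discrepancies between observed
and model-implied univariate and bivariate category tables, collapsing
sparse bivariate cells to a minimum expected count of 1 (margin-wise, the
thinnest margin first), with df = summed table df minus free item
parameters. RMSEA and a TLI against an independence (thresholds-only)
baseline follow the usual formulas; TLI is *not* truncated at 1. This is a
deliberate approximation to published quadratic-form statistics: its
contract, enforced by simulation tests, is calibration under the true
model (RMSEA ≤ 0.03, TLI ≥ 0.97 in ≥ 90% of replicates at n = 2000) and
strict ordering against misspecified models — not numerical equality with
any particular software's M2/C2. SRMR is the RMS difference between
sample polychoric and model-implied latent correlations.

`apply_gates()` encodes the a priori adequacy rules (TLI > 0.97,
RMSEA < 0.089, SRMR < 0.05 or < 0.033 for 3-item composites,
ρ_xx > 0.7, ω_T > 0.7); unavailable criteria (e.g., df ≤ 0) are reported
as such rather than failing a scale.

## Structure exploration

Polychoric correlations use two-step ML: thresholds from the univariate
margins, then a 1-D likelihood search over the latent correlation, with a
fast Gauss–Legendre bivariate-normal CDF (checked against an independent
implementation to 1e-5). Pairs with fewer than 30 joint observations or a
degenerate margin are dropped (optionally replaced by Pearson values).

`iclust_refine()` merges the cluster pair maximizing the worst-split
(Rulon/beta) reliability of the merged composite, freezes a branch when a
merge would lower both alpha and beta, then removes items whose
correlation with their cluster composite is below 0.30 (or that join no
cluster) and repeats until stable. The exact published removal criteria
for this construct family are not public; these defaults are therefore
documented, configurable, and held to a planted-structure recovery
contract instead of an item-list replication contract.

`ega()` estimates a graphical-lasso partial-correlation network (penalty
chosen by EBIC with γ = 0.5 over 100 log-spaced values; the in-package
coordinate-descent solver is tested against the exact inverse at zero
penalty) and detects communities with seedless walktrap. Non-PD input
matrices are repaired by eigenvalue clipping, and the repair is logged.
Whether clustering should run on polychoric or Pearson input is not
settled; polychoric is the default, Pearson a fallback/configuration.

## Bifactor indices and decision rules

`compute_indices()` implements the linear-composite (Rodriguez-style)
omega family and the ECV family (see README for formulas). Two published
inconsistencies are worth noting. First, the reference hyperreactivity
solution's printed ω_T/ω_H differ from the linear formula applied to its
own printed loadings by up to ~0.03 (most likely a categorical-omega
variant or unrounded loadings upstream); the ECV family and h² reproduce
exactly, so exactness is claimed — and tested — only for those, with a
±0.03 band on the hyperreactivity omegas. Second, one reference
hyporeactivity item's printed I-ECV (0.183) is inconsistent with its own
printed loadings (0.318²/0.645 ≈ 0.157); the package always derives I-ECV
from the loadings. Threshold comparisons in
`evaluate_interpretability()`/`evaluate_added_value()` are inclusive,
matching the boundary case ω_H = 0.800 being declared sufficient.

## The synthetic multi-site generator

Defaults emulate the pooled-study setting: 5-category items with
right-skewed thresholds placing (35, 25, 20, 13, 7)% of mass per category
(caregiver frequency ratings are bottom-heavy); orthogonal traits;
per-study effect $\beta_j = \beta + N(0, \tau^2)$ with a continuous
correlate constructed as $x = \beta_j\theta + N(0, 1-\beta_j^2)$ so the
within-study standardized slope equals $\beta_j$ by construction, or a
Bernoulli(0.5) group indicator shifting the trait by $d_j$; planned
missingness by administered item subset; and a master seed spawning
per-study substreams so adding a study never perturbs earlier ones. The
generator assumes one harmonized parameter set per homolog group — the
same assumption the analysis makes. It does not simulate MNAR
missingness or differential item functioning, so passing tests speak to
the pipeline's behaviour under its own assumptions, not to robustness
against informative missingness or cross-study item bias.

## Integrative data analysis of correlates

For each interpretable construct and correlate with ≥ 100 complete cases,
the model is $y_{ij} = (\beta_0 + b_{0j}) + (\beta_1 + b_{1j})x_{ij} +
\varepsilon_{ij}$ with jointly normal random study intercepts and slopes,
outcome standardized overall, continuous predictors standardized (β₁ = r)
and binary ones 0/1 (β₁ = d). Priors are weakly informative: Normal(0,1)
on β₀/β₁, half-Student-t(3, 0, 0.5) on random-effect SDs,
half-Student-t(3, 0, 1) on the residual SD, and Uniform(−1, 1) on the
intercept–slope correlation — the uniform is this package's choice of
correlation prior for its Gibbs backend (rjags), non-centered for
mixing. The model is fit once per plausible-value replicate (M = 10) and
pooled by concatenating posterior draws — exact Bayesian combining of
imputations, chosen over Rubin's rules for testability. Chains extend
automatically until split-R̂ ≤ 1.01 for β₀, β₁, both SDs and σ (bounded
extensions); non-converged results carry no evidence class.

Evidence uses the ROPE (r: ±0.1, d: ±0.2): P_ROPE is posterior mass
inside; BF_ROPE compares posterior to prior odds of lying outside, the
prior odds computed from fresh Normal(0,1) prior draws of β₁; |log BF|
thresholds 1.1 and 2.3 mark moderate and strong evidence, the continuity
floor of one draw is applied (and flagged) when a side is empty.
Heterogeneity: τ² is the posterior random-slope variance (τ is also
reported, as published texts sometimes mix the two); I² compares τ² with
a Higgins-style typical within-study sampling variance of the slope; ICC
is the share of outcome variance from study-level terms; the 95%
prediction interval resamples $\beta_1 + N(0, \tau_1^2)$ per draw.
Reported r is the standardized slope without clipping; hierarchical
shrinkage can in principle push draws outside [−1, 1].

## Problem sizes and what the tests show

The test suite exercises: parameter recovery at n = 3000 (loading RMSE
≤ 0.05), oracle equality for the dimension-reduced likelihood, wTO and
polychorics, fit-gate calibration on 20 parametric-bootstrap replicates
at n = 2000, and IDA validity with 12 studies of 100 children each
(credible-interval coverage of r = 0.30 at τ = 0.05; null classification
in ≥ 80% of 10 replicates; prediction intervals wider than credible
intervals when τ > 0). These sizes were chosen to mirror the pooled-study
setting at desk scale. One consequential property of plausible values is
that draws taken from the measurement model alone understate
trait-covariate covariances by the marginal reliability factor — the
classical conditioning-model requirement of the PV literature. The
package therefore supports (and the correlate stage uses by default)
conditioned draws: the general-trait prior is tilted to
N(γx, 1 − γ²) with γ estimated by moment disattenuation, which removes
the bias; both behaviours are verified in the tests.

## Known limitations

No multi-group models or DIF testing; no MNAR missingness; no exact
replication of published M2/C2 values or of the published item lists
(both depend on restricted data or unavailable supplementary criteria);
the omega variant used upstream of the reference tables is not
recoverable from the printed information, so the hyperreactivity omegas
are matched only approximately; single-item fallback selection is a
configuration decision, never automated.
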