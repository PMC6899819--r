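---
title: "Arm-based and contrast-based models for network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-based and contrast-based models for network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Network meta-analysis (NMA) synthesizes randomized trials comparing several
treatments for one condition, combining direct comparisons (within a trial)
with indirect ones (through a common comparator).  A long-running debate
contrasts *contrast-based* models — which model relative effects, anchored
to each study's own control arm — with *arm-based* models, which model the
absolute outcome level of every arm.  The real axis of disagreement is not
the CB/AB label but whether **study intercepts** (the outcome level on the
reference treatment) are *fixed effects*, estimated freely per study, or
*random effects* drawn from a common distribution.  Random intercepts let
the model compare outcome levels *across* studies ("between-study
information"), which can sharpen estimates but also silently break
randomization: if trials of treatment Y happen to enroll sicker patients
than trials of treatment Z, Y will look worse even when the two treatments
are identical.

`abnma` implements a ladder of four structural models that isolates this
axis, together with the machinery to probe it: deterministic hypothetical
data sets with known truth, matched priors, conditional and marginal
estimands, and MCMC fitting with an exact binomial likelihood.

# The models

Data are arm-level binary counts: in study $i$ ($i = 1,\dots,n$), arm
$k \in R_i \subseteq \{1,\dots,K\}$ has $y_{ik}$ events among $n_{ik}$
participants.  Throughout,

$$y_{ik} \sim \mathrm{Binomial}(n_{ik}, \operatorname{expit}(\theta_{ik})),$$

an exact likelihood that needs no continuity corrections for zero-event
arms.  The models differ in the structural equation for the arm log-odds
$\theta_{ik}$ (normal distributions are written mean/variance):

* **Model 1** (fixed intercepts, observed arms; the classic CB model):
  $\theta_{ik} = \alpha_{i b_i} + \delta_{i b_i k}$ with study-specific
  base treatment $b_i$, $\delta_{i b_i k} \sim
  N(\mu^c_{1k} - \mu^c_{1 b_i},\, \sigma^{c2})$, and $\delta_{i b_i b_i} = 0$.
  The package takes $b_i$ as the lowest-numbered treatment in $R_i$.
* **Model 2** (fixed intercepts, all arms):
  $\theta_{ik} = \alpha_{i1} + \delta_{i1k}$ for *all* $k$, with
  $\boldsymbol\delta_i \sim N(\boldsymbol\mu^c, \Sigma^c)$ and
  $\delta_{i11}=0$.  Modeling unobserved arms changes nothing statistically
  — models 1 and 2 have the same posterior for shared parameters — but
  model 2 extends cleanly to non-common heterogeneity and to multi-arm
  studies.  An equivalent *arm-based form* writes
  $\theta_{ik} = \alpha_i + \mu^c_k + \eta_{ik}$ with iid
  $\eta_{ik} \sim N(0, \tfrac12\sigma^{c2})$.
* **Model 3** (random intercepts, independent of effects): model 2 plus
  $\alpha_{i1} \sim N(\mu^a_1, \sigma^{a2})$.
* **Model 4** (random intercepts correlated with effects; the AB model):
  $\boldsymbol\theta_i \sim N(\boldsymbol\mu^a, \Sigma^a)$, the parameters
  of interest being $\mu^c_k = \mu^a_k - \mu^a_1$.  An equivalent CB form
  models $(\alpha_{i1}, \boldsymbol\delta_i)$ jointly.

Models 1–2 use only within-study information; models 3–4 also use
between-study information; model 4 additionally lets treatment effects
covary with underlying risk.

## Heterogeneity structures

*Common heterogeneity* (CH) gives every pairwise contrast the same
variance $\sigma^{c2}$.  In models 2–3 this is
$\Sigma^c = \sigma^{c2} P_{K-1}(0.5)$, where $P_n(\rho)$ has unit diagonal
and off-diagonals $\rho$; in the AB form of model 2 it is
$\tfrac12\sigma^{c2} I_K$.  For model 4 the package uses the compound
symmetry structure

$$\Sigma^a = \sigma^{a2} P_K(\rho^a), \qquad
  \sigma^{c2} = 2\sigma^{a2}(1-\rho^a),$$

which separates arm heterogeneity $\sigma^{a2}$ from contrast
heterogeneity: $\rho^a = 1$ means effects are homogeneous and unrelated to
underlying risk, and the within-study regression of a contrast on the
intercept has slope $\rho^a - 1$.  *Non-common heterogeneity* (NCH) leaves
$\Sigma^c$ (models 2–3) or $\Sigma^a$ (model 4) unstructured.  A diagonal
$\Sigma^a$ is provided only as a comparison object
(`diag_arm_cov()`): it forces every contrast to be more heterogeneous than
every arm, which is rarely credible.

## Priors, and how they are matched across models

Model comparisons are only meaningful if priors are comparable, so all
variance-component priors are derived from one anchor: a lognormal
evidence-based prior on $\sigma^{c2}$, by default
$\log\sigma^{c2} \sim N(-2.56, 1.74^2)$, an external predictive
distribution for log-odds-ratio heterogeneity in
pharmacological-versus-placebo comparisons.  It is a default, not a
constant: `prior_config()` exposes it.  Location parameters get flat
$N(0, 1000)$ priors (variance 1000).

* Models 1–3 (CH) place the lognormal directly on $\sigma^{c2}$.
* Model 3's intercept variance $\sigma^{a2}$ is a different kind of
  quantity — variation in underlying risk across trial populations, which
  is typically much larger than treatment-effect heterogeneity — and gets
  its own lognormal, by default $\log\sigma^{a2} \sim N(0, 2^2)$: weakly
  informative, centered at $\sigma^a = 1$ on the log-odds scale with a
  95% range of roughly $\sigma^a \in (0.14, 7)$.
* Model 4 (CH) needs a joint prior on two heterogeneity quantities.  The
  package keeps the likelihood parameterized in $(\sigma^{c2}, \rho^a)$
  but places the *same two independent lognormals* on $\sigma^{c2}$ and on
  the derived $\sigma^{a2} = \sigma^{c2}/(2(1-\rho^a))$, restricted to the
  positive-definite range $\rho^a \in (-1/(K-1), 1)$.  This was a genuine
  design decision; the obvious alternative — a uniform prior on $\rho^a$ —
  was implemented first and rejected, because it is *not* comparable with
  models 1–3: it concentrates prior mass on
  $\sigma^{a2} \approx \sigma^{c2}$, i.e. on arm heterogeneity as small as
  contrast heterogeneity, which contradicts both the arm-variance prior
  used in model 3 and the empirical regularity that underlying risk varies
  more than treatment effects.  On networks with very low-risk control
  arms the two priors give visibly different posteriors for
  $(\rho^a, \sigma^a)$; matching the arm-variance prior across models 3
  and 4 is what makes their comparison a comparison of structure.
* NCH models use inverse-Wishart priors on the native covariance
  ($\Sigma^c$ for models 2–3, $\Sigma^a$ for model 4) with
  dimension + 2 degrees of freedom.  Any quadratic form of an
  inverse-Wishart is inverse-gamma, so the prior mean of each *log*
  variance is available in closed form; the scale matrix is chosen so the
  mean log contrast variances equal the CH lognormal's location (and, for
  model 4, the mean log arm variances equal the arm prior's location).
  The spread of the log variances is set by the degrees of freedom and
  comes out near 0.97 — the same order as, but not equal to, the
  lognormal spreads; with inverse-Wishart priors the spread and the
  location cannot both be matched, a known rigidity of the family.  These
  priors are informative, and `sample_prior()` exists precisely so users
  can inspect all of them side by side.

# Estimands

The mean contrasts $\mu^c_{1k}$ are *conditional* (within-study) log odds
ratios.  Marginal (population-averaged) quantities follow from
$\pi_k = E[\operatorname{expit}(\theta_{ik})]$ with the expectation over
the fitted between-study distribution; conditional odds ratios are further
from 1 than marginal ones.  `marginal_mean()` and `marginal_contrast()`
compute these for models 3–4 per posterior draw by 32-node Gauss–Hermite
quadrature (deterministic given the draws; the node count is configurable
and 32 nodes are accurate to well below Monte Carlo error for the logistic
integrand).  For model 3 the integration variance for a non-reference arm
is $\sigma^{a2} + \Sigma^c_{kk}$ (intercept and contrast heterogeneity are
independent); for model 4 it is $\Sigma^a_{kk}$.  Models 1–2 have no
fitted intercept distribution, so marginal estimands are refused with an
explanatory error; the supported route for them is
`external_target()`, which applies the conditional odds ratio to an
externally estimated underlying risk — usually the better-founded choice
anyway, since the NMA's own studies are rarely representative of the
target population.  `external_target()` by default plugs the posterior
contrast into a point external risk; integrating the contrast
heterogeneity is available behind a flag, and with heterogeneity the two
versions differ in the direction of expit's curvature.

# The hypothetical data sets

`generate_scenario()` builds ten fixed data sets for a three-treatment
network (X = 1, Y = 2, Z = 3) in which Y and Z are *identical*, every
study has an X arm, and Z is never compared with Y directly, so the Z–Y
estimate (truth 0) is purely indirect.  The X-arm log odds runs over an
equally spaced grid from −2 to 0 (event fractions around 25%).  Scenarios:
1 no effect, 2 effect 0.5, both 200/arm; 3 as 2 with 50/arm; 4/5 effects
averaging 0.5 and decreasing/increasing linearly in the X log odds,
200/arm.  Type *a* interleaves six Y-vs-X with five Z-vs-X designs across
the grid (11 studies); type *b* gives Y-vs-X the five low-risk grid points
and Z-vs-X the five high-risk points (10 studies), so design is
confounded with underlying risk.

Counts are **expected counts rounded half-up**, not binomial draws: the
data sets are constructions, not simulations, so every analysis of them is
exactly reproducible (binomial sampling is available behind
`sample_counts = TRUE` for robustness checks).  Two generator choices were
open and are fixed as follows: the grid spacing is uniform (only the
endpoints −2 and 0 are prescribed), and type b has 10 studies (five per
design).  The slope of the scenario-4/5 effect rule is calibrated so that
the gap in mean true effects between the two designs of a type-b data set
is exactly ∓0.5 — `design_bias_oracle()` checks this bookkeeping — because
that gap, not the slope itself, is the quantity with a stated target: it
is the bias an analysis inherits if it (implicitly) pools by design.

What these data sets do *not* emulate: sampling noise (counts are
expected values), multi-arm studies, non-binary outcomes, and any
treatment-by-covariate structure beyond the linear risk-effect rule.
Passing the bias-pattern tests on them shows that a model uses or ignores
between-study information as its structure dictates — it does not show how
large such biases are in any real network.

# Sampling and numerics

`nma_fit()` translates the chosen model into a JAGS program (the full
code is in `bugs_model_code()`'s source, one block per model variant).
Compound-symmetry covariances are sampled via the decomposition
$\sigma^{c2}P_{K-1}(0.5) = \tfrac12\sigma^{c2}(I + J)$ — a shared plus an
independent normal component — in models 2–3, and via the analytic inverse
of $P_K(\rho)$ in model 4, whose correlation is truncated to
$(-1/(K-1) + 10^{-3},\, 1 - 10^{-3})$ to keep the precision matrix
numerically well-conditioned near the singular boundary.  Initial values
use empirical logits with a 0.5 continuity correction (initialization
only; the likelihood never modifies counts), variance components start at
their prior medians.  The default chain regime is a single chain with
50 000 burn-in updates and 200 000 further updates thinned to every 20th;
on the networks shipped with the package this keeps post-thinning
autocorrelations of monitored parameters low (lag 2–8 depending on the
model, model 4 NCH being the slowest mixer).  Fixed seeds give bitwise
identical draws.  Credible intervals are central 95% intervals with
type-7 (linear-interpolation) quantiles; the Monte Carlo error of a
posterior median is estimated by batch medians (`mcse_median()`), which
slightly overstates the error and is therefore safe for equivalence
checks.  Autocorrelation of a constant chain is reported as 0 with a
warning rather than NaN.

The package's own test suite uses scaled-down versions of everything
stochastic: chains of a few thousand retained draws for posterior
comparisons, 50 replicates for the coverage study (30 studies of 500 per
arm, $\sigma^c = 0.3$), and the ten hypothetical data sets at their
defining sizes.  These sizes are the package's choices for routine
verification; the full-length regime remains the default for analyses.

# Worked example

```{r, eval = FALSE}
library(abnma)
net <- corticosteroids()
summarize_designs(net)        # a star: every design is {placebo, drug}

fits <- lapply(c(1, 3, 4), function(m) {
  nma_fit(model_spec(m), net, chain_config(seed = 1))
})
compare_fits(setNames(fits, c("model 1", "model 3", "model 4")), k = 7)
# model 1 (fixed intercepts) estimates mometasone vs placebo around 4.5
# log-odds units; model 3 (random intercepts) around 2 units lower -- the
# between-study information shrinks the very low underlying risk of the
# mometasone trials upward.  Model 4 sits between the two, closer to
# model 3; its rho_a posterior (~0.4) reports a negative association
# between contrasts and underlying risk (slope rho_a - 1), and the
# treatment-7 contrast co-moves strongly with sigma_a across the
# posterior (posterior_slope()).
```

# Known limitations

* Model 1 is restricted to two-arm studies (its multi-arm correction is
  not implemented); models 2–4 handle multi-arm studies through their
  multivariate forms.
* Only point-valued external risks are supported in `external_target()`;
  combining a full external risk *distribution* with the posterior is out
  of scope.
* NCH priors are informative by construction; report sensitivity to
  `prior_config()` rather than assuming it away.
* Inconsistency terms, meta-regression, ranking probabilities, and
  non-binary outcomes are out of scope.
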