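---
title: "Methods: Bayesian space-time smoothing of child malnutrition prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian space-time smoothing of child malnutrition prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

National household panel surveys measure the heights and weights of
young children to track malnutrition: stunting (low height-for-age),
wasting/thinness (low weight-for-length or BMI-for-age) and obesity
(high weight-based z-scores). Such surveys are powered for national
estimates, not for the roughly 50 district councils a policy maker has
to plan for. At district level, per-wave samples shrink to a few dozen
children, many district-waves are empty, and crude prevalences bounce
between 0% and implausibly large values. `nutrimap` implements the full
analysis chain that turns child-level anthropometry from a stratified
two-stage cluster panel into stable district-by-wave prevalence
surfaces and policy-target assessments:

1. LMS z-scores and classification (`compute_zscores()`,
   `classify_nutrition()`);
2. design-based prevalence, totals and association tests
   (`weighted_prevalence()`, `rao_scott_chi2()`);
3. a Moran's I spatial screen (`moran_screen()`);
4. a Bayesian hierarchical binomial space-time model
   (`fit_spacetime()`);
5. exceedance probabilities against the WHO 2025 nutrition targets
   (`assess_who_targets()`).

A synthetic-data generator reproduces the survey's structure so every
stage is testable without access-restricted microdata.

# Anthropometric classification

The LMS method maps a measurement $x$ to a z-score via age- and
sex-specific skewness $L$, median $M$ and coefficient of variation $S$:
$z = ((x/M)^L - 1)/(LS)$ for $L \neq 0$ and $z = \log(x/M)/S$ at the
log limit. We interpolate $L$, $M$, $S$ linearly in the indexing
variable between tabulated rows — the behaviour of common LMS software,
and exactly reproducible. Children under 24 months use
weight-for-length indexed by length in cm (the WHO convention; below
two years length, not age, is the appropriate index for the
weight-based score); children at 24 months and older use BMI-for-age.
Cut-offs: stunted if HAZ $< -2$; thin/wasted if the weight-based z
$< -2$; obese if it is $\geq +2$. We apply the $\geq$ boundary
uniformly at all ages: the boundary set has probability zero in
continuous data, and a single rule keeps the classification coherent
across the age switch. Plausibility limits (|HAZ| ≤ 6, |weight-based z|
≤ 5 by default) flag gross measurement errors as invalid rather than
deleting records; no restricted tail adjustment of extreme z-scores is
applied — the plain LMS transform is used throughout.

The package ships no copyrighted growth-standard tables. The bundled
reference (`make_reference_fixture()`) is a synthetic, smooth,
strictly-monotone LMS table with realistic scale, clearly labelled as
such; real WHO tables in the same CSV layout can be supplied by the
user.

# Design-based estimation

Prevalence is the ratio estimator $\hat p = \sum w_i y_i / \sum w_i$
over records with a valid classification. Standard errors use Taylor
linearization over PSU totals within strata (the with-replacement
first-stage approximation); confidence intervals are Wald intervals on
the logit scale, back-transformed so they respect $[0, 1]$, with
degrees of freedom equal to PSUs minus strata. A stratum contributing a
single PSU cannot contribute a variance term; the estimate is returned
with `se_reliable = FALSE` rather than silently understated.
Association tests use the weighted Pearson chi-square with the
Rao-Scott second-order (Satterthwaite) correction referenced to an F
distribution — the standard design-corrected test for complex samples.
Missing covariate values form an explicit "Missing" category, as
survey tabulations conventionally do for incompletely ascertained
covariates such as birth weight and maternal characteristics.

# The space-time model

For outcome $k$, district $i = 1, \dots, I$ (default 52) and wave
$j = 1, \dots, J$ (default 5),

$$Y_{kij} \sim \mathrm{Binomial}(n_{ij}, \pi_{kij}), \qquad
\mathrm{logit}(\pi_{kij}) = \alpha_k + \phi_{ki} + \gamma_{kj} + \nu_{kij}.$$

Each outcome is fitted independently: the pre-modelling Moran screen
(univariate and bivariate Moran's I with permutation inference,
row-standardized common-boundary weights) assesses whether the
outcomes share spatial structure; when cross-outcome spatial
correlation is weak, separate models per outcome are the appropriate
choice, and that is the only structure this package implements.

* $\phi$ follows an intrinsic CAR (Gaussian Markov random field) prior
  with binary common-boundary adjacency: conditionally,
  $\phi_i \mid \phi_{-i} \sim N(\bar\phi_{\partial i},
  1/(\tau_\phi m_i))$ with $m_i$ the neighbour count. An isolated
  district falls back to an exchangeable $N(0, 1/\tau_\phi)$.
* $\gamma$ follows a first-order random walk — the CAR prior on the
  path graph of waves.
* $\nu$ is iid $N(0, 1/\tau_\nu)$, absorbing district-wave wobble the
  structured terms cannot.
* $\alpha$ has an improper flat prior; identifiability comes from
  sum-to-zero recentring of $\phi$ and $\gamma$.
* The three precisions have Gamma(0.5, 0.0005) (shape-rate) priors —
  i.e. inverse-gamma on the variances — a conventional weakly
  informative choice for disease-mapping random effects.

The binomial numerators are survey-weighted pseudo-counts: the
design-based prevalence for each district-wave applied to that cell's
valid sample size, rounded and clamped to $[0, n_{ij}]$
(`build_count_panel()`). Cells with $n_{ij} = 0$ contribute no
likelihood, so their prevalence is inferred purely from the CAR/RW1
smoothing — this is precisely how empty district-waves are handled.

## Sampler

`fit_spacetime()` runs a Metropolis-within-Gibbs sampler written for
this model (C++ core, R's RNG for reproducibility):

* scalar Gaussian random-walk Metropolis for $\alpha$, each $\phi_i$,
  $\gamma_j$ and $\nu_{ij}$, with proposal scales adapted towards a
  ~44% acceptance rate during burn-in only (frozen afterwards, so the
  kept chain is a genuine Markov chain);
* conjugate Gibbs draws for the precisions,
  $\tau \sim \mathrm{Gamma}(a + r/2, b + q/2)$, with $q$ the
  structure's quadratic form and $r$ its rank ($I$ minus the number of
  connected components for the CAR term, $J - 1$ for the RW1, $IJ$ for
  the iid block; isolated districts count full rank through their
  proper fallback prior);
* after each $\phi$ and $\gamma$ sweep the block mean is moved into
  $\alpha$. Because the intrinsic priors are invariant to level shifts
  and $\alpha$ is flat, this recentring changes neither likelihood nor
  prior; it just fixes the gauge, keeping $|\sum\phi|$ and
  $|\sum\gamma|$ below $10^{-10}$;
* one joint scaling move per variance component and iteration,
  $(\tau, u) \to (c\,\tau, u/\sqrt{c})$ with $\log c \sim N(0, 0.6^2)$,
  accepted by Metropolis-Hastings with the exact Jacobian factor. This
  move keeps $u\sqrt\tau$ fixed, so the precision can cross scales even
  when the effects are individually pinned by the likelihood. Without
  it the interaction precision $\tau_\nu$ — weakly identified whenever
  cell sizes are small — has a near-absorbing high-precision state and
  mixes far too slowly for any practical run length.

Two chains with overdispersed starting values are run by default.
Monitored parameters are $\alpha$, the three precisions, and all cell
prevalences $\pi_{ij}$. Convergence requires the Gelman-Rubin
$\hat R < 1.1$ for every monitored parameter **and** a batch-means
Monte Carlo error below 5% of the posterior SD (per-chain batch-means
SEs combined as the standard error of the average of chain means —
pooling draws across chains would let a persistent between-chain offset
masquerade as Monte Carlo noise that never shrinks). Sampling extends
in segments until both criteria hold or a 200,000-iteration cap is
reached, in which case the fit is returned flagged
`converged = FALSE` — never a silent success. Model fit is summarised
by the DIC ($\bar D + p_D$ with the plug-in deviance at the posterior
mean cell logits) and by observed-vs-fitted displays
(`plot_observed_fitted()`); `holdout_validation()` masks a random 10%
of observed cells, refits, and reports RMSE, correlation, and coverage
of the held-out crude prevalences by their 95% posterior-predictive
intervals — predictive, not posterior, because the crude `Y/n` of a
held-out cell carries binomial sampling noise on top of the
uncertainty in $\pi$ (the validation metric is not standardised in
this literature, so all three are reported); `prior_sensitivity()`
refits under alternative
hyperpriors and reports the largest change in posterior median
prevalence.

## Numerical choices

Binomial log-likelihood terms use a guarded `log1p(exp(x))`; the
linear predictor is cached and updated incrementally. Metropolis
proposal scales start at (0.05, 0.3, 0.1, 0.5) for the
$\alpha/\phi/\gamma/\nu$ blocks and adapt multiplicatively every 50
burn-in iterations, clipped to $[10^{-4}, 5]$. Chain $c$ is seeded
`seed + 1000c`, so any chain count is reproducible from one integer.
Degenerate inputs fail fast: a panel with fewer than 2 districts or 2
waves is rejected (the CAR and RW1 structures are undefined), as is a
panel-graph size mismatch. $\hat R$ is floored at 1, since values
below 1 arise only from the $(N-1)/N$ finite-sample factor.

# WHO 2025 targets

Three target rules are assessed per district from the posterior draws:
a relative reduction in stunting between the 2012 and 2017 waves of at
least the interim fraction of the 40% by-2025 target; wasting below 5%
in 2017; and no increase in obesity from 2012 to 2017 (ties satisfy
"no increase"). The interim fraction defaults to the conventional 17%
constant used for 2012-to-2017 assessments; linear pro-rating gives
15.4% and constant-annual-rate (geometric) pro-rating 17.8%, and both
are available (`required_interim_fraction()`) since the 17% figure
matches neither derivation exactly. "Met" is defined on the posterior
median, matching mapped point estimates; the exceedance probability
$P(\text{event} \mid \text{data})$ is reported alongside and flagged
significant only when strictly above 0.8 — exactly 0.8 does not
qualify. Draws with zero baseline prevalence would make a relative
reduction undefined; they are excluded and logged. National roll-ups
(`summarize_targets()`) report counts and integer-rounded percentages
of districts.

# The synthetic-data generator

`pipeline_simulate()` fabricates everything the pipeline reads,
emulating the NIDS-like design: five waves of 3,254 to 4,710 children
(the published per-wave totals), allocated to 52 districts with
unequal shares, nested in six PSUs per district (survey SEs estimated
from very few clusters per stratum are too noisy to be meaningful;
half a dozen clusters per district is typical of national panels at
this tier), lognormal design weights expanding to a 5.5-million
under-five population, uniform ages, balanced sex, and Table-1-style
marginal covariate frequencies. True prevalences come from the exact
forward model: CAR spatial effects simulated by Gaussian increments
along a BFS spanning tree and recentred (the intrinsic prior is
improper — a draw is defined only up to level, and recentring fixes
the same gauge the fitted model uses), an RW1 temporal walk, iid
interaction — and, in the bundled end-to-end generator, a
deterministic drift on the logit scale following the published
per-wave national prevalences (stunting 11.0%, 16%, 13%, 8%, 7.6%
across the five waves, with the analogous thinness/wasting and
obesity paths), so the target-assessment stage exercises realistic
secular change including the wave-2 spike — with
default precisions $\tau_\phi = 10$,
$\tau_\gamma = 40$, $\tau_\nu = 40$ (spatial SD ≈ 0.32 on the logit
scale, temporal and interaction SDs ≈ 0.16 — heterogeneity of the
order seen in district-level malnutrition mapping: prevalences
spanning roughly half to double the national level). Anthropometry is
generated by inverting the LMS transform from normal z-draws whose
mean (and, for the weight-based score, SD) are solved in closed form
so the classification prevalences match the true district-wave
prevalences in expectation — $P(\mathrm{HAZ} < -2) = \pi_\text{stunt}$
and the two weight-based tails match thinness and obesity jointly.
Covariates are marginal by default; an optional odds-ratio mode ties
one covariate category to one outcome to give the association tests
something to detect.

What the generator does **not** emulate: panel attrition and
refreshment, within-household correlation beyond the PSU effect,
informative missingness, measurement error and digit preference,
real contiguity geometry (a 4×13 rook lattice or a random planar
Gabriel graph stands in for the district map), and covariate
dependence structure beyond the optional single association. Passing
tests therefore demonstrate that the estimators and the sampler are
correct under the stated design, not that any substantive conclusion
transfers to the real survey.

# Problem sizes used in the tests

The checked-in tests and the acceptance script scale the study down to
run comfortably on one CPU: recovery and end-to-end checks use the
full 52-district × 5-wave layout with about 60 children per cell and
2 chains × 5,000 post-burn-in draws (burn-in 2,500); the toy-model
quadrature check uses 2 districts × 2 waves against a dense 2-D grid
with the precision integrated out analytically; unit tests use 4-20
district graphs. These sizes were chosen so that Monte Carlo noise is
an order of magnitude below every tolerance being asserted. The
package defaults (burn-in 10,000, 10,000 kept draws, thinning 10)
reflect the production protocol for a real analysis.

# Known limitations

* The pseudo-count construction (weighted prevalence × cell sample
  size) carries the design weights into the binomial likelihood only
  through the numerator; the effective sample size is taken as the
  unweighted count, which understates design effects within cells.
  This is the standard compromise when a fully design-weighted
  likelihood is unavailable.
* The intrinsic CAR prior smooths towards neighbours regardless of
  whether a boundary is epidemiologically meaningful; no
  covariate-adjusted or proper (Leroux-type) variant is provided.
* Three outcomes are modelled independently; a shared-component model
  could borrow strength across outcomes but is out of scope.
* The interaction term is unconstrained; its mean is absorbed jointly
  with $\alpha$, which is monitored but can slow mixing of $\alpha$
  itself on very sparse panels.
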