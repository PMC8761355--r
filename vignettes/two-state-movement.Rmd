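---
title: "A two-state correlated random walk for daily telemetry, fit by proposal-recursive MCMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state correlated random walk for daily telemetry, fit by proposal-recursive MCMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`statewalk` models daily animal relocations $s_t$ (projected planar
coordinates, metres) through their nightly displacements
$\delta_t = s_t - s_{t-1}$. Each night an individual is in one of two
behavioural states. In the *encamped* state the displacement is small and
directionless, $\delta_t \sim \mathrm{N}(0, \sigma_0^2 I)$, with
$\sigma_0 = 5$ m fixed for all individuals — by the package's reporting
convention twice the standard deviation is quoted as the "95% movement
kernel", so the encamped kernel is 10 m, about one tree canopy plus GPS
error. In the *movement* state the displacement is long and autocorrelated:

$$\delta_t \sim \mathrm{N}\!\big(\gamma\, M(\theta)\, \delta_{t-1},\;
\sigma_1^2 I\big), \qquad
M(\theta) = \begin{pmatrix} \cos\theta & -\sin\theta \\
\sin\theta & \cos\theta \end{pmatrix},$$

where $\theta$ is a turning angle and $\gamma \in (0,1)$ damps adherence to
the rotated previous displacement ($\gamma = 1$, $\theta = \pi/2$ would
produce rigid 90° turns every night). The nightly probability of the
movement state is probit-linked to the landscape category occupied at the
step's *starting* position: $p_t = \Phi(x_{t-1}'\beta)$, with $x$ a one-hot
(cell-means) indicator over the four categories tree, pavement, grass,
building. Cell-means coding is used so that $\Phi(\mu_{\beta,k})$ is
directly interpretable as a per-feature movement probability; the data
carry no intercept column.

Each individual $i$ has its own $(\beta_i, \gamma_i, \theta_i,
\sigma_{1,i}^2)$, drawn from treatment-group distributions on transformed
scales: $\beta_i \sim \mathrm{N}(\mu_{\beta,j}, \Sigma_{\beta,j})$,
$\mathrm{logit}(\gamma_i)$, $\theta_i$ and $\log \sigma_{1,i}$ each normal
with group means and variances. $\theta$ is kept on its natural scale,
canonicalised to $[0, 2\pi)$, with a plain normal group density: a normal
centred near $\pi$ with most of its mass inside the circle mixes better
than a wrapped circular family here, at the cost of ignoring wrap-around —
acceptable because turning-angle estimates concentrate near $\pi$
(course reversals) in this system.

The three treatment groups mirror a translocation experiment on brown
treesnakes: residents, forest-to-urban translocations, and urban-to-urban
translocations.

### Likelihood indexing and day gaps

$\delta_2$ is a fixed initial condition, never modelled; likelihood terms
run $t = 3, \dots, T$ because the autoregression needs $\delta_{t-1}$. When
relocation days have gaps, a term enters the likelihood only if days
$t-2, t-1, t$ are consecutive — a displacement spanning several nights is
not a nightly displacement, and we exclude rather than impute.

### Identifiability: encamped-only individuals

An individual with no displacement over 10 m gives the mixture nothing to
separate: the movement variance collapses below $\sigma_0^2$. Such
trajectories are detected up front (`detect_encamped_only()`, threshold
inclusive) and fit with every step pinned to the encamped state; their
$\gamma$, $\theta$, $\sigma_1^2$ then simply return their priors in stage 1
and their group-level process distributions in stage 2, while $\beta$
remains informed by the (all-encamped) state sequence.

## Two-stage proposal-recursive fitting

Fitting everything jointly is expensive and mixes poorly, so fitting is
split in two.

**Stage 1** fits each individual independently (`fit_stage1()`) with
temporary priors chosen to match each parameter's support and make every
update tuning-free: $\beta \sim \mathrm{N}(0, I)$ with the Albert–Chib
probit augmentation ($z_t$ the latent state, $v_t \sim \mathrm{N}(x'\beta,
1)$ with $z_t = \mathbf{1}[v_t > 0]$), giving a conjugate normal draw for
$\beta$; $\gamma \sim \mathrm{Beta}(1,1)$ and $\theta \sim
\mathrm{WC}(0, 0.1)$ (near-uniform wrapped Cauchy) updated by
prior-as-proposal Metropolis steps whose acceptance ratio is just the
likelihood ratio; and $\sigma_1^2 \sim \mathrm{IG}(1, 0.1)$ with a
conjugate inverse-gamma Gibbs draw. The scan order is $(z, v) \to \beta \to
\gamma \to \theta \to \sigma_1^2$; any fixed scan is valid, and this one
follows the dependence flow of the augmented model. Initialisation is
moment-matched: $z_t = \mathbf{1}[\lvert\delta_t\rvert > 10]$, $\beta = 0$,
$\gamma = 0.5$, $\theta = \pi$, and $\sigma_1^2$ from the spread of the
large steps (floored at $2\sigma_0^2$). All stage-1 iterations are stored;
no burn-in is removed at this stage (the default burn-in knob is 0) since
stage 2 consumes the pools whole.

**Stage 2** (`fit_stage2()`) runs the hierarchical model, recycling each
individual's stage-1 draws as Metropolis–Hastings proposals: a proposed
value is a uniform draw from the stage-1 pool, and the proposal density in
the acceptance ratio is approximated by the Gaussian kernel density
estimate of that pool (normal-reference/Silverman bandwidth, floored at
$10^{-6}$ of the pool range). Because stage 1 used different priors, the
acceptance ratio carries a change-of-variables correction: the group
process density is evaluated on the transformed scale with the Jacobian
($-\log \gamma(1-\gamma)$ for $\gamma$; $-\log 2\sigma_1^2$ for
$\sigma_1^2$ via $\log \sigma_1$; none for $\theta$). Individual
parameters are updated one at a time — the generalized ratio for
autocorrelated pools makes no independence assumption, so pools are used
un-thinned — and the likelihood integrates over the latent states (the
two-component mixture), so stage 2 never tracks $z$. The four correlated
$\beta$ coefficients are updated component-wise using the exact univariate
conditional normal given the others under $(\mu_{\beta,j},
\Sigma_{\beta,j})$. Group-level means, variances and $\Sigma_{\beta,j}$
then get conjugate Gibbs draws (normal–normal, inverse-gamma, and
inverse-Wishart with the variance draws conditioning on the previous
iteration's means to preserve a valid scan). The first 10% of stage-2
iterations are discarded as burn-in in all downstream summaries.

Default iteration counts are 100,000 (stage 1, per individual) and 50,000
(stage 2).

## Priors and the inverse-gamma convention

Throughout the package the inverse gamma is parameterised shape–scale:
$f(s^2) \propto (s^2)^{-(q+1)} e^{-r/s^2}$. Full-model hyperpriors default
to: $\mu_{\beta,j} \sim \mathrm{N}(0, I)$ (diffuse on the probit scale);
$\mu_{\mathrm{logit}(\gamma),j} \sim \mathrm{N}(\mathrm{logit}(0.7), 1.5)$,
regularised away from zero so the movement state stays distinct from the
encamped state; $\mu_{\theta,j} \sim \mathrm{N}(\pi, \pi^2/4)$, mass mostly
inside $[0, 2\pi)$; $\mu_{\log\sigma_1,j} \sim \mathrm{N}(\log 20, 100)$
($2 \times 20$ m = a 40 m nightly kernel, a typical movement distance for
small brown treesnakes).

For the group *variances* the conventional rate-style hyperparameter pairs
(0.001, 1000), (2.5, 0.5), (0.01, 10) are interpreted with the second
element as a **rate**, i.e. scale $= 1/r$: $\sigma^2 \sim
\mathrm{IG}(0.001, 0.001)$ for the logit-$\gamma$ and $\log\sigma_1$
variances (the textbook diffuse inverse gamma), $\mathrm{IG}(2.5, 2)$ for
the $\theta$ variance, and $\mathrm{IG}(0.01, 0.1)$ per coordinate in the
diagonal $\beta$-covariance variant. Read literally as scales, those pairs
would concentrate prior mass on variances near $10^3$ on logit/log scales —
large enough to pin every back-transformed group mean at its saturation
point and overwhelm any data set of realistic size — which contradicts the
stated intent of diffuse priors kept "within reasonable bounds" of each
transformation. The stage-1 $\mathrm{IG}(1, 0.1)$ is kept literal: it is a
temporary prior, dominated by data (or deliberately returned for
encamped-only individuals), and harmless either way.

The $\beta$ covariance prior is a genuinely open choice: a full inverse
Wishart ($\Sigma^{-1}_{\beta,j} \sim \mathrm{Wish}((S\nu)^{-1}, \nu)$, $S =
I$, $\nu = 6$ = dimension + 2, the default) or independent diagonal
inverse-gamma variances (`hyper_priors(beta_cov_model = "diag")`). The
Wishart is the default because the component-wise $\beta$ updates use the
conditional given the *other* coefficients, which is only informative when
off-diagonal covariance is representable.

## Derived quantities and hypothesis tests

Group-level summaries are reported on natural scales via Monte Carlo
integration (`derived_quantities()`): for each retained stage-2 draw,
`n_mc` pseudo-individuals are drawn from the group distributions and their
inverse transforms averaged — $\mu_\gamma$ (inverse logit), $\mu_{\sigma_1}$
(exp, metres), and $\mu_{p}$ per landscape feature ($\Phi$ of coefficient
draws under $\mathrm{N}(\mu_\beta, \Sigma_\beta)$). This integrates
individual heterogeneity into the group mean; a deterministic plug-in
transform of the means is available (`plugin = TRUE`) for comparison.
`n_mc` defaults to 1,000 per retained iteration.

Hypotheses about treatment effects are tested with derived differences:
the posterior mean of $a - b$ and the posterior probability
$\Pr(a > b)$, computed as the fraction of iterations in which $a$ exceeds
$b$ (ties, measure-zero for continuous draws, count one half — this keeps
$\Pr(a>b) + \Pr(b>a) = 1$ identically). Individual heterogeneity within a
group is the per-iteration $(n-1)$-denominator sample variance of the
individuals' current natural-scale values.

In place of purely visual trace inspection, `trace_diagnostics()` reports
a Geyer initial-positive-sequence effective sample size (capped at the
number of draws) and a split-chain $\widehat{R}$, flagging parameters with
$\widehat{R} > 1.1$; trace figures are still written by the CLI for manual
review.

## The synthetic-data generator

`simulate_study()` is the generative counterpart of the model, used for
parameter-recovery testing in place of the original field data. Its
defaults are the study conditions: three treatment groups of 29, 32 and 23
individuals; trajectory lengths uniform on 5–77 relocations; $\sigma_0 = 5$
m. Group truth defaults (`default_truth()`) place mean movement scales at
23, 31 and 34 m (residents smallest, translocated snakes 35–48% larger),
mean movement probabilities per feature inside the 0.24–0.52 band via
probit-scale means, turning-angle means at $\pi$, and autocorrelation means
at 0.50/0.60/0.65. Between-individual variances are moderate by design —
sd 0.3 on the probit scale, 0.5 on logit $\gamma$, ~0.3 rad on $\theta$,
0.25 on $\log \sigma_1$ (individual scales roughly half to double the group
mean) — values a field ecologist would recognise as realistic heterogeneity
rather than noise-free clones or unstructured scatter.

The synthetic landscape (`generate_synthetic_raster()`) tiles the grid into
square patches assigned to the four categories in exact proportion (up to
block rounding) before a seeded shuffle, with optional pavement strips as
road analogues; real classified imagery has irregular patch shapes and
classification error, which this does not emulate. Three deliberate
departures from nature: trajectories **reflect** at the raster boundary
(real animals can leave a study site, but a simulator must keep every
position on covariate support); $\delta_2$ is drawn from the encamped
kernel (the unconditioned first displacement must come from something, and
encamped is the modal state); and there is no telemetry error — positions
are exact. Passing recovery tests therefore demonstrates that the
*samplers* invert the *model*, not that the model is robust to
classification error, positional error, or edge emigration.

## Numerical choices

* Latent-state probabilities, mixture likelihoods and KDE densities are
  computed in log space (log-sum-exp), so extreme displacements or distant
  KDE evaluations stay finite.
* Truncated-normal auxiliaries use inverse-CDF draws with the uniform
  clamped to $[10^{-300}, 1 - 10^{-16}]$.
* The one-hot design makes the stage-1 $\beta$ posterior precision
  diagonal; the sampler exploits this, while the exported
  `update_beta_gibbs()` handles general designs.
* Proposals landing outside a parameter's support get process density
  $-\infty$ and are rejected, never raised as errors.
* Per-individual seeds derive from the master seed by a stable polynomial
  hash of the individual's label, so stage-1 results are independent of
  processing order or concurrency.
* Degenerate KDE pools (all values identical) are an error with advice,
  rather than a silent point mass.

## Problem sizes used by the test suite

The automated checks run at sizes chosen to finish quickly while leaving
the estimators identifiable: single-individual recovery at $T = 300$ with
10,000 stage-1 iterations; recursive-vs-direct agreement on 2 groups × 2
individuals × 30 steps, with three replicate chains per method (10,000
recursive / 20,000 direct iterations each) so the Monte Carlo error of each
posterior-mean estimate is measured from between-chain spread rather than
within-chain autocorrelation; hierarchical recovery on
3 groups × 8 individuals × 80 steps with 10,000 stage-1 and 5,000 stage-2
iterations and a built-in logit-$\gamma$ difference of 1.5 between extreme
groups. These are the package's own verification sizes; the defaults above
remain the full-scale settings.

## Known limitations

* The stage-2 proposal support for individual parameters is the discrete
  set of stage-1 draws; if a stage-1 posterior badly misses the region
  favoured by the hierarchy (tiny $T$, extreme shrinkage), mixing degrades.
  Acceptance rates are logged per parameter to surface this.
* $\theta$'s plain-normal treatment ignores circular wrap-around; estimates
  far from the bulk of $[0, 2\pi)$ would be distorted.
* Reflection at the raster boundary slightly perturbs the displacement
  distribution of steps that hit the edge; generators default to rasters
  much larger than a trajectory's reach.
* No measurement error, missing-data imputation, or continuous-time
  formulation; day gaps are excluded, not modelled.
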