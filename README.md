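# statewalk

Hierarchical Bayesian two-state correlated random walks for daily animal
telemetry, with landscape-dependent state switching and a two-stage
proposal-recursive MCMC fitter.

`statewalk` is for movement ecologists analysing daily relocation data from
a multi-group design — here, a translocation experiment on brown treesnakes
with resident, forest-to-urban and urban-to-urban treatment groups — who
want mechanistic movement parameters (step length, turning angle,
autocorrelation) and landscape-specific movement probabilities with full
posterior uncertainty at both the individual and treatment level.

## The model

Nightly displacements δ*ₜ* = s*ₜ* − s*ₜ₋₁* follow a two-component normal
mixture:

- **encamped**: δ*ₜ* ~ N(0, σ₀²I), σ₀ = 5 m fixed (a "95% movement kernel"
  of 2σ₀ = 10 m);
- **movement**: δ*ₜ* ~ N(γ M(θ) δ*ₜ₋₁*, σ₁²I), where M(θ) is the 2×2
  rotation by turning angle θ and γ ∈ (0,1) damps the autoregression;

with movement probability p*ₜ* = Φ(x′*ₜ₋₁*β), a probit regression on the
one-hot landscape category (tree, pavement, grass, building) at the step's
starting position. Individual parameters (βᵢ, γᵢ, θᵢ, σ²₁ᵢ) arise from
treatment-level normals on transformed scales (logit γ, θ, log σ₁, and a
full covariance Σ_β for β).

Fitting is in two stages: independent per-individual samplers (probit data
augmentation, conjugate Gibbs and prior-as-proposal Metropolis updates),
whose draws are then recycled as proposals — with kernel-density proposal
corrections and change-of-variables adjustments — inside the hierarchical
sampler. Treatment-level means, variances and Σ_β get conjugate Gibbs
updates. See `vignette("two-state-movement")` for the full account.

## Worked example

```r
library(statewalk)

# a synthetic landscape and a small known-truth study
raster <- generate_synthetic_raster(150, 150, cell_size = 2, seed = 3)
study  <- simulate_study(study_config(n_individuals = c(4, 4, 4),
                                      length_range = c(30, 60),
                                      raster = raster, seed = 42))

# the full two-stage fit (reduced iterations for the example)
fit <- fit_movement(study, stage1_iter = 2000, stage2_iter = 1000,
                    n_mc = 300, seed = 9)
print(fit)
```

```
Two-state correlated random walk, hierarchical fit
  12 individuals, 3 treatment groups
  stage 1: 2000 iterations/individual; stage 2: 1000 (100 burn-in)

Treatment-level posterior means (natural scales):
                mu_gamma mu_sigma1 mu_theta mu_p.tree mu_p.pavement mu_p.grass
forest_to_urban    0.505    35.450    2.860     0.416         0.546      0.438
resident           0.574    20.376    2.872     0.491         0.407      0.552
urban_to_urban     0.555    25.685    3.141     0.550         0.393      0.484
...
```

`mu_gamma` is the group-mean autocorrelation (truths here 0.50/0.60/0.65),
`mu_sigma1` the group-mean movement-state scale in metres (truths
23/31/34 — recovered within posterior uncertainty even at this toy size),
`mu_theta` the turning angle in radians (truth π ≈ 3.14, i.e. course
reversals), and `mu_p.<feature>` the mean nightly movement probability from
each landscape feature, integrated over individual heterogeneity by Monte
Carlo. `summary(fit)` adds credible intervals, pairwise treatment
differences with posterior probabilities, and individual-heterogeneity
variances; `plot(fit)` draws group-level traces.

A file-based pipeline with the same semantics is available from the shell:

```sh
Rscript inst/cli/statewalk all --config config.yml --seed 7
```

which writes trajectory tables, per-individual stage-1 draws, hierarchical
draws, summary/comparison/diagnostic CSVs and trace figures, and a run log
recording the resolved configuration, its hash and every seed.

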